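# RPKM computation, expression classes, and RNA-seq vs microarray
# present/absent concordance.

#' Compute RPKM
#'
#' Reads per kilobase of exon per million mapped reads.
#'
#' @param exon_reads Reads assigned to the gene's exon union.
#' @param exonic_kb Exonic length in kb (must be positive).
#' @param mapped_millions Library size in millions of mapped reads.
#' @return RPKM value(s).
#' @export
compute_rpkm <- function(exon_reads, exonic_kb, mapped_millions) {
  assert_that(all(exonic_kb > 0), "exonic length must be positive")
  assert_that(all(mapped_millions > 0), "mapped read count must be positive")
  exon_reads / (exonic_kb * mapped_millions)
}

#' Log-transform RPKM with a pseudo-count of 1
#'
#' @param rpkm Non-negative RPKM value(s).
#' @return `log2(rpkm + 1)`.
#' @export
log_rpkm <- function(rpkm) {
  assert_that(all(rpkm >= 0), "RPKM must be non-negative")
  log2(rpkm + 1)
}

#' Classify genes by expression level
#'
#' Genes with RPKM at or below `silent_max` form the silent group; genes
#' with RPKM of at least 1 are expressed; the remainder are intermediate.
#' Expressed genes are subdivided into low/moderate/high by `group_bounds`
#' (defaults to tertiles of the expressed genes in `rpkm`).
#'
#' @param rpkm RPKM vector.
#' @param group_bounds Numeric `(b1, b2)` with `1 <= b1 < b2`, the
#'   low/moderate and moderate/high RPKM boundaries; `NULL` (default) uses
#'   tertiles of the expressed genes.
#' @param silent_max Largest RPKM still called silent (default 0: only
#'   fully undetected genes are silent; the differentiation-gene logic uses
#'   its own 0.5 cutoff via [flag_differentiation()]).
#' @param expressed_min Smallest RPKM called expressed (default 1).
#' @return `data.table` with `rpkm`, `expression_class` (ordered factor
#'   silent < intermediate < expressed) and `subgroup` (low/moderate/high
#'   for expressed genes, `NA` otherwise).
#' @export
classify_expression <- function(rpkm, group_bounds = NULL, silent_max = 0,
                                expressed_min = 1) {
  cls <- fifelse(rpkm <= silent_max, "silent",
                 fifelse(rpkm >= expressed_min, "expressed", "intermediate"))
  expr <- rpkm[cls == "expressed"]
  if (is.null(group_bounds)) {
    if (length(expr) >= 3L) {
      group_bounds <- unname(quantile(expr, c(1 / 3, 2 / 3)))
    } else {
      group_bounds <- c(Inf, Inf)  # too few genes to split
    }
  }
  assert_that(length(group_bounds) == 2L && group_bounds[1] <= group_bounds[2],
              "group_bounds must be an ordered pair")
  sub <- rep(NA_character_, length(rpkm))
  sub[cls == "expressed"] <-
    fifelse(expr <= group_bounds[1], "low",
            fifelse(expr <= group_bounds[2], "moderate", "high"))
  data.table(
    rpkm = rpkm,
    expression_class = factor(cls, levels = c("silent", "intermediate",
                                              "expressed"), ordered = TRUE),
    subgroup = factor(sub, levels = c("low", "moderate", "high"))
  )
}

#' Read an RPKM table
#'
#' @param path TSV with a `gene_id` column and one or more numeric RPKM
#'   columns (e.g. `rpkm_bam`, `rpkm_wt`).
#' @return `data.table` keyed by `gene_id`.
#' @export
read_rpkm_table <- function(path) {
  x <- fread(path, sep = "\t")
  assert_that("gene_id" %in% names(x), "RPKM table must have a gene_id column")
  setkey(x, gene_id)
  x[]
}

#' Read microarray present/absent calls
#'
#' @param path TSV with `gene_id` and one column per replicate holding
#'   `P`, `A` or `M` calls. Multiple rows per gene are interpreted as
#'   multiple probes.
#' @return `data.table` with one row per probe.
#' @export
read_microarray_calls <- function(path) {
  x <- fread(path, sep = "\t", colClasses = "character")
  assert_that("gene_id" %in% names(x), "call table must have a gene_id column")
  callcols <- setdiff(names(x), "gene_id")
  assert_that(length(callcols) >= 1L, "call table needs at least one replicate column")
  for (cc in callcols)
    assert_that(all(x[[cc]] %in% c("P", "A", "M")),
                "call column %s contains symbols other than P/A/M", cc)
  x[]
}

#' RNA-seq vs microarray concordance summary
#'
#' Collapses probes to genes (dropping genes whose probes give inconsistent
#' call patterns), joins with an RPKM table, and summarizes the two failure
#' modes of detection calls: all-Absent genes that RNA-seq finds expressed
#' (RPKM >= 1), and all-Present genes with RPKM below 0.5. The log2 RPKM
#' histogram (pseudo-count 1) of all-Present genes supports choosing the
#' expressed-gene RPKM cutoff.
#'
#' @param calls Probe-level call table from [read_microarray_calls()].
#' @param rpkm RPKM table with `gene_id` and the column named by
#'   `rpkm_column`.
#' @param rpkm_column Which RPKM column to compare against.
#' @return List with `n_replicates`, gene counts (`n_all_absent`,
#'   `n_all_absent_expressed`, `n_all_present`, `n_all_present_expressed`,
#'   `n_all_present_below_half`), the corresponding fractions
#'   (`frac_absent_expressed`, `frac_present_expressed`), `dropped`
#'   (inconsistent multi-probe genes), `unjoined` (genes without RPKM), and
#'   `hist_all_present` (log2 RPKM histogram of all-Present genes).
#' @export
concordance <- function(calls, rpkm, rpkm_column = "rpkm_bam") {
  calls <- as.data.table(calls)
  callcols <- setdiff(names(calls), "gene_id")
  gene <- calls[, .(call_string = paste(do.call(paste0, .SD), collapse = "|"),
                    n_probes = .N), .SDcols = callcols, by = gene_id]
  gene[, consistent := !grepl("|", call_string, fixed = TRUE) |
         lengths(lapply(strsplit(call_string, "|", fixed = TRUE), unique)) == 1L]
  dropped <- gene[consistent == FALSE, gene_id]
  gene <- gene[consistent == TRUE]
  gene[, call_string := vapply(strsplit(call_string, "|", fixed = TRUE),
                               `[[`, character(1), 1L)]
  rp <- as.data.table(rpkm)
  assert_that(rpkm_column %in% names(rp), "RPKM table lacks column %s", rpkm_column)
  m <- merge(gene, rp[, .(gene_id, rpkm = get(rpkm_column))], by = "gene_id",
             all.x = TRUE)
  unjoined <- m[is.na(rpkm), gene_id]
  m <- m[!is.na(rpkm)]
  n_rep <- nchar(m$call_string[1])
  all_a <- m[call_string == strrep("A", n_rep)]
  all_p <- m[call_string == strrep("P", n_rep)]
  h <- if (nrow(all_p) > 0)
    graphics::hist(log_rpkm(all_p$rpkm), breaks = "Sturges", plot = FALSE)
  else NULL
  list(
    n_replicates = n_rep,
    n_all_absent = nrow(all_a),
    n_all_absent_expressed = sum(all_a$rpkm >= 1),
    frac_absent_expressed = if (nrow(all_a)) mean(all_a$rpkm >= 1) else NA_real_,
    n_all_present = nrow(all_p),
    n_all_present_expressed = sum(all_p$rpkm >= 1),
    frac_present_expressed = if (nrow(all_p)) mean(all_p$rpkm >= 1) else NA_real_,
    n_all_present_below_half = sum(all_p$rpkm < 0.5),
    dropped = dropped,
    unjoined = unjoined,
    hist_all_present = h
  )
}
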