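# Gene annotation ingestion, transcript eligibility filtering, strand-aware
# analysis windows, and dominant-transcript selection.

#' Read transcript models from an annotation file
#'
#' Parses gene annotations into a transcript table with 0-based half-open
#' coordinates. Three dialects are supported: UCSC genePred/refFlat (plain
#' TSV; 10 columns, or 11 with a leading gene symbol), BED12 and GTF (both
#' read through \pkg{rtracklayer}).
#'
#' @param path Path to the annotation file.
#' @param format One of `"genepred"`, `"bed12"`, `"gtf"`.
#' @return A `data.table` with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end` (0-based half-open),
#'   `exon_starts`/`exon_ends` (list columns), `tx_len`, `exonic_len`, and
#'   `tss` (equal to `tx_end` on the minus strand).
#' @details Records with a strand symbol other than `+`/`-` are dropped with
#'   a warning; structurally malformed lines abort with the offending line
#'   number.
#' @export
read_transcripts <- function(path, format = c("genepred", "bed12", "gtf")) {
  format <- match.arg(format)
  assert_that(file.exists(path), "annotation file not found: %s", path)
  tx <- switch(format,
    genepred = read_genepred(path),
    bed12 = read_bed12(path),
    gtf = read_gtf(path)
  )
  bad <- !(tx$strand %in% c("+", "-"))
  if (any(bad)) {
    warning(sprintf("dropping %d record(s) with unknown strand symbol", sum(bad)))
    tx <- tx[!bad]
  }
  tx[, tx_len := tx_end - tx_start]
  tx[, exonic_len := vapply(seq_len(.N), function(i)
    sum(exon_ends[[i]] - exon_starts[[i]]), integer(1))]
  tx[, tss := fifelse(strand == "+", tx_start, tx_end)]
  validate_transcripts(tx)
  setorder(tx, chrom, tx_start, transcript_id)
  tx[]
}

read_genepred <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (!all(ncols %in% c(10L, 11L)) || length(unique(ncols)) != 1L) {
    bad <- which(!(ncols %in% c(10L, 11L)) | ncols != ncols[1])[1]
    stop(sprintf("genePred parse error at line %d: expected 10 (genePred) or 11 (refFlat) tab-separated fields, found %d",
                 bad, ncols[bad]), call. = FALSE)
  }
  off <- if (ncols[1] == 11L) 1L else 0L  # refFlat: leading gene symbol
  get <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i, what) {
    v <- suppressWarnings(as.integer(get(i)))
    if (anyNA(v)) stop(sprintf("genePred parse error at line %d: non-numeric %s",
                               which(is.na(v))[1], what), call. = FALSE)
    v
  }
  parse_ints <- function(s) lapply(strsplit(s, ",", fixed = TRUE),
                                   function(x) as.integer(x[nzchar(x)]))
  data.table(
    transcript_id = get(off + 1L),
    gene_id = if (off == 1L) get(1L) else get(1L),
    chrom = get(off + 2L),
    strand = get(off + 3L),
    tx_start = num(off + 4L, "txStart"),
    tx_end = num(off + 5L, "txEnd"),
    exon_starts = parse_ints(get(off + 9L)),
    exon_ends = parse_ints(get(off + 10L))
  )
}

read_bed12 <- function(path) {
  requireNamespace_or_stop("rtracklayer", "reading BED12")
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- rtracklayer::blocks(gr)
  data.table(
    transcript_id = as.character(gr$name),
    gene_id = as.character(gr$name),  # BED12 carries no gene grouping
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    tx_start = GenomicRanges::start(gr) - 1L,
    tx_end = GenomicRanges::end(gr),
    exon_starts = lapply(blocks, function(b) GenomicRanges::start(b) - 1L),
    exon_ends = lapply(blocks, function(b) GenomicRanges::end(b))
  )
}

read_gtf <- function(path) {
  requireNamespace_or_stop("rtracklayer", "reading GTF")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  assert_that(length(gr) > 0, "GTF contains no exon records: %s", path)
  ex <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id)
  )
  setorder(ex, transcript_id, start)
  ex[, .(
    gene_id = gene_id[1], chrom = chrom[1], strand = strand[1],
    tx_start = min(start), tx_end = max(end),
    exon_starts = list(start), exon_ends = list(end)
  ), by = transcript_id]
}

requireNamespace_or_stop <- function(pkg, what) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop(sprintf("package '%s' is required for %s", pkg, what), call. = FALSE)
}

validate_transcripts <- function(tx) {
  assert_that(all(tx$tx_start < tx$tx_end), "transcript with tx_start >= tx_end")
  for (i in seq_len(nrow(tx))) {
    s <- tx$exon_starts[[i]]; e <- tx$exon_ends[[i]]
    assert_that(length(s) == length(e) && length(s) > 0,
                "transcript %s: empty or ragged exon list", tx$transcript_id[i])
    assert_that(all(s < e), "transcript %s: exon with start >= end", tx$transcript_id[i])
    assert_that(!is.unsorted(s, strictly = FALSE) && all(head(e, -1) <= tail(s, -1)),
                "transcript %s: exons unsorted or overlapping", tx$transcript_id[i])
    assert_that(s[1] >= tx$tx_start[i] && tail(e, 1) <= tx$tx_end[i],
                "transcript %s: exons outside transcript span", tx$transcript_id[i])
  }
  invisible(tx)
}

#' Apply the three-step transcript eligibility filter
#'
#' Step 1 removes transcripts shorter than `min_len`. Step 2 removes, per
#' promoter analysis, transcripts whose promoter window intersects the
#' transcript span of a different gene, and flags non-overlapping
#' opposite-strand transcript pairs whose TSSs lie closer than `tss_gap`
#' (these stay usable for the H3K4me3/H3K27me3 promoter window but are
#' excluded from the Pol II and stalling analyses, whose -250..+250 window
#' the close TSS would contaminate). Step 3 reports the surviving set with
#' per-transcript eligibility flags.
#'
#' @param tx Transcript table from [read_transcripts()].
#' @param min_len Minimum transcript length in bp (default 500).
#' @param tss_gap Minimum TSS separation in bp for divergent non-overlapping
#'   neighbours (default 400); applied to the Pol II analysis only.
#' @return An object of class `eligibility_set`: a `data.table` with the
#'   input identifier columns plus logical flags `too_short`,
#'   `overlap_k4k27`, `overlap_polII`, `tss_too_close`, `promoter_eligible`,
#'   `polII_eligible`, `stalling_eligible`, `k36_eligible` and a `reason`
#'   code (`too_short`, `overlap_conflict`, `tss_too_close`,
#'   `unknown_chrom`, or `NA` when no exclusion applies).
#' @export
filter_transcripts <- function(tx, min_len = 500L, tss_gap = 400L) {
  es <- copy(tx[, .(transcript_id, gene_id, chrom, strand, tx_start, tx_end,
                    tx_len, tss)])
  es[, unknown_chrom := is.na(chrom) | !nzchar(chrom)]
  es[, too_short := !unknown_chrom & tx_len < min_len]

  surv <- es[!too_short & !unknown_chrom]
  # Step 2a: promoter window vs other-gene transcript span, per analysis.
  spans <- surv[, .(chrom, s = tx_start, e = tx_end - 1L, gene_id)]
  setkey(spans, chrom, s, e)
  window_conflict <- function(ws, we) {
    w <- surv[, .(transcript_id, gene_id, chrom,
                  s = pmax(ws, 0L), e = pmax(we - 1L, 0L))]
    hits <- foverlaps(w, spans, type = "any", nomatch = NULL)
    unique(hits[gene_id != i.gene_id, transcript_id])
  }
  # the Pol II window is symmetric about the TSS so both strands share it
  conf_polII <- window_conflict(surv$tss - 250L, surv$tss + 250L)
  conf_k4k27 <- window_conflict(
    fifelse(surv$strand == "+", surv$tss, surv$tss - 500L),
    fifelse(surv$strand == "+", surv$tss + 500L, surv$tss)
  )
  es[, overlap_polII := transcript_id %in% conf_polII]
  es[, overlap_k4k27 := transcript_id %in% conf_k4k27]

  # Step 2b: divergent non-overlapping neighbours with close TSSs.
  pts <- surv[, .(transcript_id, gene_id, chrom, strand, tx_start, tx_end,
                  tss, s = tss, e = tss)]
  nb <- surv[, .(transcript_id, gene_id, chrom, strand, tx_start, tx_end, tss,
                 s = tss - (tss_gap - 1L), e = tss + (tss_gap - 1L))]
  setkey(nb, chrom, s, e)
  pr <- foverlaps(pts, nb, type = "any", nomatch = NULL)
  close_ids <- unique(pr[
    gene_id != i.gene_id & strand != i.strand &
      (tx_end <= i.tx_start | i.tx_end <= tx_start),
    c(transcript_id, i.transcript_id)])
  es[, tss_too_close := transcript_id %in% close_ids]

  es[, promoter_eligible := !unknown_chrom & !too_short & !overlap_k4k27]
  es[, polII_eligible := promoter_eligible & !overlap_polII & !tss_too_close]
  es[, stalling_eligible := polII_eligible & tx_len > 1000L]
  es[, k36_eligible := promoter_eligible & tx_len > 1500L]
  es[, reason := fifelse(unknown_chrom, "unknown_chrom",
                 fifelse(too_short, "too_short",
                 fifelse(overlap_k4k27 | overlap_polII, "overlap_conflict",
                 fifelse(tss_too_close, "tss_too_close", NA_character_))))]
  setattr(es, "class", c("eligibility_set", class(es)))
  es[]
}

#' Summarize eligibility at the gene level
#'
#' A gene is eligible for an analysis when at least one of its transcripts
#' is. Stalling-eligible genes are a subset of promoter-eligible genes;
#' H3K36me3-eligible genes additionally need a transcript longer than 1.5 kb.
#'
#' @param es An `eligibility_set` from [filter_transcripts()].
#' @return A `data.table` keyed by `gene_id` with transcript counts and
#'   per-analysis eligibility flags.
#' @export
gene_eligibility <- function(es) {
  es[, .(
    n_transcripts = .N,
    n_excluded = sum(!is.na(reason)),
    promoter_eligible = any(promoter_eligible),
    polII_eligible = any(polII_eligible),
    stalling_eligible = any(stalling_eligible),
    k36_eligible = any(k36_eligible)
  ), by = gene_id]
}

#' Derive strand-aware analysis windows for transcripts
#'
#' Four windows are defined relative to the TSS, in the direction of
#' transcription: the Pol II promoter window (-250..+250), the
#' H3K4me3/H3K27me3 promoter window (0..+500), the gene body (+500..+1000,
#' only for transcripts longer than 1 kb) and the H3K36me3 window
#' (+500..+1500, only for transcripts longer than 1.5 kb). On the minus
#' strand the "+x" offsets run leftward from the TSS (= `tx_end`).
#'
#' @param tx Transcript table from [read_transcripts()] (or any table with
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `tss`, `tx_len`).
#' @return A long-format `data.table` with columns `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `kind` (one of `promoter_polII`,
#'   `promoter_k4k27`, `gene_body`, `k36_window`), `start`, `end` (genomic,
#'   half-open). Windows crossing the chromosome start are truncated at 0
#'   with a warning.
#' @export
derive_windows <- function(tx) {
  mk <- function(kind, up, down, min_len = 0L) {
    keep <- tx$tx_len > min_len
    t2 <- tx[keep]
    # up/down are offsets along the direction of transcription
    s <- fifelse(t2$strand == "+", t2$tss + up, t2$tss - down)
    e <- fifelse(t2$strand == "+", t2$tss + down, t2$tss - up)
    data.table(transcript_id = t2$transcript_id, gene_id = t2$gene_id,
               chrom = t2$chrom, strand = t2$strand, kind = kind,
               start = s, end = e)
  }
  w <- rbindlist(list(
    mk("promoter_polII", -250L, 250L),
    mk("promoter_k4k27", 0L, 500L),
    mk("gene_body", 500L, 1000L, min_len = 1000L),
    mk("k36_window", 500L, 1500L, min_len = 1500L)
  ))
  if (any(w$start < 0L)) {
    warning(sprintf("%d window(s) truncated at chromosome start", sum(w$start < 0L)))
    w[, start := pmax(start, 0L)]
    w[, end := pmax(end, 0L)]
  }
  w[]
}

#' Select the dominant transcript for each gene
#'
#' Multi-isoform genes are represented by a single transcript chosen by an
#' ordered chain of read-count criteria. Three chains are provided, matching
#' the three comparisons the windows feed: `polII_vs_rpkm` (primary
#' criterion: Pol II reads in -250..+250; ties broken by gene-body Pol II
#' reads for isoform sets longer than 1 kb, otherwise H3K4me3 promoter
#' reads), `k4_vs_k27` (primary: H3K4me3 reads in 0..+500; ties by H3K36me3
#' reads for sets longer than 1.5 kb, otherwise Pol II promoter reads) and
#' `k36_vs_rpkm` (restricted to transcripts longer than 1.5 kb; primary:
#' H3K36me3 reads, ties by H3K4me3 promoter reads). Remaining ties go to the
#' longest transcript, then to a seeded random choice.
#'
#' @param tx Transcript table (may contain several genes).
#' @param counts `data.table` keyed by `transcript_id` with count columns
#'   `polII_prom`, `polII_body`, `k4_prom`, `k36` (missing columns are
#'   treated as all-zero only if unused by the chosen chain).
#' @param chain Which criterion chain to apply.
#' @param seed Integer seed for the final random tie-break (recorded so
#'   "chosen randomly" is reproducible).
#' @return `data.table` with one row per gene: `gene_id`, `transcript_id`.
#' @export
select_dominant_transcript <- function(tx, counts,
                                       chain = c("polII_vs_rpkm", "k4_vs_k27",
                                                 "k36_vs_rpkm"),
                                       seed = 1L) {
  chain <- match.arg(chain)
  cand <- merge(tx[, .(transcript_id, gene_id, tx_len)], counts,
                by = "transcript_id", all.x = TRUE)
  for (col in c("polII_prom", "polII_body", "k4_prom", "k36"))
    if (!col %in% names(cand)) cand[, (col) := 0]
  for (col in c("polII_prom", "polII_body", "k4_prom", "k36"))
    cand[is.na(get(col)), (col) := 0]
  if (chain == "k36_vs_rpkm") cand <- cand[tx_len > 1500L]

  pick_one <- function(d, gid) {
    if (nrow(d) == 0L) return(character(0))
    d <- d[order(transcript_id)]  # order-invariance of the input
    primary <- switch(chain, polII_vs_rpkm = d$polII_prom,
                      k4_vs_k27 = d$k4_prom, k36_vs_rpkm = d$k36)
    d <- d[primary == max(primary)]
    if (nrow(d) > 1L) {
      secondary <- switch(chain,
        polII_vs_rpkm = if (all(d$tx_len > 1000L)) d$polII_body else d$k4_prom,
        k4_vs_k27 = if (all(d$tx_len > 1500L)) d$k36 else d$polII_prom,
        k36_vs_rpkm = d$k4_prom)
      d <- d[secondary == max(secondary)]
    }
    if (nrow(d) > 1L) d <- d[tx_len == max(tx_len)]
    if (nrow(d) > 1L)
      d <- d[with_seed(derive_seed(seed, gid), sample.int(nrow(d), 1L))]
    d$transcript_id
  }
  res <- cand[, .(transcript_id = pick_one(.SD, .BY$gene_id)), by = gene_id]
  missing <- setdiff(unique(tx$gene_id), res$gene_id)
  if (length(missing) > 0)
    stop(sprintf("no eligible transcript to select for gene(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  res[]
}
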