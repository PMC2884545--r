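# Synthetic-data generator: annotations with planted filter special cases,
# ChIP read libraries with planted valency / Pol II pausing classes, RPKM
# tables and microarray calls with planted expression status.

#' Simulation configuration
#'
#' Defines the conditions the generator emulates: uniform Poisson
#' background reads over a mappable genome, promoter-localized enrichment
#' with a fixed fragment-size strand offset, planted valency and Pol II
#' pausing classes, RPKM values consistent with planted silent/expressed
#' status, and microarray calls with a configurable false-absent rate.
#'
#' @param seed Master seed; all generator stages derive their streams from
#'   it.
#' @param n_genes Number of regular (fully analyzable) genes.
#' @param chrom Name of the single synthetic chromosome.
#' @param genome_bp Chromosome length; `NULL` (default) sizes it to fit the
#'   requested genes with spacing. If supplied and too small, generation
#'   aborts suggesting a larger value.
#' @param background_rate Background read density in reads/bp per library
#'   (default 0.008, the density of a ~1M-read library on the ~120-Mb
#'   mappable fly genome; gives lambda = 4 per 500-bp window).
#' @param enrichment_fold Enriched windows receive *additional* reads at
#'   this multiple of the local background (default 5).
#' @param fragment_size ChIP fragment size in bp (default 160); plus- and
#'   minus-strand 5' positions are offset by half of it on each side of the
#'   binding point.
#' @param read_len Read length in bp (default 25).
#' @param summit_sd Spread (bp, s.d.) of enriched reads' binding points
#'   around the window-centre summit (default 25, a well-positioned summit).
#' @param promoter_body_ratio Promoter:body total read-rate ratio for
#'   stalled genes (default 15, strong promoter-proximal pausing; must be
#'   at least 5 so planted stalled genes sit in the stalled class).
#' @param active_body_ratio Promoter:body ratio for active genes (default
#'   1.2; must be at most 3).
#' @param valency_mix,polII_mix,expression_mix Named proportions over the
#'   planted classes (each must sum to 1).
#' @param diff_fraction Fraction of silent genes planted as differentiation
#'   genes (silent in the undifferentiated condition, expressed wild-type).
#' @param up_extra_fraction Fraction of expressed genes planted with a
#'   >= 2-fold wild-type gain.
#' @param false_absent_rate Probability that an expressed gene is flipped
#'   to all-Absent microarray calls.
#' @param n_microarray_replicates Replicate count for the call table.
#' @param n_short_transcripts,n_overlapping_pairs,n_close_tss_pairs,n_multi_isoform
#'   Planted filter special cases (counts of genes / gene pairs).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_genes = 2000L, chrom = "chrS",
                              genome_bp = NULL,
                              background_rate = 0.008, enrichment_fold = 5,
                              fragment_size = 160L, read_len = 25L,
                              summit_sd = 25,
                              promoter_body_ratio = 15,
                              active_body_ratio = 1.2,
                              valency_mix = c(k4_monovalent = 0.34,
                                              k27_monovalent = 0.16,
                                              bivalent = 0.05,
                                              neither = 0.45),
                              polII_mix = c(active = 0.35, stalled = 0.15,
                                            none = 0.50),
                              expression_mix = c(silent = 0.40,
                                                 expressed = 0.60),
                              diff_fraction = 0.5,
                              up_extra_fraction = 0.3,
                              false_absent_rate = 0.1,
                              n_microarray_replicates = 3L,
                              n_short_transcripts = 0L,
                              n_overlapping_pairs = 0L,
                              n_close_tss_pairs = 0L,
                              n_multi_isoform = 0L) {
  chk_mix <- function(m, nm) assert_that(abs(sum(m) - 1) < 1e-8,
                                         "%s must sum to 1", nm)
  chk_mix(valency_mix, "valency_mix")
  chk_mix(polII_mix, "polII_mix")
  chk_mix(expression_mix, "expression_mix")
  assert_that(enrichment_fold > 1, "enrichment_fold must exceed 1")
  assert_that(promoter_body_ratio >= 5,
              "promoter_body_ratio must be >= 5 for stalled genes")
  assert_that(active_body_ratio <= 3,
              "active_body_ratio must be <= 3 for active genes")
  cfg <- as.list(environment())
  cfg$chk_mix <- NULL
  structure(cfg, class = "simulation_config")
}

#' Generate an annotation with planted special cases
#'
#' Places `n_genes` regular genes (2-4 kb, random strand, spaced so no
#' promoter window touches a neighbour) followed by the requested special
#' cases: sub-500-bp transcripts (planted `too_short` exclusions),
#' same-strand nested gene pairs whose promoter windows fall inside the
#' partner's span (planted `overlap_conflict`), divergent non-overlapping
#' pairs with TSSs 300 bp apart (planted `tss_too_close`), and two-isoform
#' genes sharing a TSS (dominant-transcript exercise).
#'
#' @param cfg A `simulation_config`.
#' @return List with `transcripts` (same shape as [read_transcripts()]
#'   output), `truth` (per-gene planted labels), `chrom_sizes`, and `cfg`.
#' @export
simulate_annotation <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "annotation"), {
    rows <- list()
    truth <- list()
    cursor <- 2000L
    place <- function(len) {
      gap <- 1500L + as.integer(floor(runif(1, 0, 1000)))
      st <- cursor + gap
      cursor <<- st + len
      st
    }
    add_tx <- function(gene, txid, st, len, strand) {
      rows[[length(rows) + 1L]] <<- data.table(
        transcript_id = txid, gene_id = gene, chrom = cfg$chrom,
        strand = strand, tx_start = st, tx_end = st + len,
        exon_starts = list(st), exon_ends = list(st + len))
    }
    add_truth <- function(gene, special, dominant) {
      truth[[length(truth) + 1L]] <<- data.table(
        gene_id = gene, special = special, dominant_transcript = dominant)
    }
    for (i in seq_len(cfg$n_genes)) {
      g <- sprintf("gene%05d", i)
      len <- as.integer(sample(2000:4000, 1))
      st <- place(len)
      strand <- sample(c("+", "-"), 1)
      add_tx(g, paste0(g, ".t1"), st, len, strand)
      add_truth(g, "regular", paste0(g, ".t1"))
    }
    for (i in seq_len(cfg$n_multi_isoform)) {
      g <- sprintf("multi%03d", i)
      st <- place(3000L)
      strand <- sample(c("+", "-"), 1)
      # both isoforms share the TSS; the longer one is the planted dominant
      if (strand == "+") {
        add_tx(g, paste0(g, ".t1"), st, 3000L, strand)
        add_tx(g, paste0(g, ".t2"), st, 2600L, strand)
      } else {
        add_tx(g, paste0(g, ".t1"), st, 3000L, strand)
        add_tx(g, paste0(g, ".t2"), st + 400L, 2600L, strand)
      }
      add_truth(g, "multi_isoform", paste0(g, ".t1"))
    }
    for (i in seq_len(cfg$n_short_transcripts)) {
      g <- sprintf("short%03d", i)
      st <- place(400L)
      add_tx(g, paste0(g, ".t1"), st, 400L, "+")
      add_truth(g, "too_short", paste0(g, ".t1"))
    }
    for (i in seq_len(cfg$n_overlapping_pairs)) {
      ga <- sprintf("ovlA%03d", i); gb <- sprintf("ovlB%03d", i)
      st <- place(3200L)
      add_tx(ga, paste0(ga, ".t1"), st, 3000L, "+")
      add_tx(gb, paste0(gb, ".t1"), st + 200L, 3000L, "+")
      add_truth(ga, "overlap_conflict", paste0(ga, ".t1"))
      add_truth(gb, "overlap_conflict", paste0(gb, ".t1"))
    }
    for (i in seq_len(cfg$n_close_tss_pairs)) {
      ga <- sprintf("tssA%03d", i); gb <- sprintf("tssB%03d", i)
      st <- place(5300L)
      add_tx(ga, paste0(ga, ".t1"), st, 2500L, "-")          # TSS = st + 2500
      add_tx(gb, paste0(gb, ".t1"), st + 2800L, 2500L, "+")  # TSS 300 bp away
      add_truth(ga, "tss_too_close", paste0(ga, ".t1"))
      add_truth(gb, "tss_too_close", paste0(gb, ".t1"))
    }
    tx <- rbindlist(rows)
    tx[, tx_len := tx_end - tx_start]
    tx[, exonic_len := tx_len]
    tx[, tss := fifelse(strand == "+", tx_start, tx_end)]
    genome_bp <- cursor + 2000L
    if (!is.null(cfg$genome_bp)) {
      assert_that(cfg$genome_bp >= genome_bp,
                  "infeasible packing: %d genes need %d bp; increase genome_bp (got %d)",
                  nrow(tx), genome_bp, cfg$genome_bp)
      genome_bp <- as.integer(cfg$genome_bp)
    }
    truth <- rbindlist(truth)
    truth <- assign_classes(truth, cfg)
    list(transcripts = tx[], truth = truth,
         chrom_sizes = setNames(genome_bp, cfg$chrom), cfg = cfg)
  })
}

# Draw per-gene planted classes. Special-case genes that the filter removes
# are planted as unmarked/unbound so every planted mark is recoverable.
assign_classes <- function(truth, cfg) {
  n <- nrow(truth)
  analyzable <- truth$special %in% c("regular", "multi_isoform")
  truth[, valency_truth := "neither"]
  truth[, polII_truth := "none"]
  k <- sum(analyzable)
  truth[analyzable, valency_truth := sample(names(cfg$valency_mix), k,
                                            replace = TRUE,
                                            prob = cfg$valency_mix)]
  truth[analyzable, polII_truth := sample(names(cfg$polII_mix), k,
                                          replace = TRUE,
                                          prob = cfg$polII_mix)]
  truth[, expression_truth := sample(names(cfg$expression_mix), n,
                                     replace = TRUE,
                                     prob = cfg$expression_mix)]
  truth[]
}

#' Generate a ChIP read library with planted enrichment
#'
#' Background reads fall uniformly over the genome at
#' `cfg$background_rate`. Marked genes receive additional reads in the
#' mark's window at `enrichment_fold` times the window's background
#' expectation (Pol II promoter/body rates follow the planted pausing
#' class). Each enriched read derives from a binding point uniform in the
#' window; sequencing from either fragment end offsets plus- and
#' minus-strand 5' positions by half the fragment size in opposite
#' directions, so the strand peak offset equals `cfg$fragment_size`.
#'
#' @param sim Output of [simulate_annotation()].
#' @param mark One of `"polII"`, `"k4"`, `"k27"`, `"k36"`, `"h3"` (the `h3`
#'   control library carries no planted enrichment).
#' @return A `read_library`.
#' @export
simulate_chip_library <- function(sim, mark = c("polII", "k4", "k27", "k36",
                                                "h3")) {
  mark <- match.arg(mark)
  cfg <- sim$cfg
  genome_bp <- unname(sim$chrom_sizes[[cfg$chrom]])
  with_seed(derive_seed(cfg$seed, paste0("lib_", mark)), {
    lam_bp <- cfg$background_rate
    n_bg <- rpois(1, lam_bp * genome_bp)
    bg <- data.table(five = as.integer(floor(runif(n_bg, 0, genome_bp))),
                     strand = sample(c("+", "-"), n_bg, replace = TRUE))

    dom <- sim$transcripts[sim$truth, on = c(transcript_id = "dominant_transcript"),
                           nomatch = NULL]
    w <- derive_windows(dom)
    tr <- merge(w, sim$truth, by = "gene_id")
    pick <- switch(mark,
      k4 = tr[kind == "promoter_k4k27" &
                valency_truth %in% c("k4_monovalent", "bivalent")][
        , rate := cfg$enrichment_fold * lam_bp * (end - start)],
      k27 = tr[kind == "promoter_k4k27" &
                 valency_truth %in% c("k27_monovalent", "bivalent")][
        , rate := cfg$enrichment_fold * lam_bp * (end - start)],
      k36 = tr[kind == "k36_window" & expression_truth == "expressed"][
        , rate := cfg$enrichment_fold * lam_bp * (end - start)],
      polII = rbindlist(list(
        tr[kind == "promoter_polII" & polII_truth == "active"][
          , rate := cfg$enrichment_fold * lam_bp * (end - start)],
        tr[kind == "gene_body" & polII_truth == "active"][
          , rate := ((1 + cfg$enrichment_fold) / cfg$active_body_ratio - 1) *
                    lam_bp * (end - start)],
        tr[kind == "promoter_polII" & polII_truth == "stalled"][
          , rate := (cfg$promoter_body_ratio - 1) * lam_bp * (end - start)]
      )),
      h3 = tr[0][, rate := numeric(0)]
    )
    enr <- if (nrow(pick) > 0) {
      n_extra <- rpois(nrow(pick), pick$rate)
      rows <- rep(seq_len(nrow(pick)), n_extra)
      # point-source model: one binding summit per window (its centre),
      # reads spread around it; keeps the strand peak offset sharp
      summit <- (pick$start[rows] + pick$end[rows]) %/% 2L
      x <- as.integer(round(summit + rnorm(length(rows), 0, cfg$summit_sd)))
      x <- pmin(pmax(x, pick$start[rows]), pick$end[rows] - 1L)
      str <- sample(c("+", "-"), length(rows), replace = TRUE)
      half <- cfg$fragment_size %/% 2L
      data.table(five = fifelse(str == "+", x - half, x + half), strand = str)
    } else data.table(five = integer(0), strand = character(0))

    all5 <- rbind(bg, enr)
    all5[, five := pmin(pmax(five, 0L), genome_bp - 1L)]
    reads <- all5[, .(
      chrom = cfg$chrom,
      start = fifelse(strand == "+", five, five - cfg$read_len + 1L),
      end = fifelse(strand == "+", five + cfg$read_len, five + 1L),
      strand = strand)]
    reads[, start := pmax(start, 0L)]
    new_read_library(reads, name = paste0("sim_", mark),
                     fragment_size = cfg$fragment_size)
  })
}

#' Generate RPKM and microarray-call tables consistent with planted status
#'
#' Silent genes draw RPKM below 0.5 (log-normal near zero) and expressed
#' genes at least 1. A `diff_fraction` of silent genes is planted as
#' differentiation genes (wild-type RPKM >= 1); an `up_extra_fraction` of
#' expressed genes gains at least two-fold in wild type. Microarray calls
#' are Present in all replicates for expressed genes except a
#' `false_absent_rate` fraction flipped to all-Absent; silent genes are
#' all-Absent.
#'
#' @param sim Output of [simulate_annotation()].
#' @return List with `rpkm` (`gene_id`, `rpkm_bam`, `rpkm_wt`), `calls`
#'   (one row per gene, one column per replicate), and `flags` (planted
#'   `differentiation` / `upregulated` / `false_absent` logicals).
#' @export
simulate_expression <- function(sim) {
  cfg <- sim$cfg
  truth <- sim$truth
  with_seed(derive_seed(cfg$seed, "expression"), {
    n <- nrow(truth)
    silent <- truth$expression_truth == "silent"
    rpkm_bam <- numeric(n)
    rpkm_bam[silent] <- pmin(rlnorm(sum(silent), log(0.05), 1), 0.45)
    rpkm_bam[!silent] <- 1 + rlnorm(sum(!silent), log(4), 1)

    is_diff <- silent & (runif(n) < cfg$diff_fraction)
    up_extra <- !silent & (runif(n) < cfg$up_extra_fraction)
    rpkm_wt <- numeric(n)
    rpkm_wt[is_diff] <- 1 + rlnorm(sum(is_diff), log(4), 1)
    rpkm_wt[silent & !is_diff] <- pmin(rlnorm(sum(silent & !is_diff),
                                              log(0.05), 1), 0.45)
    rpkm_wt[up_extra] <- pmax(rpkm_bam[up_extra], 0.5) *
      runif(sum(up_extra), 2, 8)
    rest <- !silent & !up_extra
    rpkm_wt[rest] <- pmax(rpkm_bam[rest], 0.5) * runif(sum(rest), 0.3, 1.9)

    false_absent <- !silent & (runif(n) < cfg$false_absent_rate)
    present <- !silent & !false_absent
    reps <- cfg$n_microarray_replicates
    calls <- data.table(gene_id = truth$gene_id)
    for (r in seq_len(reps))
      calls[, paste0("rep", r) := fifelse(present, "P", "A")]

    list(
      rpkm = data.table(gene_id = truth$gene_id, rpkm_bam = rpkm_bam,
                        rpkm_wt = rpkm_wt),
      calls = calls,
      flags = data.table(gene_id = truth$gene_id,
                         differentiation = flag_differentiation(rpkm_bam, rpkm_wt),
                         upregulated = flag_upregulated(rpkm_bam, rpkm_wt),
                         false_absent = false_absent)
    )
  })
}

#' Write a transcript table as refFlat (11-column genePred)
#'
#' @param tx Transcript table.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_refflat <- function(tx, path) {
  lines <- vapply(seq_len(nrow(tx)), function(i) {
    paste(tx$gene_id[i], tx$transcript_id[i], tx$chrom[i], tx$strand[i],
          tx$tx_start[i], tx$tx_end[i], tx$tx_start[i], tx$tx_end[i],
          length(tx$exon_starts[[i]]),
          paste0(paste(tx$exon_starts[[i]], collapse = ","), ","),
          paste0(paste(tx$exon_ends[[i]], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a read library as BED6
#'
#' @param lib A `read_library`.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_reads_bed <- function(lib, path) {
  bed <- lib$reads[, .(chrom, start, end, name = ".", score = 0L, strand)]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs [simulate_annotation()], [simulate_chip_library()] for the five
#' marks and [simulate_expression()], writing annotation (refFlat), read
#' BEDs, RPKM/call TSVs and the ground-truth table to `dir`.
#'
#' @param cfg A `simulation_config`.
#' @param dir Output directory (created if needed).
#' @param marks Libraries to generate.
#' @return List of the in-memory objects plus a `paths` list.
#' @export
simulate_dataset <- function(cfg, dir,
                             marks = c("polII", "k4", "k27", "k36", "h3")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_annotation(cfg)
  expr <- simulate_expression(sim)
  paths <- list(annotation = file.path(dir, "annotation.refflat"),
                rpkm = file.path(dir, "rpkm.tsv"),
                calls = file.path(dir, "microarray_calls.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_refflat(sim$transcripts, paths$annotation)
  write_tsv(expr$rpkm, paths$rpkm)
  write_tsv(expr$calls, paths$calls)
  truth_out <- merge(sim$truth, expr$flags, by = "gene_id")
  write_tsv(truth_out, paths$truth)
  libs <- list()
  for (mk in marks) {
    libs[[mk]] <- simulate_chip_library(sim, mk)
    paths[[paste0("reads_", mk)]] <- file.path(dir, sprintf("reads_%s.bed", mk))
    write_reads_bed(libs[[mk]], paths[[paste0("reads_", mk)]])
  }
  list(sim = sim, expression = expr, libraries = libs, truth = truth_out,
       chrom_sizes = sim$chrom_sizes, paths = paths)
}
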