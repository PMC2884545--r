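test_that("generation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 5, n_genes = 30, n_multi_isoform = 2)
  a <- simulate_annotation(cfg)
  b <- simulate_annotation(cfg)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_chip_library(a, "k4")$reads,
                   simulate_chip_library(b, "k4")$reads)
  expect_identical(simulate_expression(a)$rpkm, simulate_expression(b)$rpkm)
  # a different seed changes the layout
  c2 <- simulate_annotation(simulation_config(seed = 6, n_genes = 30))
  expect_false(identical(a$transcripts$tx_start[1:30],
                         c2$transcripts$tx_start[1:30]))
})

test_that("planted special cases are recovered exactly by the filter", {
  cfg <- simulation_config(seed = 12, n_genes = 50, n_short_transcripts = 7,
                           n_overlapping_pairs = 4, n_close_tss_pairs = 5,
                           n_multi_isoform = 3)
  sim <- simulate_annotation(cfg)
  es <- filter_transcripts(sim$transcripts)
  tab <- table(es$reason)
  expect_equal(unname(tab[["too_short"]]), 7L)
  expect_equal(unname(tab[["overlap_conflict"]]), 8L)
  expect_equal(unname(tab[["tss_too_close"]]), 10L)
  # all regular and multi-isoform genes survive untouched
  reg <- sim$truth[sim$truth$special %in% c("regular", "multi_isoform"), ]
  ge <- gene_eligibility(es)
  expect_true(all(ge[ge$gene_id %in% reg$gene_id, ]$promoter_eligible))
})

test_that("infeasible packing is rejected with advice", {
  cfg <- simulation_config(seed = 1, n_genes = 100, genome_bp = 10000)
  expect_error(simulate_annotation(cfg), "genome_bp")
})

test_that("expression tables satisfy the planted construction rules", {
  cfg <- simulation_config(seed = 23, n_genes = 400)
  sim <- simulate_annotation(cfg)
  ex <- simulate_expression(sim)
  silent <- sim$truth$expression_truth == "silent"
  expect_true(all(ex$rpkm[silent]$rpkm_bam < 0.5))
  expect_true(all(ex$rpkm[!silent]$rpkm_bam >= 1))
  # planted differentiation genes satisfy the (bam < 0.5, wt >= 1) rule
  d <- ex$flags$differentiation
  expect_true(all(ex$rpkm[d]$rpkm_bam < 0.5 & ex$rpkm[d]$rpkm_wt >= 1))
  # differentiation implies up-regulation
  expect_true(all(ex$flags$upregulated[d]))
})

test_that("microarray false-absent planting is recovered by concordance", {
  cfg <- simulation_config(seed = 31, n_genes = 1000, false_absent_rate = 0.1,
                           expression_mix = c(silent = 0, expressed = 1))
  sim <- simulate_annotation(cfg)
  ex <- simulate_expression(sim)
  cc <- concordance(ex$calls, ex$rpkm)
  expect_equal(cc$n_all_absent, sum(ex$flags$false_absent))
  expect_gt(cc$n_all_absent, 1000 * 0.1 - 3 * sqrt(1000 * 0.1 * 0.9))
  expect_lt(cc$n_all_absent, 1000 * 0.1 + 3 * sqrt(1000 * 0.1 * 0.9))
  expect_equal(cc$frac_absent_expressed, 1)  # every flipped gene is expressed

  cfg0 <- simulation_config(seed = 31, n_genes = 300, false_absent_rate = 0)
  sim0 <- simulate_annotation(cfg0)
  ex0 <- simulate_expression(sim0)
  cc0 <- concordance(ex0$calls, ex0$rpkm)
  expect_equal(cc0$n_all_absent_expressed, 0L)
})

test_that("stalled genes reproduce the planted promoter:body rate ratio", {
  cfg <- simulation_config(seed = 61, n_genes = 600, promoter_body_ratio = 8)
  sim <- simulate_annotation(cfg)
  lib <- simulate_chip_library(sim, "polII")
  dom <- sim$transcripts[match(sim$truth$dominant_transcript,
                               sim$transcripts$transcript_id), ]
  w <- derive_windows(dom)
  stalled <- sim$truth[sim$truth$polII_truth == "stalled", ]$gene_id
  wp <- count_in_windows(lib, w[w$kind == "promoter_polII" &
                                  w$gene_id %in% stalled, ])
  wb <- count_in_windows(lib, w[w$kind == "gene_body" &
                                  w$gene_id %in% stalled, ])
  ratio <- sum(wp$count) / sum(wb$count)
  expect_gt(ratio, 8 * 0.75)
  expect_lt(ratio, 8 * 1.25)
})

test_that("the H3 control library carries no planted enrichment", {
  cfg <- simulation_config(seed = 71, n_genes = 500)
  sim <- simulate_annotation(cfg)
  lib <- deduplicate(simulate_chip_library(sim, "h3"))
  cal <- calibrate_threshold(lib$total_unique, 500,
                             unname(sim$chrom_sizes[[1]]))
  dom <- sim$transcripts[match(sim$truth$dominant_transcript,
                               sim$transcripts$transcript_id), ]
  w <- derive_windows(dom)
  cnt <- count_in_windows(lib, w[w$kind == "promoter_k4k27", ])
  frac_sig <- mean(cnt$count >= cal$threshold_count)
  se <- sqrt(0.05 * 0.95 / nrow(cnt))
  expect_lte(frac_sig, 0.05 + 3 * se)
})

test_that("bivalent genes are enriched in both mark libraries", {
  cfg <- simulation_config(seed = 81, n_genes = 400)
  sim <- simulate_annotation(cfg)
  k4 <- simulate_chip_library(sim, "k4")
  k27 <- simulate_chip_library(sim, "k27")
  dom <- sim$transcripts[match(sim$truth$dominant_transcript,
                               sim$transcripts$transcript_id), ]
  w <- derive_windows(dom)
  wp <- w[w$kind == "promoter_k4k27", ]
  biv <- sim$truth[sim$truth$valency_truth == "bivalent", ]$gene_id
  none <- sim$truth[sim$truth$valency_truth == "neither", ]$gene_id
  m4 <- count_in_windows(k4, wp)
  m27 <- count_in_windows(k27, wp)
  expect_gt(mean(m4[m4$gene_id %in% biv, ]$count),
            3 * mean(m4[m4$gene_id %in% none, ]$count))
  expect_gt(mean(m27[m27$gene_id %in% biv, ]$count),
            3 * mean(m27[m27$gene_id %in% none, ]$count))
})

test_that("dataset files round-trip through the readers", {
  dir <- tempfile()
  cfg <- simulation_config(seed = 91, n_genes = 25, n_multi_isoform = 2)
  ds <- simulate_dataset(cfg, dir, marks = c("k4"))
  tx <- read_transcripts(ds$paths$annotation, "genepred")
  expect_equal(nrow(tx), nrow(ds$sim$transcripts))
  expect_setequal(tx$gene_id, ds$sim$transcripts$gene_id)
  lib <- load_reads(ds$paths$reads_k4)
  expect_equal(nrow(lib$reads), nrow(ds$libraries$k4$reads))
  rp <- read_rpkm_table(ds$paths$rpkm)
  expect_equal(nrow(rp), nrow(ds$truth))
  calls <- read_microarray_calls(ds$paths$calls)
  expect_equal(ncol(calls), 4L)
})
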