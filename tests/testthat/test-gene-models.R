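test_that("genePred and refFlat lines map to transcript models", {
  path <- tempfile(fileext = ".refflat")
  writeLines(c(
    paste("geneA", "tx1", "chr2L", "+", 100, 1100, 100, 1100, 2,
          "100,600,", "400,1100,", sep = "\t"),
    paste("geneA", "tx2", "chr2L", "+", 150, 2100, 150, 2100, 1,
          "150,", "2100,", sep = "\t"),
    paste("geneB", "tx3", "chr2L", "-", 5000, 8000, 5000, 8000, 1,
          "5000,", "8000,", sep = "\t")
  ), path)
  tx <- read_transcripts(path, "genepred")
  expect_equal(nrow(tx), 3L)
  expect_equal(length(unique(tx$gene_id)), 2L)
  t1 <- tx[tx$transcript_id == "tx1"]
  expect_equal(t1$tx_len, 1000L)
  expect_equal(t1$tss, 100L)
  expect_equal(t1$exonic_len, 800L)
  # minus-strand convention: TSS is the end coordinate
  expect_equal(tx[tx$transcript_id == "tx3"]$tss, 8000L)
})

test_that("malformed genePred lines abort with the line number", {
  path <- tempfile()
  writeLines(c(
    paste("g", "t1", "chr2L", "+", 100, 1100, 100, 1100, 1, "100,", "1100,",
          sep = "\t"),
    paste("g", "t2", "chr2L", "+", "oops", 1100, 100, 1100, 1, "100,", "1100,",
          sep = "\t")
  ), path)
  expect_error(read_transcripts(path, "genepred"), "line 2")
})

test_that("records with unknown strand symbols are dropped with a warning", {
  path <- tempfile()
  writeLines(c(
    paste("g1", "t1", "chr2L", "+", 100, 1100, 100, 1100, 1, "100,", "1100,",
          sep = "\t"),
    paste("g2", "t2", "chr2L", ".", 100, 1100, 100, 1100, 1, "100,", "1100,",
          sep = "\t")
  ), path)
  expect_warning(tx <- read_transcripts(path, "genepred"), "strand")
  expect_equal(tx$transcript_id, "t1")
})

test_that("BED12 minus-strand records use the end coordinate as TSS", {
  skip_if_not_installed("rtracklayer")
  path <- tempfile(fileext = ".bed")
  writeLines(paste("chr2L", 999, 3000, "txm", 0, "-", 999, 3000, "0",
                   2, "501,500,", "0,1501,", sep = "\t"), path)
  tx <- read_transcripts(path, "bed12")
  expect_equal(tx$tx_start, 999L)
  expect_equal(tx$tx_end, 3000L)
  expect_equal(tx$tss, 3000L)
  expect_equal(tx$exonic_len, 1001L)
})

test_that("short transcripts are excluded with reason too_short", {
  tx <- make_tx(c("a", "b"), c("gA", "gB"), c(1000, 10000), c(1400, 12000))
  es <- filter_transcripts(tx)
  expect_equal(es[es$transcript_id == "a"]$reason, "too_short")
  expect_false(es[es$transcript_id == "a"]$promoter_eligible)
  expect_true(es[es$transcript_id == "b"]$promoter_eligible)
  expect_true(es[es$transcript_id == "b"]$stalling_eligible)
})

test_that("divergent non-overlapping TSSs under 400 bp apart lose Pol II eligibility", {
  # minus gene ends (TSS) at 10000; plus gene starts (TSS) at 10300
  tx <- make_tx(c("a", "b"), c("gA", "gB"), c(8000, 10300), c(10000, 12300),
                strand = c("-", "+"))
  es <- filter_transcripts(tx)
  expect_true(all(es$tss_too_close))
  expect_equal(es$reason, c("tss_too_close", "tss_too_close"))
  expect_false(any(es$polII_eligible))
  expect_false(any(es$stalling_eligible))
  # the 0..+500 promoter window analysis is unaffected
  expect_true(all(es$promoter_eligible))
  # widening the pair beyond the gap restores eligibility
  tx2 <- make_tx(c("a", "b"), c("gA", "gB"), c(8000, 10450), c(10000, 12450),
                 strand = c("-", "+"))
  expect_true(all(filter_transcripts(tx2)$polII_eligible))
})

test_that("overlapping genes stay eligible when their promoter windows are clear", {
  # convergent overlap: promoters at the outer ends, each window outside
  # the partner's span
  tx <- make_tx(c("a", "b"), c("gA", "gB"), c(0, 1000), c(3000, 4000),
                strand = c("+", "-"))
  es <- filter_transcripts(tx)
  expect_true(all(es$promoter_eligible))
  # nested same-strand overlap: promoter of the inner gene sits inside the
  # outer gene's span -> conflict for both analyses
  tx2 <- make_tx(c("a", "b"), c("gA", "gB"), c(0, 200), c(3000, 3200))
  es2 <- filter_transcripts(tx2)
  expect_false(any(es2$promoter_eligible))
  expect_equal(unique(es2$reason), "overlap_conflict")
})

test_that("filtering is idempotent", {
  cfg <- simulation_config(seed = 11, n_genes = 40, n_short_transcripts = 4,
                           n_overlapping_pairs = 3, n_close_tss_pairs = 3,
                           n_multi_isoform = 3)
  tx <- simulate_annotation(cfg)$transcripts
  es1 <- filter_transcripts(tx)
  surv <- tx[tx$transcript_id %in% es1[is.na(es1$reason), ]$transcript_id]
  es2 <- filter_transcripts(surv)
  expect_true(all(is.na(es2$reason)))
  expect_true(all(es2$promoter_eligible))
})

test_that("filter agrees with a brute-force pairwise oracle", {
  for (sd in c(3, 17)) {
    cfg <- simulation_config(seed = sd, n_genes = 30, n_short_transcripts = 3,
                             n_overlapping_pairs = 2, n_close_tss_pairs = 2,
                             n_multi_isoform = 2)
    tx <- simulate_annotation(cfg)$transcripts
    es <- filter_transcripts(tx)
    bf <- bf_filter(tx)
    m <- merge(as.data.frame(es), bf, by = "transcript_id",
               suffixes = c("", ".bf"))
    for (col in c("too_short", "overlap_k4k27", "overlap_polII",
                  "tss_too_close", "promoter_eligible", "polII_eligible",
                  "stalling_eligible", "k36_eligible")) {
      expect_equal(m[[col]], m[[paste0(col, ".bf")]],
                   info = paste("seed", sd, col))
    }
  }
})

test_that("windows have the defined widths and strand mirroring", {
  tp <- make_tx("p", "gP", 10000, 13000, "+")
  wp <- derive_windows(tp)
  expect_equal(wp[wp$kind == "promoter_k4k27", c(start, end)], c(10000L, 10500L))
  expect_equal(wp[wp$kind == "promoter_polII", c(start, end)], c(9750L, 10250L))
  expect_equal(wp[wp$kind == "gene_body", c(start, end)], c(10500L, 11000L))
  expect_equal(wp[wp$kind == "k36_window", c(start, end)], c(10500L, 11500L))
  tm <- make_tx("m", "gM", 7000, 10000, "-")
  wm <- derive_windows(tm)
  expect_equal(wm[wm$kind == "promoter_k4k27", c(start, end)], c(9500L, 10000L))
  expect_equal(wm[wm$kind == "gene_body", c(start, end)], c(9000L, 9500L))
  expect_equal(wm[wm$kind == "k36_window", c(start, end)], c(8500L, 9500L))
  expect_equal(sort(unique(wp$end - wp$start)), c(500L, 1000L))
})

test_that("window mirror symmetry: strand flip + reflection maps windows onto themselves", {
  L <- 50000L
  for (sd in 1:5) {
    set.seed(sd)
    st <- as.integer(sample(5000:20000, 1))
    len <- as.integer(sample(1600:4000, 1))
    fwd <- make_tx("f", "g", st, st + len, "+")
    rev <- make_tx("f", "g", L - (st + len), L - st, "-")
    wf <- derive_windows(fwd)
    wr <- derive_windows(rev)
    m <- merge(as.data.frame(wf), as.data.frame(wr), by = "kind")
    expect_equal(m$start.x, L - m$end.y)
    expect_equal(m$end.x, L - m$start.y)
  }
})

test_that("short transcripts lack gene-body and K36 windows; promoter truncates at 0", {
  t900 <- make_tx("s", "gS", 2000, 2900, "+")
  w <- derive_windows(t900)
  expect_false(any(w$kind %in% c("gene_body", "k36_window")))
  expect_true(all(c("promoter_polII", "promoter_k4k27") %in% w$kind))
  tedge <- make_tx("e", "gE", 100, 2100, "+")
  expect_warning(we <- derive_windows(tedge), "truncated")
  expect_equal(we[we$kind == "promoter_polII", ]$start, 0L)
})

test_that("dominant transcript selection follows the criterion chains", {
  # single isoform: chosen regardless of counts
  tx1 <- make_tx("only", "g1", 0, 2000)
  expect_equal(select_dominant_transcript(
    tx1, data.table::data.table(transcript_id = "only", polII_prom = 0)
  )$transcript_id, "only")

  # primary criterion: highest Pol II promoter count
  tx2 <- make_tx(c("a", "b"), "g2", c(0, 0), c(2000, 3000))
  cnt2 <- data.table::data.table(transcript_id = c("a", "b"),
                                 polII_prom = c(12, 7),
                                 polII_body = c(0, 99), k4_prom = c(0, 99))
  expect_equal(select_dominant_transcript(tx2, cnt2, "polII_vs_rpkm")$transcript_id, "a")

  # tie on primary -> gene-body count decides (both transcripts > 1 kb)
  cnt3 <- data.table::data.table(transcript_id = c("a", "b"),
                                 polII_prom = c(5, 5),
                                 polII_body = c(2, 9), k4_prom = c(99, 0))
  expect_equal(select_dominant_transcript(tx2, cnt3, "polII_vs_rpkm")$transcript_id, "b")

  # tie everywhere, unequal length -> longest
  cnt4 <- data.table::data.table(transcript_id = c("a", "b"),
                                 polII_prom = c(5, 5), polII_body = c(1, 1),
                                 k4_prom = c(1, 1), k36 = c(0, 0))
  expect_equal(select_dominant_transcript(tx2, cnt4, "polII_vs_rpkm")$transcript_id, "b")

  # k36 chain restricted to transcripts > 1.5 kb
  tx5 <- make_tx(c("a", "b"), "g5", c(0, 0), c(1200, 3000))
  cnt5 <- data.table::data.table(transcript_id = c("a", "b"),
                                 k36 = c(50, 1), k4_prom = c(0, 0))
  expect_equal(select_dominant_transcript(tx5, cnt5, "k36_vs_rpkm")$transcript_id, "b")
  expect_error(select_dominant_transcript(make_tx("a", "g", 0, 1000),
                                          cnt5, "k36_vs_rpkm"), "no eligible")
})

test_that("random tie-break is reproducible and order-invariant", {
  tx <- make_tx(c("a", "b", "c"), "g", c(0, 0, 0), c(2000, 2000, 2000))
  cnt <- data.table::data.table(transcript_id = c("a", "b", "c"),
                                polII_prom = 3, polII_body = 1, k4_prom = 1)
  pick1 <- select_dominant_transcript(tx, cnt, "polII_vs_rpkm", seed = 99)
  pick2 <- select_dominant_transcript(tx, cnt, "polII_vs_rpkm", seed = 99)
  expect_identical(pick1, pick2)
  # permuted input rows give the same choice
  perm <- tx[c(3, 1, 2)]
  pick3 <- select_dominant_transcript(perm, cnt[c(2, 3, 1)], "polII_vs_rpkm",
                                      seed = 99)
  expect_identical(pick1$transcript_id, pick3$transcript_id)
  # a different seed may choose a different isoform but stays in the set
  expect_true(select_dominant_transcript(tx, cnt, "polII_vs_rpkm",
                                         seed = 1)$transcript_id %in%
                c("a", "b", "c"))
})
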