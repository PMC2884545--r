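# End-to-end orchestration: config handling, stage sequencing, report and
# table emission.

default_run_config <- function() {
  list(
    annotation = NULL, annotation_format = "genepred",
    reads = list(),                     # named: polII, k4, k27, k36, h3
    rpkm = NULL, microarray = NULL,
    genome_mappable_bp = 120381546,
    alpha = 0.05,
    count_mode = "five_prime",
    fragment_size = 160L,
    max_copies = 3L,
    min_transcript_len = 500L, tss_gap = 400L,
    active_max = 3, stalled_min = 5,
    silent_below = 0.5, expressed_min = 1, up_fold = 2, up_floor = 0.5,
    seed = 1L,
    outdir = NULL,
    write_wiggle = FALSE, wiggle_bin = 4L,
    islands = FALSE, island_window = list(polII = 200L, k4 = 200L,
                                          k27 = 400L, k36 = 400L),
    island_e_value = 100, island_null = 20L,
    saturation = FALSE, saturation_marks = "polII",
    metaprofile = FALSE, metaprofile_flank = 3000L, metaprofile_bin = 5L
  )
}

#' Run the promoter chromatin-state pipeline
#'
#' Executes every stage on real or synthetic inputs: annotation loading and
#' eligibility filtering, read loading and duplicate capping, per-library
#' Poisson calibration, window counting on the dominant transcript per
#' gene, valency / Pol II / expression classification, quadrant reporting,
#' and (optionally) coverage tracks, island calls, saturation curves and
#' TSS metaprofiles. Every parameter, including seeds and per-library
#' calibration constants, is echoed into the report so a run is fully
#' reproducible from its output directory.
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Required fields: `annotation` (path), `reads` (named list of BED
#'   paths; any of `polII`, `k4`, `k27`, `k36`, `h3`), `rpkm` (TSV with
#'   `gene_id`, `rpkm_bam`, `rpkm_wt`), `outdir`. Defaults for everything
#'   else mirror the analysis constants (alpha 0.05, windows -250..+250 /
#'   0..+500 / +500..+1000 / +500..+1500, stalling cutoffs 3 and 5, RPKM
#'   cutoffs 0.5 and 1 with fold 2).
#' @return Invisibly, the report: a list with `params`, `calibrations`,
#'   `eligibility`, `genes` (per-gene classification), `quadrants`,
#'   `concordance` (when a microarray table is given), `notes` (skipped
#'   stages), and `paths` of all written files. Stages whose inputs are
#'   missing are skipped with an explicit note instead of failing.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  assert_that(!is.null(cfg$annotation), "config: 'annotation' path is required")
  assert_that(!is.null(cfg$outdir), "config: 'outdir' is required")
  assert_that(length(cfg$reads) > 0, "config: at least one read library is required")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  notes <- character(0)
  note <- function(msg) notes <<- c(notes, msg)

  tx <- read_transcripts(cfg$annotation, format = cfg$annotation_format)
  es <- filter_transcripts(tx, min_len = cfg$min_transcript_len,
                           tss_gap = cfg$tss_gap)
  w <- derive_windows(tx)

  libs <- lapply(cfg$reads, function(p)
    deduplicate(load_reads(p, fragment_size = cfg$fragment_size),
                max_copies = cfg$max_copies))
  chrom_sizes <- infer_chrom_sizes(libs)

  # per-library calibration: 500-bp promoter windows, 1-kb H3K36me3 window
  calib_window <- c(polII = 500L, k4 = 500L, k27 = 500L, k36 = 1000L)
  calibs <- list()
  for (mk in intersect(names(libs), names(calib_window))) {
    calibs[[mk]] <- calibrate_threshold(libs[[mk]]$total_unique,
                                        calib_window[[mk]],
                                        cfg$genome_mappable_bp,
                                        alpha = cfg$alpha)
  }

  # transcript-level window counts per mark
  count_for <- function(mk, kinds) {
    if (!mk %in% names(libs)) return(NULL)
    count_in_windows(libs[[mk]], w[kind %in% kinds], mode = cfg$count_mode,
                     fragment = cfg$fragment_size)
  }
  cpol <- count_for("polII", c("promoter_polII", "gene_body"))
  ck4 <- count_for("k4", "promoter_k4k27")
  ck27 <- count_for("k27", "promoter_k4k27")
  ck36 <- count_for("k36", "k36_window")

  tx_counts <- data.table(transcript_id = tx$transcript_id)
  put <- function(src, knd, colname) {
    if (is.null(src)) return()
    m <- src[kind == knd, .(transcript_id, count)]
    tx_counts[m, (colname) := i.count, on = "transcript_id"]
    tx_counts[is.na(get(colname)), (colname) := 0L]
  }
  put(cpol, "promoter_polII", "polII_prom")
  put(cpol, "gene_body", "polII_body")
  put(ck4, "promoter_k4k27", "k4_prom")
  put(ck27, "promoter_k4k27", "k27_prom")
  put(ck36, "k36_window", "k36")

  # dominant transcript per gene, per analysis chain
  gel <- gene_eligibility(es)
  gene_counts <- gel[promoter_eligible == TRUE,
                     .(gene_id, stalling_eligible, k36_eligible)]
  prom_tx <- tx[transcript_id %in% es[promoter_eligible == TRUE, transcript_id]]
  dom_k4 <- select_dominant_transcript(prom_tx, tx_counts, "k4_vs_k27",
                                       seed = cfg$seed)
  add_dom_counts <- function(gene_counts, dom, cols) {
    m <- merge(dom, tx_counts, by = "transcript_id")
    for (cc in cols) {
      if (!cc %in% names(m)) next
      gene_counts[m, (cc) := get(paste0("i.", cc)), on = "gene_id"]
    }
    gene_counts
  }
  gene_counts <- add_dom_counts(gene_counts, dom_k4, c("k4_prom", "k27_prom"))
  pol_tx <- tx[transcript_id %in% es[polII_eligible == TRUE, transcript_id]]
  if (nrow(pol_tx) > 0) {
    dom_pol <- select_dominant_transcript(pol_tx, tx_counts, "polII_vs_rpkm",
                                          seed = cfg$seed)
    gene_counts <- add_dom_counts(gene_counts, dom_pol,
                                  c("polII_prom", "polII_body"))
  }
  k36_tx <- tx[transcript_id %in% es[k36_eligible == TRUE, transcript_id]]
  if (nrow(k36_tx) > 0 && "k36" %in% names(tx_counts)) {
    dom_k36 <- select_dominant_transcript(k36_tx, tx_counts, "k36_vs_rpkm",
                                          seed = cfg$seed)
    gene_counts <- add_dom_counts(gene_counts, dom_k36, "k36")
  }

  expression <- if (!is.null(cfg$rpkm)) read_rpkm_table(cfg$rpkm)
                else data.table(gene_id = gene_counts$gene_id,
                                rpkm_bam = NA_real_, rpkm_wt = NA_real_)
  if (is.null(cfg$rpkm)) note("no RPKM table: expression flags undefined")
  for (mk in c("polII", "k4", "k27", "k36"))
    if (!mk %in% names(libs))
      note(sprintf("no %s library: dependent calls skipped", mk))

  genes <- classify_genes(gene_counts, calibs, expression,
                          active_max = cfg$active_max,
                          stalled_min = cfg$stalled_min)
  quadrants <- quadrant_report(genes)
  # recount check: the summary must reconcile with the per-gene table
  stopifnot(identical(
    quadrants[subset == "all", sum(n)],
    genes[!is.na(valency), .N]))

  conc <- NULL
  if (!is.null(cfg$microarray) && !is.null(cfg$rpkm)) {
    conc <- concordance(read_microarray_calls(cfg$microarray), expression,
                        rpkm_column = "rpkm_bam")
  }

  paths <- list()
  emit <- function(x, file) {
    p <- file.path(cfg$outdir, file)
    write_tsv(x, p)
    paths[[file]] <<- p
  }
  calib_tab <- rbindlist(lapply(names(calibs), function(mk) {
    cal <- calibs[[mk]]
    data.table(mark = mk, total_reads = cal$total_reads,
               window_bp = cal$window_bp, genome_bp = cal$genome_bp,
               lambda = cal$lambda, alpha = cal$alpha,
               threshold_count = cal$threshold_count)
  }))
  emit(calib_tab, "calibration.tsv")
  emit(as.data.table(es), "eligibility.tsv")
  emit(genes, "gene_classification.tsv")
  emit(quadrants, "quadrant_summary.tsv")
  fp <- flatten_params(cfg)
  params_tab <- data.table(param = names(fp),
                           value = unname(unlist(fp)))
  emit(params_tab, "params.tsv")

  if (isTRUE(cfg$write_wiggle)) {
    for (mk in names(libs)) {
      p <- file.path(cfg$outdir, sprintf("coverage_%s.wig", mk))
      write_wiggle(coverage_track(libs[[mk]], bin = cfg$wiggle_bin,
                                  fragment = cfg$fragment_size,
                                  chrom_sizes = chrom_sizes), p)
      paths[[basename(p)]] <- p
    }
  }
  if (isTRUE(cfg$islands)) {
    for (mk in names(libs)) {
      wbp <- cfg$island_window[[mk]]
      if (is.null(wbp)) next
      isl <- call_islands(libs[[mk]],
                          island_params(window_bp = wbp,
                                        e_value = cfg$island_e_value),
                          chrom_sizes, seed = derive_seed(cfg$seed, mk),
                          n_null = cfg$island_null)
      p <- file.path(cfg$outdir, sprintf("islands_%s.bed", mk))
      write_islands_bed(isl, p)
      paths[[basename(p)]] <- p
    }
  }
  if (isTRUE(cfg$saturation)) {
    for (mk in intersect(cfg$saturation_marks, names(libs))) {
      sat <- saturation_curve(libs[[mk]],
                              island_params(window_bp = cfg$island_window[[mk]]),
                              chrom_sizes, seed = derive_seed(cfg$seed, mk),
                              n_null = cfg$island_null)
      emit(sat, sprintf("saturation_%s.tsv", mk))
    }
  }
  if (isTRUE(cfg$metaprofile)) {
    tss_tab <- tx[transcript_id %in% es[promoter_eligible == TRUE,
                                        transcript_id],
                  .(chrom, tss, strand)]
    for (mk in names(libs)) {
      prof <- tss_metaprofile(libs[[mk]], tss_tab,
                              flank = cfg$metaprofile_flank,
                              bin = cfg$metaprofile_bin)
      emit(prof, sprintf("metaprofile_%s.tsv", mk))
    }
  }

  report <- list(params = cfg, calibrations = calibs, eligibility = es,
                 gene_eligibility = gel, genes = genes, quadrants = quadrants,
                 concordance = conc, notes = notes, paths = paths)
  invisible(report)
}

infer_chrom_sizes <- function(libs) {
  sz <- rbindlist(lapply(libs, function(l) l$reads[, .(m = max(end)),
                                                   by = chrom]))
  out <- sz[, .(m = max(m)), by = chrom]
  setNames(out$m, out$chrom)
}

flatten_params <- function(cfg) {
  flat <- list()
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (is.list(v)) {
      for (nm2 in names(v)) flat[[paste(nm, nm2, sep = ".")]] <-
          paste(v[[nm2]], collapse = ",")
    } else flat[[nm]] <- paste(v, collapse = ",")
  }
  flat
}
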