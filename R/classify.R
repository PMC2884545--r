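# Headline gene classifications: H3K4me3/H3K27me3 valency quadrants,
# differentiation and up-regulation flags, Pol II stalling classes, poised
# candidates, quadrant summary reports, and region-to-promoter overlap.

#' Classify promoter valency from the two histone-mark calls
#'
#' @param k4_sig,k27_sig Logical vectors: significant H3K4me3 / H3K27me3
#'   enrichment in the 0..+500 promoter window.
#' @return Factor with levels `k4_only`, `k27_only`, `bivalent`, `neither`.
#' @export
classify_valency <- function(k4_sig, k27_sig) {
  v <- fifelse(k4_sig & k27_sig, "bivalent",
       fifelse(k4_sig, "k4_only",
       fifelse(k27_sig, "k27_only", "neither")))
  factor(v, levels = c("k4_only", "k27_only", "bivalent", "neither"))
}

#' Flag differentiation genes
#'
#' A differentiation gene is silent in the undifferentiated-cell-enriched
#' condition (RPKM < 0.5) and expressed in the differentiated condition
#' (RPKM >= 1).
#'
#' @param rpkm_bam RPKM in the undifferentiated-enriched condition.
#' @param rpkm_wt RPKM in the differentiated (wild-type) condition.
#' @param silent_below Silent cutoff (default 0.5).
#' @param expressed_min Expressed cutoff (default 1).
#' @return Logical vector (`NA` where either RPKM is missing).
#' @export
flag_differentiation <- function(rpkm_bam, rpkm_wt, silent_below = 0.5,
                                 expressed_min = 1) {
  rpkm_bam < silent_below & rpkm_wt >= expressed_min
}

#' Flag up-regulated genes
#'
#' Up-regulated genes gain at least `fold` expression in the differentiated
#' condition; RPKM values below `floor` in the undifferentiated condition
#' are raised to `floor` before forming the ratio, so fully silent genes do
#' not produce infinite fold changes.
#'
#' @inheritParams flag_differentiation
#' @param fold Minimum fold change (default 2).
#' @param floor Denominator floor in RPKM (default 0.5).
#' @return Logical vector.
#' @export
flag_upregulated <- function(rpkm_bam, rpkm_wt, fold = 2, floor = 0.5) {
  rpkm_wt / pmax(rpkm_bam, floor) >= fold
}

#' Pol II stalling index
#'
#' Ratio of Pol II reads in the promoter window (-250..+250) to reads in
#' the gene body window (+500..+1000). The index is `+Inf` when the body
#' count is zero but the promoter count is positive (the limit of the
#' ratio) and `NA` when both counts are zero (no information).
#'
#' @param promoter_count,body_count Non-negative read counts.
#' @return Numeric vector of stalling indices.
#' @export
stalling_index <- function(promoter_count, body_count) {
  assert_that(all(promoter_count >= 0) && all(body_count >= 0),
              "read counts must be non-negative")
  fifelse(body_count > 0, promoter_count / body_count,
          fifelse(promoter_count > 0, Inf, NA_real_))
}

#' Classify Pol II state from stalling index and promoter enrichment
#'
#' Genes without significant promoter Pol II are `none`. Significant genes
#' are `active` (stalling index <= `active_max`), `stalled` (index >=
#' `stalled_min`, including an infinite index from an empty gene body), or
#' `intermediate` for the gap in between, which is reported explicitly
#' rather than silently dropped. A significant gene whose index is
#' undefined (both windows empty cannot occur when significant; `NA` index
#' with significance yields `NA`).
#'
#' @param si Stalling index vector from [stalling_index()].
#' @param significant Logical: significant promoter Pol II enrichment.
#' @param active_max Upper index bound for active Pol II (default 3).
#' @param stalled_min Lower index bound for stalled Pol II (default 5).
#' @return Factor with levels `active`, `intermediate`, `stalled`, `none`.
#' @export
classify_polII <- function(si, significant, active_max = 3, stalled_min = 5) {
  cls <- fifelse(!significant, "none",
         fifelse(is.na(si), NA_character_,
         fifelse(si <= active_max, "active",
         fifelse(si >= stalled_min, "stalled", "intermediate"))))
  factor(cls, levels = c("active", "intermediate", "stalled", "none"))
}

#' Flag candidate poised genes
#'
#' Poised candidates carry significant promoter Pol II while being
#' expressed at very low to undetectable levels (RPKM < 1): polymerase is
#' recruited but the gene is not productively transcribed.
#'
#' @param significant Logical: significant promoter Pol II enrichment.
#' @param rpkm RPKM in the assayed condition.
#' @param expressed_min Expressed cutoff (default 1).
#' @return Logical vector.
#' @export
flag_poised <- function(significant, rpkm, expressed_min = 1) {
  significant & rpkm < expressed_min
}

#' Assemble per-gene chromatin records
#'
#' Joins per-gene window counts with the per-library calibrations and an
#' expression table into the full gene-level classification: enrichment
#' calls per mark, stalling index, Pol II class, valency, and the
#' differentiation / up-regulation / poised flags.
#'
#' @param counts `data.table` with one row per gene: `gene_id`, and count
#'   columns among `polII_prom`, `polII_body`, `k4_prom`, `k27_prom`,
#'   `k36`; missing marks yield `NA` calls. Optional logical columns
#'   `stalling_eligible` / `k36_eligible` gate the corresponding fields.
#' @param calibs Named list of `library_calibration` objects with entries
#'   among `polII`, `k4`, `k27`, `k36`.
#' @param expression `data.table` with `gene_id`, `rpkm_bam`, `rpkm_wt`.
#' @param active_max,stalled_min Stalling-index class bounds.
#' @return `data.table`, one row per gene, with `*_count`, `*_sig` and
#'   `*_p` per mark, `si`, `polII_class`, `valency`, `differentiation`,
#'   `upregulated`, `poised`.
#' @export
classify_genes <- function(counts, calibs, expression,
                           active_max = 3, stalled_min = 5) {
  rec <- copy(as.data.table(counts))
  marks <- list(polII = "polII_prom", k4 = "k4_prom", k27 = "k27_prom",
                k36 = "k36")
  for (mk in names(marks)) {
    col <- marks[[mk]]
    if (col %in% names(rec) && mk %in% names(calibs)) {
      cal <- calibs[[mk]]
      rec[, paste0(mk, "_p") := window_pvalue(get(col), cal)]
      rec[, paste0(mk, "_sig") := get(col) >= cal$threshold_count]
    } else {
      rec[, paste0(mk, "_p") := NA_real_]
      rec[, paste0(mk, "_sig") := NA]
    }
  }
  if (!"stalling_eligible" %in% names(rec)) rec[, stalling_eligible := TRUE]
  if (all(c("polII_prom", "polII_body") %in% names(rec))) {
    rec[, si := fifelse(stalling_eligible,
                        stalling_index(polII_prom, polII_body), NA_real_)]
  } else rec[, si := NA_real_]
  rec[, polII_class := classify_polII(si, polII_sig, active_max, stalled_min)]
  rec[stalling_eligible == FALSE, polII_class := factor(NA, levels = levels(polII_class))]
  rec[, valency := classify_valency(k4_sig, k27_sig)]
  ex <- as.data.table(expression)
  rec <- merge(rec, ex[, .(gene_id, rpkm_bam, rpkm_wt)], by = "gene_id",
               all.x = TRUE)
  rec[, differentiation := flag_differentiation(rpkm_bam, rpkm_wt)]
  rec[, upregulated := flag_upregulated(rpkm_bam, rpkm_wt)]
  rec[, poised := flag_poised(polII_sig, rpkm_bam)]
  rec[]
}

#' Quadrant summary of valency calls
#'
#' Counts genes per valency quadrant -- overall and restricted to the
#' differentiation and up-regulated subsets -- with percentages formatted
#' round-half-up to `digits` decimals. Counts always reconcile with the
#' per-gene table by construction.
#'
#' @param records Output of [classify_genes()] (needs `valency`,
#'   `differentiation`, `upregulated`).
#' @param digits Decimal places for percentages (default 1).
#' @return `data.table` with one row per `(subset, valency)` combination:
#'   `n`, `total`, `percent`.
#' @export
quadrant_report <- function(records, digits = 1) {
  rec <- as.data.table(records)[!is.na(valency)]
  one <- function(d, label) {
    tot <- nrow(d)
    tab <- d[, .(n = .N), by = valency]
    tab <- merge(data.table(valency = factor(levels(rec$valency),
                                             levels = levels(rec$valency))),
                 tab, by = "valency", all.x = TRUE)
    tab[is.na(n), n := 0L]
    tab[, `:=`(subset = label, total = tot,
               percent = if (tot > 0) percent_of(n, tot, digits) else NA_real_)]
    tab
  }
  out <- rbindlist(list(
    one(rec, "all"),
    one(rec[differentiation == TRUE], "differentiation"),
    one(rec[upregulated == TRUE], "upregulated")
  ))
  setcolorder(out, c("subset", "valency", "n", "total", "percent"))
  out[]
}

#' Genes whose promoter window overlaps any of a set of regions
#'
#' Utility for comparing external enriched regions (e.g. from tiling-array
#' experiments) with the gene set: returns the genes whose 0..+500 promoter
#' window intersects at least one region.
#'
#' @param regions `data.table` with `chrom`, `start`, `end` (half-open).
#' @param windows Window table from [derive_windows()]; only
#'   `promoter_k4k27` rows are used.
#' @return Character vector of hit `gene_id`s.
#' @export
region_overlap <- function(regions, windows) {
  w <- as.data.table(windows)
  if ("kind" %in% names(w)) w <- w[kind == "promoter_k4k27"]
  if (nrow(regions) == 0L || nrow(w) == 0L) return(character(0))
  r <- as.data.table(regions)[, .(chrom, s = start, e = end - 1L)]
  setkey(r, chrom, s, e)
  q <- w[, .(gene_id, chrom, s = start, e = end - 1L)]
  hits <- foverlaps(q, r, type = "any", nomatch = NULL)
  sort(unique(hits$gene_id))
}
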