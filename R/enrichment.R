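# Poisson calibration of window read-count significance and per-window
# enrichment calls.

#' Calibrate the Poisson significance threshold for a library
#'
#' The null model distributes the library's reads uniformly over the
#' mappable genome, so the read count of a fixed `window_bp` window is
#' Poisson with mean `lambda = total * window_bp / genome_bp`. The
#' enrichment threshold is the minimal count `n` in `count_range` whose
#' exact upper-tail probability `P(X >= n)` is at most `alpha`.
#'
#' @param total Total (unique, post-deduplication) read count of the library.
#' @param window_bp Window width in bp.
#' @param genome_bp Mappable genome length in bp. The default,
#'   120,381,546 bp, is the summed length of the major fly euchromatic
#'   chromosome arms (2L, 2R, 3L, 3R, X, 4).
#' @param alpha Per-window significance level (default 0.05).
#' @param count_range Candidate thresholds (default 1..99).
#' @return A `library_calibration`: list with `total_reads`, `genome_bp`,
#'   `window_bp`, `lambda`, `alpha`, `threshold_count` and `pvalue_table`
#'   (a `data.table` of `count` and upper-tail `p_value` over
#'   `0..max(count_range)`).
#' @examples
#' cal <- calibrate_threshold(1342075, 500, 120381546)
#' cal$threshold_count          # 11
#' round(window_pvalue(11, cal), 2)  # 0.03
#' @export
calibrate_threshold <- function(total, window_bp,
                                genome_bp = 120381546, alpha = 0.05,
                                count_range = 1:99) {
  assert_that(total > 0, "total read count must be positive")
  assert_that(genome_bp > window_bp, "genome_bp must exceed window_bp")
  lambda <- total * window_bp / genome_bp
  counts <- 0:max(count_range)
  tail_p <- poisson_tail(counts, lambda)
  ok <- count_range[tail_p[count_range + 1L] <= alpha]
  if (length(ok) == 0L)
    stop(sprintf("no count in %d..%d reaches alpha=%g (lambda=%.3f); extend count_range",
                 min(count_range), max(count_range), alpha, lambda), call. = FALSE)
  structure(list(
    total_reads = total, genome_bp = genome_bp, window_bp = window_bp,
    lambda = lambda, alpha = alpha, threshold_count = min(ok),
    pvalue_table = data.table(count = counts, p_value = tail_p)
  ), class = "library_calibration")
}

#' @export
print.library_calibration <- function(x, ...) {
  cat(sprintf(paste0("<library_calibration> %s reads over %s bp, %d-bp window\n",
                     "  lambda=%.4f  alpha=%g  threshold=%d reads ",
                     "(P(X>=thr)=%.4g)\n"),
              format(x$total_reads, big.mark = ","),
              format(x$genome_bp, big.mark = ","), x$window_bp,
              x$lambda, x$alpha, x$threshold_count,
              poisson_tail(x$threshold_count, x$lambda)))
  invisible(x)
}

# Exact Poisson upper tail P(X >= n), vectorized over n; computed via the
# complementary CDF (log-space internally), not a normal approximation.
poisson_tail <- function(n, lambda) {
  p <- ppois(n - 1, lambda, lower.tail = FALSE)
  p[n <= 0] <- 1
  p
}

#' Upper-tail Poisson probability of a window count
#'
#' `P(X >= n)` under a library's calibrated background rate.
#'
#' @param n Observed read count(s) in the window.
#' @param calib A `library_calibration` from [calibrate_threshold()].
#' @return Probability vector, `1` at `n = 0`.
#' @export
window_pvalue <- function(n, calib) {
  poisson_tail(n, calib$lambda)
}

#' Call enrichment for window read counts
#'
#' A window is significantly enriched when its count reaches the library's
#' calibrated threshold; equivalently when its upper-tail probability is at
#' most `alpha`. No multiple-testing correction is applied: this is the
#' per-window `P < 0.05` convention, and reporting layers carry the number
#' of windows tested for transparency.
#'
#' @param count Read count(s).
#' @param calib A `library_calibration`.
#' @return `data.table` with `count`, `p_value`, `significant`.
#' @export
call_enrichment <- function(count, calib) {
  data.table(count = count,
             p_value = window_pvalue(count, calib),
             significant = count >= calib$threshold_count)
}

#' Depth- and width-normalized window signal
#'
#' Rescales a window count to reads per 1-kb window per 1 million total
#' reads, the scale used for cross-library scatter plots.
#'
#' @param count Read count(s).
#' @param total Library total read count.
#' @param window_bp Window width in bp.
#' @return Normalized signal.
#' @export
normalized_signal <- function(count, total, window_bp) {
  assert_that(total > 0, "total read count must be positive")
  count * (1000 / window_bp) * (1e6 / total)
}
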