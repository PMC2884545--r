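# Window-based island calling against a Poisson background with a seeded
# Monte-Carlo score null, and sequencing-depth saturation by subsampling.

#' Island-calling parameters
#'
#' @param window_bp Tiling window width in bp. 200 bp suits Pol II and
#'   H3K4me3 point enrichment; 400 bp the broader H3K27me3/H3K36me3
#'   domains.
#' @param gap_bp Allowed gap between eligible windows; 0 by default because
#'   in a gene-dense genome any gap would fuse neighbouring genes' signals.
#'   Only 0 is implemented.
#' @param e_value Expected number of islands tolerated under the null.
#' @param eligibility_p Poisson upper-tail probability below which a single
#'   window is eligible for island membership (default 0.2).
#' @return An `island_params` list.
#' @export
island_params <- function(window_bp = 200L, gap_bp = 0L, e_value = 100,
                          eligibility_p = 0.2) {
  assert_that(gap_bp == 0L, "only gap_bp = 0 is supported")
  assert_that(e_value > 0, "e_value must be positive")
  structure(list(window_bp = as.integer(window_bp), gap_bp = 0L,
                 e_value = e_value, eligibility_p = eligibility_p),
            class = "island_params")
}

# Islands from a vector of 5' positions on one virtual chromosome.
# Returns data.table(start_win, end_win, score, n_windows) of candidate
# (pre-threshold) islands; windows are window_bp-multiples.
candidate_islands <- function(pos, n_windows_total, window_bp, lambda,
                              min_count) {
  cnt <- tabulate(pos %/% window_bp + 1L, nbins = n_windows_total)
  elig <- cnt >= min_count
  if (!any(elig)) return(data.table(start_win = integer(0), end_win = integer(0),
                                    score = numeric(0), n_windows = integer(0)))
  r <- rle(elig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  sw <- starts[keep]; ew <- ends[keep]
  run_of <- integer(n_windows_total)
  run_of[elig] <- rep(seq_along(sw), ew - sw + 1L)
  wscore <- -dpois(cnt[elig], lambda, log = TRUE)
  agg <- rowsum(wscore, group = run_of[elig])
  data.table(start_win = sw - 1L, end_win = ew, score = as.numeric(agg),
             n_windows = ew - sw + 1L)
}

#' Call enriched islands against a Poisson background
#'
#' Tiles each chromosome with non-overlapping `window_bp` windows, marks a
#' window eligible when its read count exceeds the Poisson background
#' eligibility threshold, merges adjacent eligible windows (no gaps) into
#' candidate islands, and scores each island as the sum over member windows
#' of `-ln P(count | lambda)`. The score threshold is set empirically: the
#' same number of reads is placed uniformly over the genome `n_null` times
#' (seeded), and islands are retained when the expected number of
#' equal-or-higher-scoring null islands is at most `e_value`.
#'
#' @param lib A deduplicated `read_library`.
#' @param params An `island_params` object.
#' @param chrom_sizes Named integer vector of chromosome lengths covering
#'   every chromosome present in the library.
#' @param seed Integer seed for the Monte-Carlo null.
#' @param n_null Number of null placements (default 20).
#' @return `data.table` of islands: `chrom`, `start`, `end` (half-open,
#'   multiples of `window_bp`, clipped to the chromosome length), `score`,
#'   `n_windows`.
#' @export
call_islands <- function(lib, params, chrom_sizes, seed = 1L, n_null = 20L) {
  assert_that(!is.null(names(chrom_sizes)) && all(nzchar(names(chrom_sizes))),
              "chrom_sizes must be a named vector")
  r <- lib$reads
  missing_ch <- setdiff(unique(r$chrom), names(chrom_sizes))
  assert_that(length(missing_ch) == 0,
              "unknown chromosome length for: %s", paste(missing_ch, collapse = ","))
  genome_bp <- sum(as.numeric(chrom_sizes))
  wbp <- params$window_bp
  if (nrow(r) == 0L)
    return(data.table(chrom = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      n_windows = integer(0)))
  lambda <- nrow(r) * wbp / genome_bp
  min_count <- eligibility_count(lambda, params$eligibility_p)

  cand <- rbindlist(lapply(names(chrom_sizes), function(ch) {
    pos <- r[chrom == ch, five_prime]
    if (length(pos) == 0L) return(NULL)
    nw <- as.integer(ceiling(chrom_sizes[[ch]] / wbp))
    ci <- candidate_islands(pmin(pmax(pos, 0L), chrom_sizes[[ch]] - 1L),
                            nw, wbp, lambda, min_count)
    if (nrow(ci) == 0L) return(NULL)
    ci[, chrom := ch]
    ci
  }))
  if (is.null(cand) || nrow(cand) == 0L)
    return(data.table(chrom = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      n_windows = integer(0)))

  null_scores <- with_seed(seed, {
    nwg <- as.integer(ceiling(genome_bp / wbp))
    unlist(lapply(seq_len(n_null), function(i) {
      np <- floor(runif(nrow(r), 0, genome_bp))
      candidate_islands(np, nwg, wbp, lambda, min_count)$score
    }), use.names = FALSE)
  })
  # expected number of null islands scoring >= s, per placement
  null_sorted <- sort(null_scores)
  e_of <- function(s) (length(null_sorted) -
                         findInterval(s - 1e-12, null_sorted)) / n_null
  keep <- vapply(cand$score, e_of, numeric(1)) <= params$e_value
  out <- cand[keep]
  out[, `:=`(start = start_win * wbp, end = pmin(end_win * wbp,
             as.integer(chrom_sizes[chrom])))]
  setorder(out, chrom, start)
  out[, .(chrom, start, end, score, n_windows)]
}

# Minimal window count whose Poisson upper tail is <= p0.
eligibility_count <- function(lambda, p0) {
  n <- qpois(p0, lambda, lower.tail = FALSE) + 1L
  while (n > 1L && poisson_tail(n - 1L, lambda) <= p0) n <- n - 1L
  max(n, 1L)
}

#' Write islands as a BED file
#'
#' @param islands Output of [call_islands()].
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_islands_bed <- function(islands, path) {
  bed <- islands[, .(chrom, start, end,
                     name = sprintf("island_%d", .I),
                     score = round(score, 2))]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sequencing-depth saturation of island discovery
#'
#' Shuffles the library once (seeded), then takes cumulative subsamples at
#' the given `fractions` of the total unique reads and calls islands in
#' each subsample, with the expected-island tolerance growing along
#' `e_schedule` so the null allowance scales with the subsample. A library
#' sequenced to saturation shows the island count rising and then
#' plateauing as the fraction approaches 1.
#'
#' @param lib A deduplicated `read_library`.
#' @param params An `island_params` object (its `e_value` is overridden by
#'   the schedule).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param fractions Increasing subsample fractions in (0, 1]; default 2.5%
#'   steps up to 100%.
#' @param e_start,e_step E-value schedule: subsample `i` uses
#'   `e_start + (i-1) * e_step` (default 3, 6, ..., 120 over 40 fractions).
#' @param seed Integer seed (shuffling and the per-subsample nulls).
#' @param n_null Null placements per subsample (default 20).
#' @return `data.table` with `fraction`, `e_value`, `n_reads`, `n_islands`.
#' @export
saturation_curve <- function(lib, params, chrom_sizes,
                             fractions = seq(0.025, 1, by = 0.025),
                             e_start = 3, e_step = 3, seed = 1L,
                             n_null = 20L) {
  e_schedule <- e_start + (seq_along(fractions) - 1) * e_step
  assert_that(length(e_schedule) == length(fractions),
              "E-value schedule and fraction list lengths differ")
  assert_that(!is.unsorted(fractions, strictly = TRUE) &&
                all(fractions > 0) && all(fractions <= 1),
              "fractions must be strictly increasing in (0, 1]")
  n <- nrow(lib$reads)
  perm <- with_seed(derive_seed(seed, "shuffle"), sample.int(n))
  res <- lapply(seq_along(fractions), function(i) {
    k <- max(1L, as.integer(round(fractions[i] * n)))
    sub <- new_read_library(lib$reads[perm[seq_len(k)]], name = lib$name,
                            fragment_size = lib$fragment_size,
                            deduplicated = lib$deduplicated, total_unique = k)
    p <- params
    p$e_value <- e_schedule[i]
    isl <- call_islands(sub, p, chrom_sizes,
                        seed = derive_seed(seed, paste0("null", i)),
                        n_null = n_null)
    data.table(fraction = fractions[i], e_value = e_schedule[i],
               n_reads = k, n_islands = nrow(isl))
  })
  rbindlist(res)
}
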