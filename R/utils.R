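# Shared internal helpers: seeded RNG scopes, percent formatting, TSV I/O.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded components (tie-breaks, Monte-Carlo nulls) never
#' perturb user-level random streams.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a child seed from a base seed and a label, staying below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483587)
}

#' Format a count pair as a percentage, round-half-up
#'
#' Percentages are reported the way genome-scale gene tallies are usually
#' printed: round-half-up at the requested number of decimals (so 4.85 -> 4.9
#' and 94.71 -> 95 at zero decimals), never banker's rounding.
#'
#' @param num Numerator count(s).
#' @param den Denominator count(s).
#' @param digits Decimal places (0 gives integer percentages).
#' @return Numeric percentage(s) on the 0-100 scale.
#' @examples
#' percent_of(63, 1304)    # 4.8
#' percent_of(3796, 4008, digits = 0)  # 95
#' @export
percent_of <- function(num, den, digits = 1) {
  stopifnot(all(den > 0 | (den == 0 & num == 0)))
  x <- 100 * num / den
  x[x == Inf | is.nan(x)] <- NA_real_
  f <- 10^digits
  floor(x * f + 0.5) / f
}

# Write a data.frame/data.table as a TSV (no quoting, no row names).
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# Running mean with odd-ish window `k` (bp); pads edges by shrinking window.
running_mean <- function(x, k) {
  if (k <= 1L) return(x)
  kern <- rep(1 / k, k)
  y <- stats::filter(x, kern, sides = 2)
  y[is.na(y)] <- x[is.na(y)]
  as.numeric(y)
}

# stopifnot with a formatted message
assert_that <- function(ok, msg, ...) {
  if (!isTRUE(ok)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}
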