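# Aligned-read ingestion (BED), PCR-duplicate capping, fragment-size
# estimation from the strand peak offset, coverage tracks, window counting
# and TSS metaprofiles.

#' Load aligned reads from a BED file
#'
#' Reads a BED file (6 or more columns; strand in column 6 is required,
#' because fragment-size estimation and 5'-position assignment depend on
#' it) into a `read_library` object. Reads are sorted by `(chrom, start)`
#' and annotated with their 5' position (`start` on the plus strand,
#' `end - 1` on the minus strand).
#'
#' @param path BED file path.
#' @param name Library name (defaults to the file name).
#' @param fragment_size Assumed DNA fragment size in bp (default 160; can be
#'   re-estimated with [estimate_fragment_size()]).
#' @return A `read_library`: a list with `name`, `reads` (a `data.table`
#'   with `chrom`, `start`, `end`, `strand`, `five_prime`), `total_unique`
#'   (set after [deduplicate()]; `NA` until then), `fragment_size` and a
#'   `deduplicated` flag.
#' @export
load_reads <- function(path, name = basename(path), fragment_size = 160L) {
  assert_that(file.exists(path), "BED file not found: %s", path)
  bed <- fread(path, header = FALSE, sep = "\t")
  assert_that(ncol(bed) >= 6L,
              "BED file %s has %d columns; strand (column 6) is required",
              path, ncol(bed))
  reads <- bed[, .(chrom = as.character(V1), start = as.integer(V2),
                   end = as.integer(V3), strand = as.character(V6))]
  assert_that(all(reads$strand %in% c("+", "-")),
              "BED file %s: strand column contains symbols other than +/-", path)
  assert_that(all(reads$start < reads$end), "BED file %s: start >= end", path)
  new_read_library(reads, name = name, fragment_size = fragment_size)
}

# Construct a read_library from an in-memory read table.
new_read_library <- function(reads, name = "library", fragment_size = 160L,
                             deduplicated = FALSE, total_unique = NA_integer_) {
  reads <- as.data.table(reads)
  reads[, five_prime := fifelse(strand == "+", start, end - 1L)]
  setorder(reads, chrom, start, end, strand)
  structure(list(name = name, reads = reads,
                 total_unique = total_unique,
                 fragment_size = as.integer(fragment_size),
                 deduplicated = deduplicated),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("<read_library> %s: %d reads (%s), fragment_size=%d\n",
              x$name, nrow(x$reads),
              if (x$deduplicated) sprintf("deduplicated, %d unique", x$total_unique)
              else "not deduplicated",
              x$fragment_size))
  invisible(x)
}

#' Cap PCR duplicates
#'
#' For each identical alignment key `(chrom, start, end, strand)` at most
#' `max_copies` reads are retained, limiting PCR-amplification bias.
#' Opposite-strand reads at one position are distinct fragments and are
#' never collapsed together.
#'
#' @param lib A `read_library`.
#' @param max_copies Maximum retained copies per key (default 3).
#' @return The deduplicated `read_library` with `total_unique` set.
#' @export
deduplicate <- function(lib, max_copies = 3L) {
  r <- copy(lib$reads)
  r[, n_copies := seq_len(.N), by = .(chrom, start, end, strand)]
  r <- r[n_copies <= max_copies][, n_copies := NULL]
  new_read_library(r, name = lib$name, fragment_size = lib$fragment_size,
                   deduplicated = TRUE, total_unique = nrow(r))
}

#' Estimate the DNA fragment size from the strand peak offset
#'
#' ChIP fragments are sequenced from their ends, so plus-strand 5' positions
#' pile up one half fragment upstream of binding sites and minus-strand 5'
#' positions one half fragment downstream. The fragment size is the shift of
#' the minus-strand 5'-position density that best matches the plus-strand
#' density, found by cross-correlation over `0..max_shift` bp after
#' `smoothing_bp` running-mean smoothing.
#'
#' @param lib A `read_library` with reads on both strands.
#' @param smoothing_bp Running-mean window applied to the cross-correlation
#'   profile (default 10 bp).
#' @param max_shift Largest shift searched (default 500 bp).
#' @return Estimated fragment size in bp.
#' @export
estimate_fragment_size <- function(lib, smoothing_bp = 10L, max_shift = 500L) {
  r <- lib$reads
  assert_that(any(r$strand == "+") && any(r$strand == "-"),
              "fragment-size estimation requires reads on both strands")
  shifts <- 0:max_shift
  cc <- numeric(length(shifts))
  for (ch in unique(r$chrom)) {
    rc <- r[chrom == ch]
    plus <- rc[strand == "+", five_prime]
    minus <- rc[strand == "-", five_prime]
    if (length(plus) == 0L || length(minus) == 0L) next
    lo <- min(plus, minus); hi <- max(plus, minus)
    m <- integer(hi - lo + 1L + max_shift)
    tb <- table(minus - lo + 1L)
    m[as.integer(names(tb))] <- as.integer(tb)
    p_idx <- plus - lo + 1L
    for (k in seq_along(shifts)) cc[k] <- cc[k] + sum(m[p_idx + shifts[k]])
  }
  assert_that(sum(cc) > 0, "no plus/minus read pairs within %d bp", max_shift)
  cc_s <- running_mean(cc, smoothing_bp)
  shifts[which.max(cc_s)]
}

#' Build a binned fragment coverage track
#'
#' Each read is extended from its 5' end to the fragment size in its
#' orientation; per-bin counts of overlapping extended fragments form the
#' track (the wiggle-file convention for ChIP-seq browser display).
#'
#' @param lib A `read_library` (deduplicate first).
#' @param bin Bin width in bp (default 4).
#' @param fragment Fragment extension length in bp (default the library's
#'   `fragment_size`).
#' @param chrom_sizes Named integer vector of chromosome lengths; fragments
#'   extending past a chromosome end are clipped. Defaults to the furthest
#'   read end per chromosome.
#' @return Named list (per chromosome) of integer vectors of per-bin
#'   fragment counts; bin `i` covers `[(i-1)*bin, i*bin)`. The `bin` width
#'   is attached as an attribute.
#' @export
coverage_track <- function(lib, bin = 4L, fragment = lib$fragment_size,
                           chrom_sizes = NULL) {
  r <- lib$reads
  out <- list()
  for (ch in unique(r$chrom)) {
    rc <- r[chrom == ch]
    fs <- fifelse(rc$strand == "+", rc$five_prime,
                  rc$five_prime - fragment + 1L)
    fe <- fs + fragment
    size <- if (!is.null(chrom_sizes)) chrom_sizes[[ch]] else max(fe)
    fs <- pmax(fs, 0L); fe <- pmin(fe, size)
    keep <- fs < fe
    fs <- fs[keep]; fe <- fe[keep]
    nb <- as.integer(ceiling(size / bin))
    delta <- integer(nb + 1L)
    sb <- fs %/% bin + 1L
    eb <- (fe - 1L) %/% bin + 1L
    add <- tabulate(sb, nbins = nb + 1L)
    sub <- tabulate(eb + 1L, nbins = nb + 1L)
    out[[ch]] <- cumsum(add - sub)[seq_len(nb)]
  }
  attr(out, "bin") <- as.integer(bin)
  out
}

#' Write a coverage track as a fixedStep wiggle file
#'
#' @param track Output of [coverage_track()].
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_wiggle <- function(track, path) {
  bin <- attr(track, "bin")
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track)) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       ch, bin, bin), con)
    writeLines(format(track[[ch]], trim = TRUE, scientific = FALSE), con)
  }
  invisible(path)
}

# Strand-aware read assignment position.
read_positions <- function(lib, mode = c("five_prime", "midpoint"),
                           fragment = lib$fragment_size) {
  mode <- match.arg(mode)
  r <- lib$reads
  if (mode == "five_prime") r$five_prime
  else fifelse(r$strand == "+", r$five_prime + fragment %/% 2L,
               r$five_prime - fragment %/% 2L)
}

#' Count reads falling in analysis windows
#'
#' Each read is reduced to a single assignment position -- its 5' end
#' (default) or, in `midpoint` mode, the strand-aware centre of the
#' fragment-extended read -- and counted into every window containing that
#' position.
#'
#' @param lib A `read_library`.
#' @param windows `data.table` with `chrom`, `start`, `end` (half-open) and
#'   any identifier columns (e.g. from [derive_windows()]).
#' @param mode `"five_prime"` or `"midpoint"`.
#' @param fragment Fragment size for midpoint mode.
#' @return A copy of `windows` with a `count` column appended.
#' @export
count_in_windows <- function(lib, windows, mode = c("five_prime", "midpoint"),
                             fragment = lib$fragment_size) {
  mode <- match.arg(mode)
  w <- copy(as.data.table(windows))
  assert_that(all(w$start <= w$end), "window with start > end")
  pos <- data.table(chrom = lib$reads$chrom,
                    pos = read_positions(lib, mode, fragment))
  pos[, `:=`(s = pos, e = pos)]
  w[, window_id := .I]
  q <- w[, .(window_id, chrom, s = start, e = end - 1L)]
  q <- q[s <= e]
  setkey(pos, chrom, s, e)
  hits <- foverlaps(q, pos, type = "any", nomatch = NULL)
  cnt <- hits[, .N, by = window_id]
  w[, count := 0L]
  w[cnt$window_id, count := cnt$N]
  w[, window_id := NULL]
  w[]
}

#' Count reads in one genomic window
#'
#' @param lib A `read_library`.
#' @param chrom Chromosome name.
#' @param start,end Half-open window coordinates.
#' @inheritParams count_in_windows
#' @return Integer read count.
#' @export
count_in_window <- function(lib, chrom, start, end,
                            mode = c("five_prime", "midpoint"),
                            fragment = lib$fragment_size) {
  w <- data.table(chrom = chrom, start = as.integer(start), end = as.integer(end))
  count_in_windows(lib, w, mode = match.arg(mode), fragment = fragment)$count
}

#' Average read density around TSSs
#'
#' Computes a strand-oriented metaprofile: read 5' positions are expressed
#' relative to each TSS (minus-strand profiles are mirrored before
#' averaging), binned, and averaged over the supplied gene group.
#'
#' @param lib A `read_library`.
#' @param tss `data.table` with `chrom`, `tss` (bp) and `strand`.
#' @param flank Half-width of the profiled region in bp.
#' @param bin Bin width in bp (default 5).
#' @return `data.table` with `rel_start` (bin start relative to the TSS,
#'   oriented) and `density` (mean reads per bin per gene).
#' @export
tss_metaprofile <- function(lib, tss, flank, bin = 5L) {
  assert_that(nrow(tss) >= 1L, "at least one TSS is required")
  assert_that(flank > 0, "flank must be positive")
  tssdt <- as.data.table(tss)
  pos <- data.table(chrom = lib$reads$chrom, pos = lib$reads$five_prime)
  pos[, `:=`(s = pos, e = pos)]
  setkey(pos, chrom, s, e)
  q <- tssdt[, .(chrom, strand, tss, s = tss - flank, e = tss + flank - 1L)]
  hits <- foverlaps(q, pos, type = "any", nomatch = NULL)
  hits[, rel := fifelse(strand == "+", pos - tss, tss - pos)]
  breaks <- seq(-flank, flank, by = bin)
  rel_bin <- breaks[findInterval(hits$rel, breaks, rightmost.closed = FALSE)]
  counts <- as.data.table(table(factor(rel_bin, levels = head(breaks, -1))))
  setnames(counts, c("rel_start", "density"))
  counts[, rel_start := as.integer(as.character(rel_start))]
  counts[, density := as.numeric(density) / nrow(tssdt)]
  counts[]
}
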