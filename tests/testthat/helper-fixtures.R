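# Shared fixture builders and independent oracles.

# Build a transcript table by hand (single-exon transcripts).
make_tx <- function(transcript_id, gene_id, tx_start, tx_end,
                    strand = "+", chrom = "chr2L") {
  n <- length(transcript_id)
  dt <- data.table::data.table(
    transcript_id = transcript_id,
    gene_id = rep_len(gene_id, n),
    chrom = rep_len(chrom, n),
    strand = rep_len(strand, n),
    tx_start = as.integer(tx_start),
    tx_end = as.integer(tx_end),
    exon_starts = as.list(as.integer(tx_start)),
    exon_ends = as.list(as.integer(tx_end))
  )
  dt[, tx_len := tx_end - tx_start]
  dt[, exonic_len := tx_len]
  dt[, tss := data.table::fifelse(strand == "+", tx_start, tx_end)]
  dt[]
}

# Minimal in-memory read library from 5' positions.
make_lib <- function(five_prime, strand, chrom = "chr2L", read_len = 25L,
                     fragment_size = 160L, deduplicated = FALSE) {
  five_prime <- as.integer(five_prime)
  reads <- data.table::data.table(
    chrom = rep_len(chrom, length(five_prime)),
    start = as.integer(ifelse(strand == "+", five_prime,
                              five_prime - read_len + 1L)),
    end = as.integer(ifelse(strand == "+", five_prime + read_len,
                            five_prime + 1L)),
    strand = strand
  )
  promstate:::new_read_library(reads, fragment_size = fragment_size,
                               deduplicated = deduplicated,
                               total_unique = nrow(reads))
}

write_bed6 <- function(df, path = tempfile(fileext = ".bed")) {
  out <- data.frame(df$chrom, df$start, df$end, ".", 0L, df$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# Independent brute-force Poisson upper tail: direct mass summation from n
# to a far cutoff, no calls into the package's tail function.
bf_tail <- function(n, lambda) {
  if (n <= 0) return(1)
  hi <- max(ceiling(lambda + 60 * sqrt(lambda + 1)), n + 60)
  sum(stats::dpois(n:hi, lambda))
}

# Independent brute-force threshold search over 1..99.
bf_threshold <- function(total, window_bp, genome_bp, alpha = 0.05) {
  lambda <- total * window_bp / genome_bp
  for (n in 1:99) if (bf_tail(n, lambda) <= alpha) return(n)
  NA_integer_
}

# Brute-force O(n^2) reimplementation of the eligibility filter used as an
# independent oracle for filter_transcripts.
bf_filter <- function(tx, min_len = 500L, tss_gap = 400L) {
  n <- nrow(tx)
  too_short <- tx$tx_len < min_len
  surv <- which(!too_short)
  span_olap <- function(i, a, b) {   # does [a,b) hit transcript i's span?
    a < tx$tx_end[i] & b > tx$tx_start[i]
  }
  ov_pol <- ov_k4 <- close <- rep(FALSE, n)
  for (i in surv) {
    pw <- c(tx$tss[i] - 250L, tx$tss[i] + 250L)
    kw <- if (tx$strand[i] == "+") c(tx$tss[i], tx$tss[i] + 500L)
          else c(tx$tss[i] - 500L, tx$tss[i])
    for (j in surv) {
      if (tx$gene_id[j] == tx$gene_id[i] || tx$chrom[j] != tx$chrom[i]) next
      if (span_olap(j, pw[1], pw[2])) ov_pol[i] <- TRUE
      if (span_olap(j, kw[1], kw[2])) ov_k4[i] <- TRUE
      disjoint <- tx$tx_end[i] <= tx$tx_start[j] || tx$tx_end[j] <= tx$tx_start[i]
      if (tx$strand[j] != tx$strand[i] && disjoint &&
          abs(tx$tss[j] - tx$tss[i]) < tss_gap) close[i] <- TRUE
    }
  }
  prom <- !too_short & !ov_k4
  pol <- prom & !ov_pol & !close
  data.frame(transcript_id = tx$transcript_id, too_short = too_short,
             overlap_k4k27 = ov_k4, overlap_polII = ov_pol,
             tss_too_close = close, promoter_eligible = prom,
             polII_eligible = pol,
             stalling_eligible = pol & tx$tx_len > 1000L,
             k36_eligible = prom & tx$tx_len > 1500L)
}
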