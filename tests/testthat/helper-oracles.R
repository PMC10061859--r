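# Independent brute-force oracles used across tests. These deliberately take
# the slow, obvious route so they share no code with the implementation.

# per-basepair value vector of a bedGraph step track on one chromosome,
# over [0, len)
oracle_bp_vector <- function(track, chrom, len) {
  v <- numeric(len)
  d <- track[track$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(d)))
    v[(d$start[i] + 1):d$end[i]] <- d$value[i]
  v
}

# exact mean of the per-bp step function over [a, b) with fractional ends
oracle_bin_mean <- function(bp, a, b) {
  total <- 0
  for (j in floor(a):(ceiling(b) - 1)) {
    w <- min(b, j + 1) - max(a, j)
    if (w > 0) total <- total + w * bp[j + 1]
  }
  total / (b - a)
}

# quadratic promoter-CGI membership oracle: length in [200, 5000] and >= 1 bp
# overlap with some [tss - 1000, tss + 1000) window (0-based half-open)
oracle_is_promoter <- function(cgi_start, cgi_end, tss_positions) {
  len <- cgi_end - cgi_start
  if (len < 200 || len > 5000) return(FALSE)
  any(tss_positions - 1000 < cgi_end & cgi_start < tss_positions + 1000)
}

# direct-formula Tau (no shared code with tau())
oracle_tau <- function(x, log_transform = FALSE) {
  if (log_transform) x <- log2(x + 1)
  xhat <- x / max(x)
  sum(1 - xhat) / (length(x) - 1)
}

# small config used by several module tests; plants fewer tissue-specific
# genes on tiny genomes so the bivalent class can host them
small_config <- function(n = 300L, seed = 7L, ...) {
  synthetic_config(n_promoters = n, seed = seed,
                   n_specific_per_tissue = if (n >= 150L) 5L else 1L, ...)
}

# promoter matrices for one condition of a genome bundle
promoter_matrices <- function(genome, tracks, promoters, cond = "WT",
                              marks = c("H3K4me1", "H3K4me3", "H3K27me3")) {
  lapply(setNames(marks, marks), function(mk)
    bin_signal(tracks[[mk]][[cond]], promoters, mark = mk, condition = cond))
}

# adjusted Rand index between two label vectors (independent cross-check
# library)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
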