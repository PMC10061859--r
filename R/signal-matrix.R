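# Exact integration of a bedGraph step function.
# Runs must be non-overlapping within a chromosome; gaps count as coverage 0.
track_integrator <- function(track) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  if (any(!is.finite(track$value))) t_stop("track contains non-finite values")
  track$value <- pmax(track$value, 0)   # input-adjusted tracks: clamp negatives
  lapply(split(track, track$chrom), function(d) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      t_stop("overlapping runs in track on %s", d$chrom[1L])
    list(s = d$start, e = d$end, v = d$value,
         C = c(0, cumsum(d$value * (d$end - d$start))))
  })
}

# cumulative integral of the step function at (possibly fractional) x
integrate_at <- function(ti, x) {
  out <- numeric(length(x))
  idx <- findInterval(x, ti$s)
  pos <- idx > 0L
  i <- idx[pos]
  out[pos] <- ti$C[i] + ti$v[i] * pmax(0, pmin(x[pos], ti$e[i]) - ti$s[i])
  out
}

#' Bin a coverage track over promoter CGIs and their 1 kb shores
#'
#' Produces the signal matrix every downstream stage consumes: one row per
#' promoter CGI, with `n_flank` equal-width bins over the 1 kb upstream
#' shore, `n_body` bins over the CGI body rescaled to a common length, and
#' `n_flank` bins over the downstream shore. Each cell is the exact mean
#' coverage over its (possibly fractional-bp) span, computed by integrating
#' the bedGraph step function; positions without coverage count as 0, so
#' binning is linear in the track. Shores are taken in genomic orientation
#' (left/right), not flipped by strand.
#'
#' @param track bedGraph data frame (`chrom`, `start`, `end`, `value`) or a
#'   path to a bedGraph file.
#' @param promoters a `promoter_cgis` table from [define_promoter_cgis()].
#' @param n_flank,n_body bins per shore / body (each >= 1).
#' @param mark,condition metadata recorded on the matrix.
#' @param chrom_sizes optional chromosome lengths (`chrom`, `length`); when
#'   given, bins extending past a chromosome edge are truncated to the
#'   available span (with a warning) and fully off-contig bins are 0.
#' @return object of class `signal_matrix`: list with `values` (rows named
#'   by `cgi_id`, columns `L1..`, `B1..`, `R1..`), `mark`, `condition`,
#'   `n_flank`, `n_body`, `flank_bp` and per-row `body_length`.
#' @export
bin_signal <- function(track, promoters, n_flank = 20L, n_body = 20L,
                       mark = NA_character_, condition = NA_character_,
                       chrom_sizes = NULL) {
  if (is.character(track)) track <- read_bedgraph(track)
  stopifnot(n_flank >= 1L, n_body >= 1L, nrow(promoters) > 0L)
  ti <- track_integrator(track)
  flank_bp <- 1000L

  n <- nrow(promoters)
  L <- promoters$end - promoters$start
  fw <- flank_bp / n_flank
  # bin edges, rows = promoters, one column per edge
  edges <- cbind(
    outer(promoters$start - flank_bp, fw * (0:(n_flank - 1L)), `+`),
    promoters$start + outer(L, (0:(n_body - 1L)) / n_body),
    outer(promoters$end, fw * (0:n_flank), `+`)
  )
  ncol_total <- 2L * n_flank + n_body
  a <- edges[, seq_len(ncol_total), drop = FALSE]
  b <- edges[, 1L + seq_len(ncol_total), drop = FALSE]

  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes$length[match(promoters$chrom, chrom_sizes$chrom)]
    a2 <- pmax(a, 0); b2 <- pmin(b, lim)
    if (any(a2 != a | b2 != b))
      t_warn("some shore bins extend past a chromosome edge; truncated to the available span")
    a <- a2; b <- b2
  }

  vals <- matrix(0, nrow = n, ncol = ncol_total,
                 dimnames = list(promoters$cgi_id,
                                 c(paste0("L", seq_len(n_flank)),
                                   paste0("B", seq_len(n_body)),
                                   paste0("R", seq_len(n_flank)))))
  for (ch in unique(promoters$chrom)) {
    ri <- which(promoters$chrom == ch)
    tch <- ti[[ch]]
    if (is.null(tch)) next  # no coverage on this chromosome: rows stay 0
    aa <- a[ri, , drop = FALSE]; bb <- b[ri, , drop = FALSE]
    w <- bb - aa
    v <- integrate_at(tch, as.vector(bb)) - integrate_at(tch, as.vector(aa))
    m <- matrix(v, nrow = length(ri))
    m[w > 0] <- m[w > 0] / w[w > 0]
    m[w <= 0] <- 0
    vals[ri, ] <- m
  }

  structure(list(values = vals, mark = mark, condition = condition,
                 n_flank = as.integer(n_flank), n_body = as.integer(n_body),
                 flank_bp = flank_bp,
                 body_length = setNames(as.numeric(L), promoters$cgi_id)),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d promoters x %d bins (%s, %s)\n",
              nrow(x$values), ncol(x$values),
              x$mark %||% "?", x$condition %||% "?"))
  invisible(x)
}

#' Winsorize a signal matrix at an upper percentile
#'
#' Values above the matrix-wide `upper_pct` percentile (linear-interpolation
#' quantile) are clamped to it; nothing else changes. Used before k-means so
#' a handful of extreme promoters cannot dominate the distances.
#'
#' @param matrix a `signal_matrix`.
#' @param upper_pct percentile in (50, 100]; 100 is the identity.
#' @return the winsorized `signal_matrix`.
#' @export
winsorize_scale <- function(matrix, upper_pct = 99) {
  stopifnot(inherits(matrix, "signal_matrix"))
  if (!is_number(upper_pct) || upper_pct <= 50 || upper_pct > 100)
    t_stop("upper_pct must lie in (50, 100]")
  v <- matrix$values
  if (any(!is.finite(v))) t_stop("matrix contains non-finite values")
  if (upper_pct < 100) {
    cap <- quantile(v, upper_pct / 100, names = FALSE)
    v[v > cap] <- cap
  }
  matrix$values <- v
  matrix
}

#' Per-promoter summary of a signal-matrix region
#'
#' Arithmetic mean over the named column block: `left_shore`, `body`,
#' `right_shore`, `shores` (mean of the two shore summaries) or `full`
#' (bin-width-weighted mean over the whole padded region, i.e. the exact
#' bp-resolution mean since body bins have width `body_length / n_body`).
#'
#' @param matrix a `signal_matrix`.
#' @param region one of `"left_shore"`, `"body"`, `"right_shore"`,
#'   `"shores"`, `"full"`.
#' @return named numeric vector, one value per promoter.
#' @export
summarize_region <- function(matrix,
                             region = c("body", "shores", "left_shore",
                                        "right_shore", "full")) {
  stopifnot(inherits(matrix, "signal_matrix"))
  region <- match.arg(region)
  nf <- matrix$n_flank; nb <- matrix$n_body
  v <- matrix$values
  left <- seq_len(nf); body <- nf + seq_len(nb); right <- nf + nb + seq_len(nf)
  switch(region,
    left_shore = rowMeans(v[, left, drop = FALSE]),
    body = rowMeans(v[, body, drop = FALSE]),
    right_shore = rowMeans(v[, right, drop = FALSE]),
    shores = (rowMeans(v[, left, drop = FALSE]) +
              rowMeans(v[, right, drop = FALSE])) / 2,
    full = {
      fw <- matrix$flank_bp / nf
      bw <- matrix$body_length / nb   # per-row body bin width
      tot <- rowSums(v[, c(left, right), drop = FALSE]) * fw +
             rowSums(v[, body, drop = FALSE]) * bw
      tot / (2 * matrix$flank_bp + matrix$body_length)
    })
}

#' Mean coverage over arbitrary intervals
#'
#' Exact mean of a bedGraph step function over each interval (used for
#' enhancer-level summaries). Intervals on chromosomes without coverage
#' get 0.
#'
#' @param track bedGraph data frame or file path.
#' @param intervals data frame with `chrom`, `start`, `end` and `name`.
#' @return named numeric vector of per-interval means.
#' @export
summarize_intervals <- function(track, intervals) {
  if (is.character(track)) track <- read_bedgraph(track)
  ti <- track_integrator(track)
  out <- setNames(numeric(nrow(intervals)), intervals$name)
  for (ch in unique(intervals$chrom)) {
    tch <- ti[[ch]]
    if (is.null(tch)) next
    ri <- which(intervals$chrom == ch)
    out[ri] <- (integrate_at(tch, intervals$end[ri]) -
                integrate_at(tch, intervals$start[ri])) /
               (intervals$end[ri] - intervals$start[ri])
  }
  out
}
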