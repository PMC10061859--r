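.canonical_marks <- c("H3K4me1", "H3K4me3", "H3K27me3", "H3K27ac")
.canonical_conditions <- c("WT", "KO")

#' Generate synthetic coverage tracks with planted chromatin structure
#'
#' Builds bedGraph-style coverage tracks for each requested mark and
#' condition. Coverage is emitted over promoter windows (CGI body plus 1 kb
#' shores) and planted enhancer intervals; the rest of the genome is left
#' uncovered (coverage 0), mimicking a sparse input-adjusted track. The
#' deterministic shape is a plateau at the body amplitude over the CGI plus
#' Gaussian shoulders (sd = 250 bp) centred on each shore, riding on the
#' configured baseline; per-step values are drawn from a negative binomial
#' with that shape as mean (`noise_size = Inf` gives the pure shape).
#'
#' Planted structure in the second condition (`"KO"`, standing equally for a
#' differentiated tissue): every bivalent promoter loses its H3K27me3
#' (amplitude drops to baseline); bimodal-loss promoters lose their H3K4me1
#' shore elevation; bimodal-gain promoters (shore-low in `"WT"`) gain it.
#' Enhancers of planted tissue-specific genes gain H3K4me1/H3K27ac.
#'
#' Tracks for a given (mark, condition) pair are generated from a seed
#' derived from `config$seed` and the pair's canonical index, so output does
#' not depend on which other pairs are requested.
#'
#' @param genome a `trivalent_genome` from [make_genome()].
#' @param marks,conditions subsets of
#'   `c("H3K4me1", "H3K4me3", "H3K27me3", "H3K27ac")` and `c("WT", "KO")`.
#'   H3K27ac is generated at enhancers only.
#' @return nested list `tracks[[mark]][[condition]]` of bedGraph data frames
#'   (`chrom`, `start`, `end`, `value`), class `trivalent_tracks`.
#' @export
make_tracks <- function(genome, marks = .canonical_marks,
                        conditions = .canonical_conditions) {
  stopifnot(inherits(genome, "trivalent_genome"))
  config <- genome$config
  known <- union(unique(config$shape_params$mark), names(config$enhancer_amps))
  bad <- setdiff(marks, known)
  if (length(bad) > 0L)
    t_stop("no shape_params/enhancer_amps entry for mark(s): %s",
           paste(bad, collapse = ", "))
  bad_cond <- setdiff(conditions, .canonical_conditions)
  if (length(bad_cond) > 0L)
    t_stop("unknown condition(s): %s (expected WT/KO)",
           paste(bad_cond, collapse = ", "))

  out <- list()
  for (mark in marks) {
    out[[mark]] <- list()
    for (cond in conditions) {
      seed <- config$seed +
        7919L * match(mark, .canonical_marks) +
        104729L * match(cond, .canonical_conditions)
      out[[mark]][[cond]] <- withr::with_seed(seed, {
        build_track(genome, config, mark, cond)
      })
    }
  }
  class(out) <- c("trivalent_tracks", "list")
  out
}

build_track <- function(genome, config, mark, cond) {
  parts <- list()
  if (mark %in% config$shape_params$mark)
    parts <- c(parts, list(promoter_runs(genome, config, mark, cond)))
  if (mark %in% names(config$enhancer_amps))
    parts <- c(parts, list(enhancer_runs(genome, config, mark, cond)))
  track <- do.call(rbind, parts)
  track <- track[order(track$chrom, track$start), ]
  rownames(track) <- NULL
  track
}

# per-promoter amplitudes for one mark/condition, applying planted changes
resolve_amplitudes <- function(genome, config, mark, cond) {
  truth <- genome$truth
  sp <- config$shape_params[config$shape_params$mark == mark, ]
  body  <- sp$body[match(truth$class, sp$class)]
  shore <- sp$shore[match(truth$class, sp$class)]
  b <- config$baseline

  if (mark == "H3K27me3" && cond == "KO") {
    lost <- truth$class == "bivalent"
    body[lost] <- b; shore[lost] <- b
  }
  if (mark == "H3K4me1") {
    if (cond == "WT") shore[truth$transition == "bigain"] <- b
    if (cond == "KO") shore[truth$transition == "biloss"] <- b
  }
  list(body = body, shore = shore)
}

promoter_runs <- function(genome, config, mark, cond) {
  fl <- config$flank; step <- config$track_step; b <- config$baseline
  amp <- resolve_amplitudes(genome, config, mark, cond)
  cg <- genome$cgis
  L <- cg$end - cg$start
  rs <- cg$start - fl; re <- cg$end + fl

  n_steps <- ceiling((L + 2L * fl) / step)
  prom <- rep(seq_len(nrow(cg)), n_steps)
  j <- sequence(n_steps) - 1L
  s <- rs[prom] + j * step
  e <- pmin(s + step, re[prom])
  mid <- (s + e) / 2

  in_body <- mid >= cg$start[prom] & mid < cg$end[prom]
  centre <- ifelse(mid < cg$start[prom], cg$start[prom] - fl / 2,
                   cg$end[prom] + fl / 2)
  sigma <- fl / 4
  mu <- ifelse(in_body, amp$body[prom],
               b + (amp$shore[prom] - b) * exp(-((mid - centre)^2) / (2 * sigma^2)))
  data.frame(chrom = cg$chrom[prom], start = s, end = e,
             value = nb_noise(mu, config$noise_size),
             stringsAsFactors = FALSE)
}

enhancer_runs <- function(genome, config, mark, cond) {
  step <- config$track_step
  en <- genome$enhancers
  amps <- config$enhancer_amps[[mark]]
  specific <- genome$truth$tissue_specific[match(en$gene_id, genome$truth$gene_id)]
  level <- ifelse(cond == "KO" & specific, amps[["gain"]], amps[["base"]])

  wid <- en$end - en$start
  n_steps <- ceiling(wid / step)
  i <- rep(seq_len(nrow(en)), n_steps)
  j <- sequence(n_steps) - 1L
  s <- en$start[i] + j * step
  e <- pmin(s + step, en$end[i])
  data.frame(chrom = en$chrom[i], start = s, end = e,
             value = nb_noise(level[i], config$noise_size),
             stringsAsFactors = FALSE)
}

nb_noise <- function(mu, size) {
  if (is.infinite(size)) return(mu)
  rnbinom(length(mu), size = size, mu = mu)
}

#' Write coverage tracks as bedGraph files
#'
#' One file per mark and condition, named `<mark>_<condition>.bedGraph`.
#'
#' @param tracks output of [make_tracks()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_tracks <- function(tracks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (mark in names(tracks))
    for (cond in names(tracks[[mark]]))
      write_bedgraph(tracks[[mark]][[cond]],
                     file.path(dir, sprintf("%s_%s.bedGraph", mark, cond)))
  invisible(dir)
}
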