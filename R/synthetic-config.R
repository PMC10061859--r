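#' Default per-class, per-mark signal amplitudes
#'
#' Mean coverage planted at the CpG-island body (plateau) and at the shore
#' shoulders (Gaussian peak centred on each 1 kb shore) for each promoter
#' class. The three classes reproduce the canonical heatmap phenotypes:
#' `low` promoters are flat for every mark; `bivalent` promoters carry high
#' H3K4me3 and H3K27me3 with an untypical, body-high H3K4me1 distribution;
#' `active` promoters carry high H3K4me3 with a typical bimodal H3K4me1
#' (shores high, body low) and no H3K27me3.
#'
#' @return data frame with columns `class`, `mark`, `body`, `shore`.
#' @export
default_shape_params <- function() {
  data.frame(
    class = rep(c("low", "bivalent", "active"), each = 3L),
    mark  = rep(c("H3K4me1", "H3K4me3", "H3K27me3"), times = 3L),
    body  = c(1, 1, 1,   8, 7, 8,   1, 10, 1),
    shore = c(1, 1, 1,   5, 3, 4,   6,  4, 1),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic genome generator
#'
#' Assembles and validates the configuration consumed by [make_genome()],
#' [make_tracks()] and [make_expression()]. The defaults define the study
#' conditions under which the pipeline is validated: three equally sized
#' promoter classes, 20% of bivalent promoters planted as bimodal-loss and
#' 20% as bimodal-gain in the second (knockout-like) condition, negative
#' binomial count noise on the coverage tracks, and a noiseless multi-tissue
#' expression matrix with five planted tissue-specific genes per tissue.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp, or `NULL` to auto-size just
#'   large enough for the requested promoters.
#' @param n_promoters number of promoter CpG islands (one gene each).
#' @param class_proportions named simplex weights over
#'   `c("low", "bivalent", "active")`; must sum to 1 within 1e-9.
#' @param cgi_length_range CpG-island length bounds in bp; must lie within
#'   the admissible promoter-CGI range of 200-5000 bp.
#' @param flank shore width in bp (1 kb by definition of the analysis).
#' @param shape_params amplitude table, see [default_shape_params()].
#' @param baseline background coverage level outside planted features.
#' @param noise_size negative binomial size (dispersion) parameter of the
#'   per-step count noise; `Inf` gives the noiseless deterministic shape.
#' @param track_step bedGraph step width in bp.
#' @param transition_fractions named fractions (`biloss`, `bigain`) of
#'   bivalent promoters planted as bimodal-loss / bimodal-gain in the second
#'   condition; must sum to at most 1.
#' @param n_tissues,n_specific_per_tissue tissue count and number of planted
#'   tissue-specific genes per tissue for the expression matrix.
#' @param expression_noise_sd sd of multiplicative log2-normal noise on the
#'   expression matrix; 0 (default) gives the noiseless construction under
#'   which planted tissue-specific genes are recovered exactly.
#' @param enhancer_amps per-mark enhancer amplitudes: `base` in both
#'   conditions, `gain` at enhancers of planted tissue-specific genes in the
#'   second condition.
#' @param de_means,de_sd means/sd of planted `log2FoldChange` in the
#'   knockout-vs-wild-type differential expression table, by promoter group.
#' @param seed integer master seed; all generator randomness derives from it.
#' @return a validated configuration list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chroms = 2L,
                             chrom_length = NULL,
                             n_promoters = 300L,
                             class_proportions = c(low = 1 / 3, bivalent = 1 / 3,
                                                   active = 1 / 3),
                             cgi_length_range = c(500L, 3000L),
                             flank = 1000L,
                             shape_params = default_shape_params(),
                             baseline = 1,
                             noise_size = 10,
                             track_step = 25L,
                             transition_fractions = c(biloss = 0.2, bigain = 0.2),
                             n_tissues = 6L,
                             n_specific_per_tissue = 5L,
                             expression_noise_sd = 0,
                             enhancer_amps = list(H3K4me1 = c(base = 3, gain = 6),
                                                  H3K27ac = c(base = 1, gain = 6)),
                             de_means = c(biloss = 0.5, bigain = 2.0,
                                          bivalent_other = 1.0, other = 0),
                             de_sd = 0.3,
                             seed = 1L) {
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_length = chrom_length,
    n_promoters = as.integer(n_promoters),
    class_proportions = class_proportions,
    cgi_length_range = as.integer(cgi_length_range), flank = as.integer(flank),
    shape_params = shape_params, baseline = baseline,
    noise_size = noise_size, track_step = as.integer(track_step),
    transition_fractions = transition_fractions,
    n_tissues = as.integer(n_tissues),
    n_specific_per_tissue = as.integer(n_specific_per_tissue),
    expression_noise_sd = expression_noise_sd,
    enhancer_amps = enhancer_amps,
    de_means = de_means, de_sd = de_sd,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  errs <- character(0L)
  add <- function(msg) errs <<- c(errs, msg)

  if (!is_count(cfg$n_chroms)) add("n_chroms must be a positive integer")
  if (!is_count(cfg$n_promoters)) add("n_promoters must be a positive integer")
  if (!is.null(cfg$chrom_length) && !is_count(cfg$chrom_length))
    add("chrom_length must be NULL or a positive integer")

  cp <- cfg$class_proportions
  if (!setequal(names(cp), c("low", "bivalent", "active")) ||
      any(cp < 0) || abs(sum(cp) - 1) > 1e-9)
    add("class_proportions must be named weights over low/bivalent/active summing to 1")

  rng <- cfg$cgi_length_range
  if (length(rng) != 2L || rng[1L] > rng[2L])
    add("cgi_length_range must be an increasing pair")
  if (rng[1L] < 200L || rng[2L] > 5000L)
    add(sprintf("cgi_length_range [%d, %d] must lie within [200, 5000] bp (promoter-CGI length rule)",
                rng[1L], rng[2L]))

  sp <- cfg$shape_params
  if (!all(c("class", "mark", "body", "shore") %in% names(sp)))
    add("shape_params must have columns class, mark, body, shore")
  else if (any(sp$body < 0) || any(sp$shore < 0))
    add("all shape amplitudes must be >= 0")
  if (cfg$baseline < 0) add("baseline must be >= 0")
  if (!(is_number(cfg$noise_size) || identical(cfg$noise_size, Inf)) ||
      cfg$noise_size <= 0)
    add("noise_size (NB dispersion) must be > 0 (Inf for noiseless)")
  if (!is_count(cfg$track_step)) add("track_step must be a positive integer")
  if (!is_count(cfg$flank) || cfg$flank != 1000L)
    add("flank must be 1000 bp (shores are defined as the adjacent 1 kb)")

  tf <- cfg$transition_fractions
  if (!setequal(names(tf), c("biloss", "bigain")) || any(tf < 0) || sum(tf) > 1)
    add("transition_fractions must be named biloss/bigain fractions summing to <= 1")

  if (!is_count(cfg$n_tissues) || cfg$n_tissues < 2L)
    add("n_tissues must be >= 2")
  if (!is_count(cfg$n_specific_per_tissue))
    add("n_specific_per_tissue must be a positive integer")
  if (cfg$n_specific_per_tissue * cfg$n_tissues > cfg$n_promoters)
    add(sprintf("n_specific_per_tissue (%d) x n_tissues (%d) exceeds the gene count (%d)",
                cfg$n_specific_per_tissue, cfg$n_tissues, cfg$n_promoters))
  if (cfg$expression_noise_sd < 0) add("expression_noise_sd must be >= 0")
  if (!is_count(abs(cfg$seed) + 1)) add("seed must be an integer")

  if (length(errs) > 0L)
    t_stop("invalid synthetic configuration:\n  - %s",
           paste(errs, collapse = "\n  - "))
  invisible(cfg)
}
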