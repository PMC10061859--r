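#' Generate a gene-by-tissue expression matrix and differential-expression
#' tables with planted structure
#'
#' Background expression is drawn from a discrete 10-level grid
#' (10, 20, ..., 100) whose top level carries 20% of the probability mass.
#' Because the top level is shared by well over 10% of genes in every
#' tissue, the per-tissue 90th-percentile threshold used by
#' [select_tissue_specific()] lands exactly on that level, and the strict
#' "greater than" comparison excludes every background gene. Planted
#' tissue-specific genes receive a unique value above 1000 in their target
#' tissue (rank 1 there by construction) and a value below the background
#' grid elsewhere, so in the noiseless default the recovered
#' tissue-specific sets equal the planted sets exactly. Setting
#' `expression_noise_sd > 0` multiplies the matrix by log2-normal noise,
#' under which recovery holds only in expectation.
#'
#' The differential-expression table for the knockout-vs-wild-type contrast
#' plants `log2FoldChange` by promoter group (bimodal-loss mean 0.5,
#' bimodal-gain mean 2.0 by default, sd 0.3): bivalent genes are mostly
#' up-regulated upon global H3K27me3 loss, with the bimodal-loss group
#' gaining markedly less than the bimodal-gain group. Bivalent genes get
#' small p-values (1e-8 to 1e-4), other genes null fold changes and large
#' p-values.
#'
#' @param genome a `trivalent_genome` (carries the planted gene truth).
#' @param config a [synthetic_config()]; defaults to `genome$config`.
#' @return object of class `trivalent_expression`: list with `expression`
#'   (numeric matrix, genes x tissues), `de` (named list of data frames with
#'   columns `gene`, `log2FoldChange`, `pvalue`), and `gene_truth`
#'   (per-gene tissue-specificity and DE status at the 1.2 / 0.1 knockout
#'   thresholds).
#' @export
make_expression <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "trivalent_genome"))
  validate_synthetic_config(config)
  truth <- genome$truth
  genes <- truth$gene_id
  G <- length(genes)
  tissues <- paste0("tissue_", seq_len(config$n_tissues))
  if (config$n_specific_per_tissue * config$n_tissues > G)
    t_stop("n_specific_per_tissue x n_tissues (%d) exceeds gene count (%d)",
           config$n_specific_per_tissue * config$n_tissues, G)

  withr::with_seed(config$seed + 2L, {
    levels <- seq(10, 100, by = 10)
    probs <- c(rep(0.8 / 9, 9L), 0.2)
    mat <- matrix(sample(levels, G * length(tissues), replace = TRUE, prob = probs),
                  nrow = G, dimnames = list(genes, tissues))

    spec <- which(truth$tissue_specific)
    mat[spec, ] <- 5                   # below the background grid everywhere
    mat[cbind(spec, match(truth$target_tissue[spec], tissues))] <-
      1000 + seq_along(spec)           # unique top value in the target tissue

    if (config$expression_noise_sd > 0)
      mat <- mat * 2^matrix(rnorm(length(mat), sd = config$expression_noise_sd),
                            nrow = G)

    # -- knockout-vs-wild-type DE table
    grp <- ifelse(truth$transition == "biloss", "biloss",
           ifelse(truth$transition == "bigain", "bigain",
           ifelse(truth$class == "bivalent", "bivalent_other", "other")))
    mu <- config$de_means[grp]
    sdv <- ifelse(grp == "other", 0.15, config$de_sd)
    lfc <- rnorm(G, mean = mu, sd = sdv)
    pval <- ifelse(grp == "other", runif(G, 0.15, 1), runif(G, 1e-8, 1e-4))
    de <- data.frame(gene = genes, log2FoldChange = lfc, pvalue = pval,
                     stringsAsFactors = FALSE)
  })

  de_status <- ifelse(de$log2FoldChange >= 1.2 & de$pvalue <= 0.1, "up",
               ifelse(de$log2FoldChange <= -1.2 & de$pvalue <= 0.1, "down", "ns"))
  out <- list(
    expression = mat,
    de = list(KO_vs_WT = de),
    gene_truth = data.frame(gene_id = genes,
                            tissue_specific = truth$tissue_specific,
                            target_tissue = truth$target_tissue,
                            de_status_KO_vs_WT = de_status,
                            stringsAsFactors = FALSE)
  )
  class(out) <- "trivalent_expression"
  out
}

#' Write expression outputs as TSV files
#'
#' Emits `expression.tsv` (gene column plus one column per tissue),
#' `de_<contrast>.tsv` and `gene_truth.tsv` under `dir`.
#'
#' @param expr a `trivalent_expression`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_expression_bundle <- function(expr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  em <- data.frame(gene = rownames(expr$expression), expr$expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(em, file.path(dir, "expression.tsv"))
  for (contrast in names(expr$de))
    write_tsv(expr$de[[contrast]], file.path(dir, sprintf("de_%s.tsv", contrast)))
  write_tsv(expr$gene_truth, file.path(dir, "gene_truth.tsv"))
  invisible(dir)
}
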