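#' Tau tissue-specificity index
#'
#' The canonical tissue-specificity index: with `x_hat_i = x_i / max(x)`,
#' `tau = sum(1 - x_hat_i) / (N - 1)` over `N >= 2` tissues. Tau is 0 for
#' uniform non-zero expression, 1 for expression confined to a single
#' tissue, and lies in `[0, 1]` for every non-negative vector. By default
#' the vector is `log2(x + 1)`-transformed first, the convention for
#' TPM-scale expression; set `log_transform = FALSE` to evaluate the raw
#' index. An all-zero vector has no defined specificity and returns `NA`.
#'
#' @param x non-negative numeric vector of per-tissue expression values.
#' @param log_transform apply `log2(x + 1)` before scoring (default TRUE).
#' @return tau in `[0, 1]`, or `NA_real_` for an all-zero vector.
#' @export
tau <- function(x, log_transform = TRUE) {
  if (length(x) < 2L) t_stop("tau needs at least 2 tissues")
  if (any(is.na(x)) || any(x < 0)) t_stop("tau is defined for non-negative values")
  if (all(x == 0)) return(NA_real_)
  if (log_transform) x <- log2(x + 1)
  xh <- x / max(x)
  sum(1 - xh) / (length(x) - 1L)
}

#' Tau for every gene of an expression matrix
#'
#' @param expression numeric matrix, genes x tissues, row names = gene ids.
#' @inheritParams tau
#' @return data frame with columns `gene_id` and `tau`.
#' @export
tau_scores <- function(expression, log_transform = TRUE) {
  stopifnot(is.matrix(expression), ncol(expression) >= 2L)
  data.frame(gene_id = rownames(expression),
             tau = apply(expression, 1L, tau, log_transform = log_transform),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select tissue-specific genes by the two-criteria rule
#'
#' A gene is specific to a tissue when (1) that tissue ranks in the top
#' `top_rank` among all tissues for the gene (expression in decreasing
#' order, competition ranking: ties share the best rank) and (2) the gene
#' is highly expressed there — strictly above the `pct_threshold` quantile
#' (linear interpolation) of all genes' expression within that tissue. A
#' gene may qualify in several tissues. The result is invariant to row and
#' column order of the matrix.
#'
#' @param expression numeric matrix, genes x tissues (>= 2 tissues), row
#'   names = gene ids, column names = tissue names.
#' @param top_rank rank cutoff for criterion (1) (default 5).
#' @param pct_threshold quantile for criterion (2) (default 0.9, the 90th
#'   percentile).
#' @return object of class `tissue_specific_set`: list with `sets` (tissue
#'   -> character vector of gene ids) and `evidence` (long data frame with
#'   per-(gene, tissue) rank, expression and threshold for every selected
#'   pair).
#' @export
select_tissue_specific <- function(expression, top_rank = 5L,
                                   pct_threshold = 0.9) {
  stopifnot(is.matrix(expression), ncol(expression) >= 2L)
  if (nrow(expression) < 10L)
    t_warn("fewer than 10 genes: the within-tissue percentile is ill-conditioned")

  ranks <- t(apply(expression, 1L, rank_decreasing_min))
  thr <- apply(expression, 2L, quantile, probs = pct_threshold, names = FALSE)
  hit <- ranks <= top_rank & sweep(expression, 2L, thr, `>`)

  tissues <- colnames(expression)
  sets <- lapply(setNames(tissues, tissues), function(t)
    rownames(expression)[hit[, t]])
  idx <- which(hit, arr.ind = TRUE)
  evidence <- data.frame(
    gene_id = rownames(expression)[idx[, 1L]],
    tissue = tissues[idx[, 2L]],
    rank = ranks[idx], expression = expression[idx],
    threshold = thr[idx[, 2L]], stringsAsFactors = FALSE, row.names = NULL)
  evidence <- evidence[order(evidence$tissue, evidence$gene_id), ]
  rownames(evidence) <- NULL
  structure(list(sets = sets, evidence = evidence,
                 top_rank = as.integer(top_rank),
                 pct_threshold = pct_threshold),
            class = "tissue_specific_set")
}

#' @export
print.tissue_specific_set <- function(x, ...) {
  cat(sprintf("tissue_specific_set: %d tissue(s), %s gene(s) per tissue\n",
              length(x$sets), paste(lengths(x$sets), collapse = "/")))
  invisible(x)
}

#' Filter a differential-expression table at fold-change and p thresholds
#'
#' Up-regulated genes satisfy `log2FoldChange >= lfc_cut` and
#' `pvalue <= p_cut`; down-regulated genes the mirrored fold-change
#' condition. Both cuts are inclusive, so a record at exactly the threshold
#' survives; the up and down sets are disjoint by construction. The
#' standard threshold pairs are (2, 0.05) for ESC-vs-tissue contrasts and
#' (1.2, 0.1) for the knockout contrasts.
#'
#' @param de data frame with columns `gene`, `log2FoldChange`, `pvalue`.
#' @param lfc_cut,p_cut positive thresholds.
#' @return list with character vectors `up` and `down`.
#' @export
filter_de <- function(de, lfc_cut, p_cut) {
  need <- c("gene", "log2FoldChange", "pvalue")
  if (!all(need %in% names(de)))
    t_stop("DE table must have columns %s (missing: %s)",
           paste(need, collapse = ", "),
           paste(setdiff(need, names(de)), collapse = ", "))
  stopifnot(lfc_cut > 0, p_cut > 0)
  sig <- de$pvalue <= p_cut
  list(up = de$gene[sig & de$log2FoldChange >= lfc_cut],
       down = de$gene[sig & de$log2FoldChange <= -lfc_cut])
}
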