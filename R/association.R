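#' Build the per-gene design table for the tissue-specificity model
#'
#' One row per gene having both a promoter CGI and an assigned enhancer.
#' The outcome is membership of the focal tissue's specific-gene set; the
#' predictors are the condition-2 minus condition-1 deltas of promoter body
#' summaries (H3K4me1, H3K4me3, H3K27me3) and of nearest-enhancer
#' summaries (H3K4me1, H3K27ac). Predictors are standardized to zero mean
#' and unit variance by default (centers/scales recorded in attributes so
#' raw-scale coefficients are recoverable); zero-variance predictors are
#' dropped with a warning.
#'
#' @param tissue focal tissue name (must be present in `specific_set`).
#' @param specific_set a `tissue_specific_set` from
#'   [select_tissue_specific()].
#' @param promoters a `promoter_cgis` table (maps CGIs to genes).
#' @param promoter_matrices named list `mark -> list(cond1, cond2)` of
#'   `signal_matrix` objects for H3K4me1, H3K4me3 and H3K27me3.
#' @param enhancer_summaries named list `mark -> list(cond1, cond2)` of
#'   per-gene named numeric vectors (from [summarize_intervals()] over
#'   nearest-enhancer intervals) for H3K4me1 and H3K27ac.
#' @param standardize standardize predictors (default TRUE).
#' @return data frame of class `design_table` with columns `gene_id`,
#'   `outcome` (0/1) and the five delta predictors; attributes `centers`,
#'   `scales`, `dropped` and `n_no_enhancer`.
#' @export
build_design <- function(tissue, specific_set, promoters, promoter_matrices,
                         enhancer_summaries, standardize = TRUE) {
  stopifnot(inherits(specific_set, "tissue_specific_set"))
  if (!tissue %in% names(specific_set$sets))
    t_stop("tissue '%s' not present in the specific set", tissue)

  prom_marks <- c("H3K4me1", "H3K4me3", "H3K27me3")
  enh_marks <- c("H3K4me1", "H3K27ac")
  gene_of <- setNames(promoters$gene_id, promoters$cgi_id)

  prom_delta <- lapply(setNames(prom_marks, paste0("prom_", prom_marks)),
    function(mk) {
      pair <- promoter_matrices[[mk]]
      if (is.null(pair)) t_stop("missing promoter matrices for %s", mk)
      d <- summarize_region(pair[[2L]], "body") - summarize_region(pair[[1L]], "body")
      setNames(unname(d[promoters$cgi_id]), unname(gene_of[promoters$cgi_id]))
    })
  enh_delta <- lapply(setNames(enh_marks, paste0("enh_", enh_marks)),
    function(mk) {
      pair <- enhancer_summaries[[mk]]
      if (is.null(pair)) t_stop("missing enhancer summaries for %s", mk)
      common <- intersect(names(pair[[1L]]), names(pair[[2L]]))
      pair[[2L]][common] - pair[[1L]][common]
    })

  genes <- Reduce(intersect, c(lapply(prom_delta, names), lapply(enh_delta, names)))
  n_no_enh <- length(setdiff(names(prom_delta[[1L]]), genes))
  if (n_no_enh > 0L)
    message(sprintf("build_design: %d gene(s) without an assigned enhancer dropped", n_no_enh))
  if (length(genes) == 0L) t_stop("no genes with both a promoter and an enhancer")

  design <- data.frame(gene_id = genes,
                       outcome = as.integer(genes %in% specific_set$sets[[tissue]]),
                       stringsAsFactors = FALSE)
  for (nm in names(prom_delta)) design[[nm]] <- unname(prom_delta[[nm]][genes])
  for (nm in names(enh_delta)) design[[nm]] <- unname(enh_delta[[nm]][genes])

  if (sum(design$outcome) == 0L)
    t_stop("no positive outcomes for tissue '%s': the model cannot be fit", tissue)

  centers <- scales <- numeric(0L)
  dropped <- character(0L)
  if (standardize) {
    for (nm in setdiff(names(design), c("gene_id", "outcome"))) {
      s <- sd(design[[nm]])
      if (!is.finite(s) || s < 1e-12) {
        t_warn("predictor %s has zero variance; dropped", nm)
        dropped <- c(dropped, nm)
        design[[nm]] <- NULL
        next
      }
      centers[nm] <- mean(design[[nm]]); scales[nm] <- s
      design[[nm]] <- (design[[nm]] - centers[nm]) / s
    }
  }
  structure(design, centers = centers, scales = scales, dropped = dropped,
            n_no_enhancer = n_no_enh,
            class = c("design_table", "data.frame"))
}

#' Fit the logistic model of tissue specificity
#'
#' Maximum-likelihood logistic regression (binomial GLM, iteratively
#' reweighted least squares) of the binary outcome on every numeric
#' predictor column. Reports per-predictor coefficient, standard error,
#' odds ratio with Wald 95% confidence interval
#' (`exp(estimate +/- 1.96 se)`) and Wald p-value. Perfect separation is
#' surfaced as an error naming the offending predictor, and a singular
#' information matrix (aliased coefficients) as an error, rather than
#' silently reporting meaningless estimates; no regularization is applied.
#'
#' @param design a `design_table` (or any data frame with a 0/1 `outcome`
#'   column and numeric predictors; a `gene_id` column is ignored).
#' @param max_iter IRLS iteration cap.
#' @param tol IRLS convergence tolerance (relative deviance change).
#' @return object of class `logistic_fit`: list with `coefficients` (data
#'   frame: `term`, `estimate`, `se`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`), `intercept`, `converged`, `iterations`, `log_likelihood`
#'   and `n`.
#' @export
fit_logistic <- function(design, max_iter = 50L, tol = 1e-12) {
  if (!"outcome" %in% names(design)) t_stop("design must have an 'outcome' column")
  preds <- setdiff(names(design), c("gene_id", "outcome"))
  if (length(preds) == 0L) t_stop("design has no predictors")
  y <- design$outcome
  if (length(unique(y)) < 2L)
    t_stop("outcome must include both positives and negatives")

  dat <- design[, c("outcome", preds), drop = FALSE]
  sep_warning <- FALSE
  fit <- withCallingHandlers(
    glm(outcome ~ ., family = binomial(), data = dat,
        control = glm.control(epsilon = tol, maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warning <<- TRUE
      invokeRestart("muffleWarning")
    })

  cf <- coef(fit)
  if (anyNA(cf))
    t_stop("singular information matrix: predictor(s) %s aliased",
           paste(names(cf)[is.na(cf)], collapse = ", "))
  if (sep_warning) {
    worst <- names(which.max(abs(cf[preds])))
    t_stop("perfect (or quasi-perfect) separation detected; predictor '%s' separates the outcome — the maximum-likelihood fit does not exist",
           worst)
  }
  if (!fit$converged)
    t_warn("IRLS did not converge within %d iterations", max_iter)

  sm <- summary(fit)$coefficients
  est <- sm[preds, "Estimate"]; se <- sm[preds, "Std. Error"]
  coefs <- data.frame(
    term = preds, estimate = unname(est), se = unname(se),
    odds_ratio = unname(exp(est)),
    ci_low = unname(exp(est - 1.96 * se)),
    ci_high = unname(exp(est + 1.96 * se)),
    p_value = unname(2 * pnorm(-abs(est / se))),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(coefficients = coefs,
                 intercept = unname(cf["(Intercept)"]),
                 converged = fit$converged, iterations = fit$iter,
                 log_likelihood = as.numeric(logLik(fit)),
                 n = nrow(dat)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit: n = %d, logLik = %.2f, converged in %d iteration(s)\n",
              x$n, x$log_likelihood, x$iterations))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}
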