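#' Classify per-promoter H3K4me1 patterns
#'
#' Two independent 2-means clusterings — one on per-promoter body summaries,
#' one on shore summaries (mean of both shores) — each labelled high/low by
#' cluster mean. The 2 x 2 combination maps to the pattern vocabulary:
#' body high is `untypical_unimodal` (H3K4me1 over the CGI body, the
#' poised/bivalent signature, regardless of shore level since body
#' elevation dominates that signature), body low with shores high is
#' `typical_bimodal` (the active-promoter signature), and both low is
#' `flat`. Because the high/low labels come from relative cluster means,
#' the calls are invariant to positive rescaling of the whole matrix.
#'
#' @param h3k4me1_matrix a `signal_matrix` of H3K4me1 coverage (>= 4 rows).
#' @param seed seed for the 2-means restarts.
#' @return data frame of class `pattern_calls`: `cgi_id`, `condition`,
#'   `body_level`, `shore_level` (each `"high"`/`"low"`), `pattern`.
#' @export
classify_pattern <- function(h3k4me1_matrix, seed = 1L) {
  stopifnot(inherits(h3k4me1_matrix, "signal_matrix"))
  if (nrow(h3k4me1_matrix$values) < 4L)
    t_stop("pattern classification needs at least 4 promoters")
  body <- summarize_region(h3k4me1_matrix, "body")
  shore <- summarize_region(h3k4me1_matrix, "shores")

  body_level <- two_means_level(body, seed, "body")
  shore_level <- two_means_level(shore, seed + 1L, "shore")
  pattern <- ifelse(body_level == "high", "untypical_unimodal",
             ifelse(shore_level == "high", "typical_bimodal", "flat"))
  structure(data.frame(cgi_id = names(body),
                       condition = h3k4me1_matrix$condition,
                       body_level = body_level, shore_level = shore_level,
                       pattern = pattern, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("pattern_calls", "data.frame"))
}

two_means_level <- function(x, seed, what) {
  if (diff(range(x)) < 1e-12)
    t_stop("constant %s summaries: no high/low separation; supply explicit thresholds instead",
           what)
  km <- withr::with_seed(seed, kmeans(x, centers = 2L, nstart = 10L))
  hi <- which.max(km$centers)
  unname(ifelse(km$cluster == hi, "high", "low"))
}

#' Call H3K27me3-H3K4me1 transitions between two paired conditions
#'
#' A promoter loses H3K27me3 when its body-mean delta (condition 2 minus
#' condition 1) falls at or below `-loss_threshold`. The H3K4me1 group is
#' read off the pattern calls: shore level high to low is the bimodal-loss
#' group, low to high the bimodal-gain group, anything else `none`. The
#' transition flag requires both the H3K27me3 loss and a group membership.
#'
#' When `loss_threshold` is `NULL` it defaults to 50% of the condition-1
#' median body H3K27me3 over the bivalent promoters (`bivalent_ids`, or,
#' when those are not supplied, the promoters called `untypical_unimodal`
#' in condition 1) — a numeric stand-in for "visible loss on the heatmap".
#'
#' @param calls_cond1,calls_cond2 `pattern_calls` for the two conditions
#'   over the same promoter universe.
#' @param k27_pair list of two H3K27me3 `signal_matrix` objects
#'   (condition 1, condition 2).
#' @param k4me1_pair optional list of two H3K4me1 matrices; when given, the
#'   continuous body/shore deltas are reported alongside the calls.
#' @param loss_threshold positive number, or `NULL` for the default rule.
#' @param bivalent_ids optional character vector of promoter ids used for
#'   the default threshold.
#' @return data frame of class `transition_calls`: `cgi_id`,
#'   `h3k27me3_delta`, `h3k4me1_body_delta`, `h3k4me1_shore_delta`,
#'   `h3k27me3_loss`, `group` (`biloss`/`bigain`/`none`) and `transition`
#'   (logical flag).
#' @export
call_transitions <- function(calls_cond1, calls_cond2, k27_pair,
                             k4me1_pair = NULL, loss_threshold = NULL,
                             bivalent_ids = NULL) {
  ids <- calls_cond1$cgi_id
  if (!setequal(ids, calls_cond2$cgi_id))
    t_stop("pattern calls cover different promoter universes")
  c2 <- calls_cond2[match(ids, calls_cond2$cgi_id), ]

  body1 <- summarize_region(k27_pair[[1L]], "body")[ids]
  body2 <- summarize_region(k27_pair[[2L]], "body")[ids]
  if (any(is.na(body1)) || any(is.na(body2)))
    t_stop("H3K27me3 matrices do not cover the pattern-call universe")
  delta <- body2 - body1

  if (is.null(loss_threshold)) {
    biv <- bivalent_ids %||% ids[calls_cond1$pattern == "untypical_unimodal"]
    if (length(biv) == 0L)
      t_stop("cannot derive a default loss threshold: no bivalent promoters identified")
    loss_threshold <- 0.5 * median(body1[biv])
  }
  if (!is_number(loss_threshold) || loss_threshold <= 0)
    t_stop("loss_threshold must be a positive number")

  loss <- delta <= -loss_threshold
  group <- ifelse(calls_cond1$shore_level == "high" & c2$shore_level == "low",
                  "biloss",
           ifelse(calls_cond1$shore_level == "low" & c2$shore_level == "high",
                  "bigain", "none"))

  d_body <- d_shore <- rep(NA_real_, length(ids))
  if (!is.null(k4me1_pair)) {
    d_body <- (summarize_region(k4me1_pair[[2L]], "body") -
               summarize_region(k4me1_pair[[1L]], "body"))[ids]
    d_shore <- (summarize_region(k4me1_pair[[2L]], "shores") -
                summarize_region(k4me1_pair[[1L]], "shores"))[ids]
  }

  structure(data.frame(cgi_id = ids, h3k27me3_delta = unname(delta),
                       h3k4me1_body_delta = unname(d_body),
                       h3k4me1_shore_delta = unname(d_shore),
                       h3k27me3_loss = unname(loss), group = group,
                       transition = unname(loss) & group != "none",
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("transition_calls", "data.frame"))
}

#' Expression contrast between the bimodal-loss and bimodal-gain groups
#'
#' Maps transition calls to genes through the promoter table, splits the
#' differential-expression table by group and reports the two
#' `log2FoldChange` distributions, the two-sided Wilcoxon rank-sum p-value
#' between them, and a chi-squared test (no continuity correction) of
#' up/down-regulation counts against group membership. Raw p-values are
#' reported; these are single headline tests, not a screen.
#'
#' @param transitions a `transition_calls` table.
#' @param promoters a `promoter_cgis` table mapping `cgi_id` to `gene_id`.
#' @param de differential-expression data frame (`gene`, `log2FoldChange`,
#'   `pvalue`).
#' @param lfc_cut,p_cut thresholds used to classify genes as up/down for
#'   the chi-squared contingency (defaults: the knockout-contrast
#'   thresholds 1.2 and 0.1).
#' @return object of class `group_contrast`: list with per-group gene ids
#'   and `log2FoldChange` vectors, group medians, `wilcoxon_p`,
#'   `direction`, the up/down `contingency` and `chisq` (statistic, df,
#'   p-value; `NA` with a warning when a group has < 3 genes or a margin is
#'   empty).
#' @export
group_expression_contrast <- function(transitions, promoters, de,
                                      lfc_cut = 1.2, p_cut = 0.1) {
  gene_of <- setNames(promoters$gene_id, promoters$cgi_id)
  groups <- lapply(c(biloss = "biloss", bigain = "bigain"), function(g) {
    genes <- unname(gene_of[transitions$cgi_id[transitions$group == g]])
    genes[genes %in% de$gene]
  })
  lfc <- lapply(groups, function(g) de$log2FoldChange[match(g, de$gene)])

  res <- list(genes = groups, log2fc = lfc,
              medians = vapply(lfc, function(x)
                if (length(x) > 0L) median(x) else NA_real_, numeric(1L)))
  if (any(lengths(lfc) < 3L)) {
    t_warn("a transition group has fewer than 3 genes; contrast statistics undefined")
    res$wilcoxon_p <- NA_real_
    res$direction <- NA_character_
    res$contingency <- NULL
    res$chisq <- list(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  } else {
    res$wilcoxon_p <- wilcox.test(lfc$biloss, lfc$bigain)$p.value
    res$direction <- if (res$medians[["biloss"]] < res$medians[["bigain"]])
      "biloss_lower" else "bigain_lower"
    updown <- filter_de(de[de$gene %in% unlist(groups), ], lfc_cut, p_cut)
    dir_of <- function(g) ifelse(g %in% updown$up, "up",
                          ifelse(g %in% updown$down, "down", NA_character_))
    long <- data.frame(group = rep(names(groups), lengths(groups)),
                       dir = dir_of(unlist(groups)))
    long <- long[!is.na(long$dir), ]
    tab <- table(factor(long$group, levels = c("biloss", "bigain")),
                 factor(long$dir, levels = c("up", "down")))
    res$contingency <- tab
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      t_warn("up/down contingency has an empty margin; chi-squared undefined")
      res$chisq <- list(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      res$chisq <- list(statistic = unname(ct$statistic),
                        df = unname(ct$parameter), p_value = ct$p.value)
    }
  }
  class(res) <- "group_contrast"
  res
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("group_contrast: biloss n = %d (median log2FC %.3f), bigain n = %d (median log2FC %.3f)\n",
              length(x$genes$biloss), x$medians[["biloss"]],
              length(x$genes$bigain), x$medians[["bigain"]]))
  cat(sprintf("  Wilcoxon p = %.3g; chi-squared = %.3f (p = %.3g)\n",
              x$wilcoxon_p, x$chisq$statistic, x$chisq$p_value))
  invisible(x)
}
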