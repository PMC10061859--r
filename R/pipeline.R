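#' Validate and normalize a pipeline run configuration
#'
#' A run configuration either carries a `simulate` block (a
#' [synthetic_config()]) or an `inputs` block pointing at files on disk
#' (`cgis`, `tss`, `peaks`, per-mark/per-condition `tracks`, `expression`,
#' `de`). Stage parameters get defaults here; every violation is collected
#' and reported at once.
#'
#' @param config a list; see Details for recognized fields.
#' @return the normalized configuration (class `run_config`).
#' @details Recognized stage parameters (with defaults): `n_flank` (20),
#'   `n_body` (20), `winsorize_pct` (99), `k` (3), `seed` (1),
#'   `loss_threshold` (`NULL` = derived from the bivalent cluster),
#'   `de_lfc_cut` (1.2), `de_p_cut` (0.1), `top_rank` (5),
#'   `pct_threshold` (0.9), `focal_tissue` (first tissue).
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(n_flank = 20L, n_body = 20L, winsorize_pct = 99,
                   k = 3L, seed = 1L, loss_threshold = NULL,
                   de_lfc_cut = 1.2, de_p_cut = 0.1,
                   top_rank = 5L, pct_threshold = 0.9, focal_tissue = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[nm] <- defaults[nm]

  errs <- character(0L)
  add <- function(msg) errs <<- c(errs, msg)

  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (!has_sim && !has_inputs)
    add("config needs a 'simulate' block or an 'inputs' block")
  if (has_sim)
    tryCatch(validate_synthetic_config(config$simulate),
             error = function(e) add(conditionMessage(e)))
  if (has_inputs) {
    paths <- unlist(config$inputs, use.names = TRUE)
    missing <- paths[!file.exists(paths)]
    for (i in seq_along(missing))
      add(sprintf("input file not found: %s (%s)", missing[i], names(missing)[i]))
  }
  if (!is_count(config$k) || config$k < 2L) add("k must be an integer >= 2")
  if (!is_count(config$n_flank)) add("n_flank must be a positive integer")
  if (!is_count(config$n_body)) add("n_body must be a positive integer")
  if (!is_number(config$de_lfc_cut) || config$de_lfc_cut <= 0)
    add("de_lfc_cut must be > 0")
  if (!is_number(config$de_p_cut) || config$de_p_cut <= 0 || config$de_p_cut > 1)
    add("de_p_cut must be in (0, 1]")
  if (!is.null(config$loss_threshold) &&
      (!is_number(config$loss_threshold) || config$loss_threshold <= 0))
    add("loss_threshold must be NULL or > 0")
  if (!is_number(config$pct_threshold) || config$pct_threshold <= 0 ||
      config$pct_threshold >= 1)
    add("pct_threshold must be in (0, 1)")
  if (!is_count(config$top_rank)) add("top_rank must be a positive integer")
  if (!is_count(config$winsorize_pct + 0.5) &&
      (!is_number(config$winsorize_pct) || config$winsorize_pct <= 50 ||
       config$winsorize_pct > 100))
    add("winsorize_pct must lie in (50, 100]")

  if (length(errs) > 0L)
    t_stop("invalid run configuration:\n  - %s", paste(errs, collapse = "\n  - "))
  class(config) <- c("run_config", "list")
  config
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    t_stop("stage '%s' failed: %s", name, conditionMessage(e)))
}

.analysis_marks <- c("H3K4me1", "H3K4me3", "H3K27me3")
.enh_marks <- c("H3K4me1", "H3K27ac")

#' Run the full trivalent analysis pipeline
#'
#' Executes, in order: simulation (or input loading), promoter-CGI
#' definition, signal-matrix construction, three-class k-means partitioning
#' (with the traditional H3K4me3+H3K27me3 versus non-traditional
#' H3K4me1+H3K4me3 overlap comparison), H3K4me1 pattern classification per
#' condition, transition calling, the bimodal-loss/bimodal-gain expression
#' contrast, Tau scoring and tissue-specific gene selection, DE filtering,
#' enhancer assignment, and the logistic tissue-specificity model. A stage
#' error aborts with the stage name; intermediates computed so far are
#' still persisted when `outdir` is set.
#'
#' Re-running with the same configuration reproduces byte-identical
#' persisted outputs (wall time is kept on the returned object only, not
#' written to `report.json`).
#'
#' @param config a run configuration (validated with [validate_config()]).
#' @param outdir optional output directory for persisted intermediates and
#'   `report.json`.
#' @return object of class `run_report`: per-stage summary statistics plus
#'   all in-memory intermediates in the `objects` element.
#' @export
run_all <- function(config, outdir = NULL) {
  config <- validate_config(config)
  t0 <- Sys.time()
  report <- list(package_version = as.character(utils::packageVersion("trivalent")),
                 r_version = R.version.string,
                 config_hash = config_hash(config),
                 stages = list())
  obj <- list()
  persist <- !is.null(outdir)
  if (persist) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # ---- simulate / load --------------------------------------------------
  if (!is.null(config$simulate)) {
    run_stage("simulate", {
      obj$genome <- make_genome(config$simulate)
      obj$tracks <- make_tracks(obj$genome)
      obj$expr <- make_expression(obj$genome)
      if (persist) {
        write_genome_bundle(obj$genome, file.path(outdir, "genome"))
        write_tracks(obj$tracks, file.path(outdir, "tracks"))
        write_expression_bundle(obj$expr, file.path(outdir, "expression"))
      }
      report$stages$simulate <- list(
        n_promoters = nrow(obj$genome$cgis),
        class_counts = as.list(table(obj$genome$truth$class)),
        transition_counts = as.list(table(obj$genome$truth$transition)))
    })
    cgis <- obj$genome$cgis; tss <- obj$genome$tss; peaks <- obj$genome$peaks
    tracks <- obj$tracks
    expression <- obj$expr$expression
    de <- obj$expr$de$KO_vs_WT
    chrom_sizes <- obj$genome$chrom_sizes
  } else {
    run_stage("load", {
      inp <- config$inputs
      cgis <- read_bed(inp$cgis); tss <- read_bed(inp$tss)
      peaks <- read_bed(inp$peaks)
      tracks <- lapply(inp$tracks, function(conds) lapply(conds, read_bedgraph))
      em <- read_tsv(inp$expression)
      expression <- as.matrix(em[, -1L, drop = FALSE])
      rownames(expression) <- em[[1L]]
      de <- read_tsv(inp$de)
      chrom_sizes <- if (!is.null(inp$chrom_sizes))
        read_chrom_sizes(inp$chrom_sizes) else NULL
      report$stages$load <- list(n_cgis = nrow(cgis), n_tss = nrow(tss),
                                 n_peaks = nrow(peaks))
    })
  }

  # ---- promoters --------------------------------------------------------
  promoters <- run_stage("promoters", define_promoter_cgis(cgis, tss))
  obj$promoters <- promoters
  if (persist) write_tsv(promoters, file.path(outdir, "promoters.tsv"))
  report$stages$promoters <- list(n = nrow(promoters))

  # ---- matrices ---------------------------------------------------------
  mats <- run_stage("matrices", {
    for (mk in .analysis_marks)
      for (cond in c("WT", "KO"))
        if (is.null(tracks[[mk]][[cond]]))
          t_stop("missing input track: %s (%s)", mk, cond)
    out <- lapply(setNames(.analysis_marks, .analysis_marks), function(mk)
      lapply(setNames(c("WT", "KO"), c("WT", "KO")), function(cond)
        bin_signal(tracks[[mk]][[cond]], promoters,
                   n_flank = config$n_flank, n_body = config$n_body,
                   mark = mk, condition = cond, chrom_sizes = chrom_sizes)))
    out
  })
  obj$matrices <- mats
  report$stages$matrices <- list(
    n_bins = 2L * config$n_flank + config$n_body,
    marks = .analysis_marks)

  # ---- partition + cross-definition overlap -----------------------------
  run_stage("partition", {
    wt <- lapply(mats, `[[`, "WT")
    obj$partition <- label_cluster_roles(
      kmeans_partition(wt, k = config$k, seed = config$seed,
                       winsorize_pct = config$winsorize_pct), wt)
    trad <- label_cluster_roles(
      kmeans_partition(wt[c("H3K4me3", "H3K27me3")], k = config$k,
                       seed = config$seed,
                       winsorize_pct = config$winsorize_pct), wt)
    nontrad <- label_cluster_roles(
      kmeans_partition(wt[c("H3K4me1", "H3K4me3")], k = config$k,
                       seed = config$seed,
                       winsorize_pct = config$winsorize_pct), wt)
    obj$overlap <- overlap_comparison(nontrad, trad)
    biv <- obj$overlap$overlap[obj$overlap$overlap$role == "bivalent", ]
    report$stages$partition <- list(
      cluster_sizes = as.list(table(obj$partition$role)),
      bivalent_overlap_pct_of_nontraditional = biv$pct_of_a,
      bivalent_overlap_pct_of_traditional = biv$pct_of_b)
    if (persist) {
      write_tsv(data.frame(cgi_id = names(obj$partition$cluster),
                           gene_id = promoters$gene_id[match(names(obj$partition$cluster),
                                                             promoters$cgi_id)],
                           cluster = unname(obj$partition$cluster),
                           role = unname(obj$partition$role),
                           stringsAsFactors = FALSE),
                file.path(outdir, "partition.tsv"))
      write_tsv(obj$overlap$overlap, file.path(outdir, "overlap.tsv"))
    }
  })

  # ---- patterns & transitions -------------------------------------------
  run_stage("patterns", {
    obj$patterns <- list(
      WT = classify_pattern(mats$H3K4me1$WT, seed = config$seed),
      KO = classify_pattern(mats$H3K4me1$KO, seed = config$seed))
    report$stages$patterns <- list(
      WT = as.list(table(obj$patterns$WT$pattern)),
      KO = as.list(table(obj$patterns$KO$pattern)))
    if (persist) {
      write_tsv(obj$patterns$WT, file.path(outdir, "patterns_WT.tsv"))
      write_tsv(obj$patterns$KO, file.path(outdir, "patterns_KO.tsv"))
    }
  })

  run_stage("transitions", {
    biv_ids <- names(obj$partition$role)[obj$partition$role == "bivalent"]
    obj$transitions <- call_transitions(
      obj$patterns$WT, obj$patterns$KO,
      k27_pair = list(mats$H3K27me3$WT, mats$H3K27me3$KO),
      k4me1_pair = list(mats$H3K4me1$WT, mats$H3K4me1$KO),
      loss_threshold = config$loss_threshold, bivalent_ids = biv_ids)
    report$stages$transitions <- list(
      group_counts = as.list(table(obj$transitions$group)),
      n_h3k27me3_loss = sum(obj$transitions$h3k27me3_loss),
      n_transition = sum(obj$transitions$transition))
    if (persist) write_tsv(obj$transitions, file.path(outdir, "transitions.tsv"))
  })

  run_stage("contrast", {
    obj$contrast <- group_expression_contrast(
      obj$transitions, promoters, de,
      lfc_cut = config$de_lfc_cut, p_cut = config$de_p_cut)
    report$stages$contrast <- list(
      median_log2fc = as.list(obj$contrast$medians),
      wilcoxon_p = obj$contrast$wilcoxon_p,
      chisq_statistic = obj$contrast$chisq$statistic,
      chisq_p = obj$contrast$chisq$p_value,
      direction = obj$contrast$direction)
    if (persist)
      jsonlite::write_json(report$stages$contrast,
                           file.path(outdir, "contrast.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  # ---- expression -------------------------------------------------------
  run_stage("expression", {
    obj$tau <- tau_scores(expression)
    obj$specific <- select_tissue_specific(expression,
                                            top_rank = config$top_rank,
                                            pct_threshold = config$pct_threshold)
    obj$de_sets <- filter_de(de, config$de_lfc_cut, config$de_p_cut)
    report$stages$expression <- list(
      n_genes = nrow(obj$tau), n_tissues = ncol(expression),
      n_specific = lengths(obj$specific$sets),
      n_up = length(obj$de_sets$up), n_down = length(obj$de_sets$down))
    if (persist) {
      write_tsv(obj$tau, file.path(outdir, "tau.tsv"))
      write_tsv(obj$specific$evidence, file.path(outdir, "tissue_specific.tsv"))
    }
  })

  # ---- association ------------------------------------------------------
  run_stage("association", {
    for (mk in .enh_marks)
      for (cond in c("WT", "KO"))
        if (is.null(tracks[[mk]][[cond]]))
          t_stop("missing input track: %s (%s)", mk, cond)
    obj$enhancers <- define_enhancers(peaks, tss)
    enh_int <- data.frame(chrom = obj$enhancers$chrom,
                          start = obj$enhancers$start,
                          end = obj$enhancers$end,
                          name = obj$enhancers$gene_id,
                          stringsAsFactors = FALSE)
    enh_sum <- lapply(setNames(.enh_marks, .enh_marks), function(mk)
      lapply(setNames(c("WT", "KO"), c("WT", "KO")), function(cond)
        summarize_intervals(tracks[[mk]][[cond]], enh_int)))
    focal <- config$focal_tissue %||% names(obj$specific$sets)[1L]
    obj$design <- build_design(focal, obj$specific, promoters, mats, enh_sum)
    obj$fit <- fit_logistic(obj$design)
    report$stages$association <- list(
      focal_tissue = focal, n_design = nrow(obj$design),
      n_positive = sum(obj$design$outcome),
      odds_ratios = setNames(as.list(obj$fit$coefficients$odds_ratio),
                             obj$fit$coefficients$term))
    if (persist) {
      write_tsv(obj$enhancers, file.path(outdir, "enhancers_assigned.tsv"))
      write_tsv(as.data.frame(obj$design), file.path(outdir, "design.tsv"))
      write_tsv(obj$fit$coefficients, file.path(outdir, "logistic_fit.tsv"))
    }
  })

  if (persist)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$objects <- obj
  attr(report, "wall_time_s") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "run_report"
  report
}

config_hash <- function(config) {
  x <- unclass(config)
  x$inputs <- NULL  # hash parameters, not absolute paths
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(json), f)
  unname(tools::md5sum(f))
}

#' @export
print.run_report <- function(x, ...) {
  cat("trivalent run report\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-12s %s\n", nm,
                paste(names(x$stages[[nm]]), collapse = ", ")))
  invisible(x)
}
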