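#' Partition promoter CGIs into chromatin classes by k-means
#'
#' Concatenates one signal matrix per histone mark into a feature matrix
#' (each mark winsorized at `winsorize_pct`, then column-standardized to
#' zero mean and unit variance so no high-amplitude mark dominates the
#' squared-Euclidean distance) and runs k-means with `nstart` random
#' restarts under a fixed seed, keeping the restart with the lowest
#' within-cluster sum of squares. The partition is deterministic given the
#' seed and, on well-separated data, stable across seeds up to label
#' permutation.
#'
#' @param matrices named list of `signal_matrix` objects (one per mark)
#'   sharing identical row keys.
#' @param k number of clusters (>= 2; 3 for the low/bivalent/active
#'   partition).
#' @param seed integer seed for the restarts.
#' @param winsorize_pct upper winsorizing percentile applied per mark.
#' @param nstart number of random restarts.
#' @return object of class `cluster_assignment`: list with `cluster` (named
#'   integer vector in `1..k`), `k`, `seed`, `marks`, `tot_withinss`,
#'   `scaling` (per-mark center/scale record) and, after
#'   [label_cluster_roles()], `role_map` and per-promoter `role`.
#' @export
kmeans_partition <- function(matrices, k = 3L, seed = 1L,
                             winsorize_pct = 99, nstart = 10L) {
  stopifnot(is.list(matrices), length(matrices) >= 1L, k >= 2L)
  keys <- rownames(matrices[[1L]]$values)
  for (m in matrices)
    if (!identical(rownames(m$values), keys))
      t_stop("all matrices must share identical row keys in the same order")
  if (length(keys) < k)
    t_stop("fewer promoters (%d) than clusters (k = %d)", length(keys), k)

  scaling <- list()
  feats <- lapply(names(matrices), function(nm) {
    v <- winsorize_scale(matrices[[nm]], winsorize_pct)$values
    ctr <- colMeans(v)
    scl <- apply(v, 2L, sd)
    scaling[[nm]] <<- list(center = ctr, scale = scl)
    scl[scl < 1e-12] <- 1  # constant columns carry no information
    colnames(v) <- paste0(nm, ".", colnames(v))
    sweep(sweep(v, 2L, ctr), 2L, scl, "/")
  })
  feat <- do.call(cbind, feats)
  if (all(apply(feat, 2L, sd) < 1e-12))
    t_stop("degenerate input: constant feature matrix, nothing to cluster")

  km <- withr::with_seed(seed,
    kmeans(feat, centers = k, nstart = nstart, iter.max = 200L))
  structure(list(cluster = setNames(km$cluster, keys), k = as.integer(k),
                 seed = as.integer(seed), marks = names(matrices),
                 tot_withinss = km$tot.withinss, scaling = scaling),
            class = "cluster_assignment")
}

#' Label cluster roles as low / bivalent / active
#'
#' Operationalizes the verbal cluster semantics: the bivalent cluster has
#' the highest mean H3K27me3 body signal; of the remaining two, the active
#' cluster has the higher mean H3K4me3 body signal; the last is the low
#' cluster. Labelling is invariant to a permutation of cluster indices.
#' Ties in the deciding means (within 1e-9) are refused rather than broken
#' arbitrarily.
#'
#' @param assignment a `cluster_assignment` with `k = 3`.
#' @param matrices named list of `signal_matrix` objects containing at
#'   least `H3K27me3` and `H3K4me3`.
#' @return the assignment with `role_map` (cluster index -> role) and a
#'   per-promoter `role` vector added.
#' @export
label_cluster_roles <- function(assignment, matrices) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (assignment$k != 3L)
    t_stop("role labelling is defined for k = 3 (got k = %d)", assignment$k)
  for (need in c("H3K27me3", "H3K4me3"))
    if (is.null(matrices[[need]]))
      t_stop("label_cluster_roles needs a %s matrix", need)

  cl <- assignment$cluster
  cluster_mean <- function(mark) {
    s <- summarize_region(matrices[[mark]], "body")
    tapply(s[names(cl)], cl, mean)
  }
  k27 <- cluster_mean("H3K27me3")
  k4me3 <- cluster_mean("H3K4me3")

  # the deciding maximum must be unique; ties among non-winners are harmless
  check_tie <- function(x, what) {
    s <- sort(x, decreasing = TRUE)
    if (s[1L] - s[2L] < 1e-9)
      t_stop("tie in cluster mean %s signal: roles are not identifiable", what)
  }
  check_tie(k27, "H3K27me3")
  bivalent <- names(which.max(k27))
  rest <- setdiff(names(k27), bivalent)
  check_tie(k4me3[rest], "H3K4me3")
  active <- rest[which.max(k4me3[rest])]
  low <- setdiff(rest, active)

  role_map <- setNames(c("bivalent", "active", "low"),
                       c(bivalent, active, low))
  role_map <- role_map[as.character(sort(as.integer(names(role_map))))]
  assignment$role_map <- role_map
  assignment$role <- setNames(unname(role_map[as.character(cl)]), names(cl))
  assignment
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d promoters, k = %d (marks: %s)\n",
              length(x$cluster), x$k, paste(x$marks, collapse = ", ")))
  tab <- table(x$role %||% x$cluster)
  print(tab)
  invisible(x)
}

#' Compare two promoter partitions by cluster role
#'
#' Matches clusters across two labelled partitions by role identity and
#' reports, per role, the directional overlap percentages
#' `100 |A n B| / |A|` and `100 |A n B| / |B|` (the form of the headline
#' "94% of non-traditional bivalent promoter CGIs were also traditional
#' bivalent, comprising 73% of them" statistic), the Jaccard index, and the
#' full 3 x 3 role-by-role contingency table over the shared promoters.
#'
#' @param assign_a,assign_b `cluster_assignment` objects labelled with
#'   [label_cluster_roles()], over the same promoter universe.
#' @return object of class `overlap_report`: list with `contingency`
#'   (role x role counts), `overlap` (per-role data frame with
#'   `pct_of_a`, `pct_of_b`, `jaccard`) and `n_shared`.
#' @export
overlap_comparison <- function(assign_a, assign_b) {
  for (a in list(assign_a, assign_b)) {
    stopifnot(inherits(a, "cluster_assignment"))
    if (is.null(a$role))
      t_stop("assignments must be labelled with label_cluster_roles() first")
  }
  shared <- intersect(names(assign_a$role), names(assign_b$role))
  if (length(shared) == 0L)
    t_stop("assignments have disjoint promoter universes")

  ra <- factor(assign_a$role[shared], levels = c("low", "bivalent", "active"))
  rb <- factor(assign_b$role[shared], levels = c("low", "bivalent", "active"))
  tab <- table(A = ra, B = rb)

  roles <- c("low", "bivalent", "active")
  ov <- do.call(rbind, lapply(roles, function(r) {
    na <- sum(ra == r); nb <- sum(rb == r); ni <- sum(ra == r & rb == r)
    data.frame(role = r, n_a = na, n_b = nb, n_intersect = ni,
               pct_of_a = if (na > 0) 100 * ni / na else NA_real_,
               pct_of_b = if (nb > 0) 100 * ni / nb else NA_real_,
               jaccard = if (na + nb - ni > 0) ni / (na + nb - ni) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(contingency = tab, overlap = ov, n_shared = length(shared)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report over %d shared promoters\n", x$n_shared))
  print(x$overlap, row.names = FALSE)
  invisible(x)
}
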