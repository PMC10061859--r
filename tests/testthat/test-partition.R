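noiseless_setup <- function(n = 300L, seed = 7L) {
  g <- make_genome(small_config(n = n, seed = seed, noise_size = Inf))
  tr <- make_tracks(g, marks = c("H3K4me1", "H3K4me3", "H3K27me3"),
                    conditions = "WT")
  p <- define_promoter_cgis(g$cgis, g$tss)
  list(genome = g, mats = promoter_matrices(g, tr, p), promoters = p)
}

# minimal labelled assignment for overlap tests
mk_assign <- function(roles) {
  structure(list(cluster = setNames(match(roles, c("low", "bivalent", "active")),
                                    names(roles)),
                 role = roles, k = 3L,
                 role_map = c(`1` = "low", `2` = "bivalent", `3` = "active")),
            class = "cluster_assignment")
}

test_that("noiseless planted classes are recovered exactly and labelled by role", {
  s <- noiseless_setup()
  a <- label_cluster_roles(kmeans_partition(s$mats, k = 3L, seed = 1L), s$mats)
  truth <- s$genome$truth[match(names(a$role), s$genome$truth$cgi_id), ]
  expect_equal(ari(a$cluster, truth$class), 1)
  expect_identical(unname(a$role), truth$class)  # roles match planted semantics
  # the bivalent cluster's H3K27me3 body mean is strictly the greatest
  body <- summarize_region(s$mats$H3K27me3, "body")
  means <- tapply(body[names(a$role)], a$role, mean)
  expect_gt(means[["bivalent"]], max(means[c("low", "active")]))
})

test_that("the partition is stable across seeds and row order on separated data", {
  s <- noiseless_setup(n = 150L, seed = 3L)
  a1 <- kmeans_partition(s$mats, seed = 1L)
  a2 <- kmeans_partition(s$mats, seed = 99L)
  expect_equal(ari(a1$cluster, a2$cluster), 1)
  # shuffling rows consistently across matrices does not change membership
  perm <- withr::with_seed(5L, sample.int(nrow(s$promoters)))
  shuffled <- lapply(s$mats, function(m) {
    m$values <- m$values[perm, ]; m$body_length <- m$body_length[perm]; m
  })
  a3 <- kmeans_partition(shuffled, seed = 1L)
  expect_equal(ari(a1$cluster[names(a3$cluster)], a3$cluster), 1)
  # determinism: same seed, same result
  expect_identical(a1$cluster, kmeans_partition(s$mats, seed = 1L)$cluster)
})

test_that("partitioning refuses degenerate inputs", {
  s <- noiseless_setup(n = 60L, seed = 2L)
  expect_error(kmeans_partition(s$mats, k = 100L), "fewer promoters")
  flat <- lapply(s$mats, function(m) { m$values[] <- 1; m })
  expect_error(kmeans_partition(flat), "degenerate")
})

test_that("role labelling is invariant to a permutation of cluster indices", {
  s <- noiseless_setup(n = 150L, seed = 3L)
  a <- kmeans_partition(s$mats, seed = 1L)
  b <- a
  perm <- c(2L, 3L, 1L)
  b$cluster <- setNames(perm[a$cluster], names(a$cluster))
  la <- label_cluster_roles(a, s$mats)
  lb <- label_cluster_roles(b, s$mats)
  expect_identical(la$role, lb$role)
})

test_that("identical assignments overlap 100% with Jaccard 1", {
  roles <- setNames(rep(c("low", "bivalent", "active"), each = 10L),
                    sprintf("p%02d", 1:30))
  rep_ <- overlap_comparison(mk_assign(roles), mk_assign(roles))
  expect_equal(rep_$overlap$pct_of_a, rep(100, 3))
  expect_equal(rep_$overlap$pct_of_b, rep(100, 3))
  expect_equal(rep_$overlap$jaccard, rep(1, 3))
  expect_equal(sum(rep_$contingency), 30L)
})

test_that("directional overlap percentages reproduce the two-definition statistic form", {
  # A's bivalent cluster: 94 shared + 6 private; B's: 94 shared + 35 private
  universe <- sprintf("p%03d", 1:300)
  a_biv <- c(sprintf("s%03d", 1:94), sprintf("x%d", 1:6))
  b_biv <- c(sprintf("s%03d", 1:94), sprintf("y%d", 1:35))
  all_ids <- union(universe, union(a_biv, b_biv))
  ra <- setNames(ifelse(all_ids %in% a_biv, "bivalent", "low"), all_ids)
  rb <- setNames(ifelse(all_ids %in% b_biv, "bivalent", "active"), all_ids)
  # fill third role so both partitions use three clusters
  ra[tail(all_ids, 5L)] <- "active"; rb[head(all_ids, 5L)] <- "low"
  rep_ <- overlap_comparison(mk_assign(ra), mk_assign(rb))
  biv <- rep_$overlap[rep_$overlap$role == "bivalent", ]
  expect_equal(biv$pct_of_a, 94)               # 94 / 100
  expect_equal(biv$pct_of_b, 100 * 94 / 129)   # ~73%
})

test_that("the contingency table equals brute-force pair counting on random partitions", {
  ids <- sprintf("p%03d", 1:300)
  withr::with_seed(13L, {
    ra <- setNames(sample(c("low", "bivalent", "active"), 300L, TRUE), ids)
    rb <- setNames(sample(c("low", "bivalent", "active"), 300L, TRUE), ids)
  })
  rep_ <- overlap_comparison(mk_assign(ra), mk_assign(rb))
  for (x in c("low", "bivalent", "active"))
    for (y in c("low", "bivalent", "active"))
      expect_equal(unname(rep_$contingency[x, y]),
                   sum(ra == x & rb == y))
  expect_equal(sum(rep_$contingency), 300L)
  expect_error(overlap_comparison(mk_assign(ra),
                                  mk_assign(setNames(rb, paste0("z", ids)))),
               "disjoint")
})

test_that("partition accuracy is monotone in class separation and perfect in the limit", {
  aris <- vapply(c(1.5, 3, 8), function(s) {
    sp <- default_shape_params()
    amp <- sp[, c("body", "shore")]
    sp$body <- 1 + (amp$body - 1) * s / 8
    sp$shore <- 1 + (amp$shore - 1) * s / 8
    g <- make_genome(small_config(n = 150L, seed = 5L, shape_params = sp))
    tr <- make_tracks(g, marks = c("H3K4me1", "H3K4me3", "H3K27me3"),
                      conditions = "WT")
    p <- define_promoter_cgis(g$cgis, g$tss)
    a <- kmeans_partition(promoter_matrices(g, tr, p), seed = 1L)
    truth <- g$truth[match(names(a$cluster), g$truth$cgi_id), ]
    ari(a$cluster, truth$class)
  }, numeric(1L))
  expect_true(all(diff(aris) >= 0))
  expect_equal(aris[3L], 1)
})
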