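test_that("generated bundles are byte-identical under a fixed seed", {
  cfg <- small_config(n = 300L, seed = 7L)
  d1 <- file.path(tempdir(), "gen1"); d2 <- file.path(tempdir(), "gen2")
  write_genome_bundle(make_genome(cfg), d1)
  write_genome_bundle(make_genome(cfg), d2)
  g <- make_genome(cfg)
  write_tracks(make_tracks(g, marks = "H3K4me1"), d1)
  write_tracks(make_tracks(g, marks = "H3K4me1"), d2)
  write_expression_bundle(make_expression(g), d1)
  write_expression_bundle(make_expression(g), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", n = 2e7),
                     readBin(file.path(d2, f), "raw", n = 2e7),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("CGI length bounds outside 200-5000 bp are rejected", {
  expect_error(synthetic_config(cgi_length_range = c(150, 400)),
               "\\[200, 5000\\]")
  expect_error(synthetic_config(cgi_length_range = c(500, 6000)),
               "\\[200, 5000\\]")
})

test_that("every generated CGI passes the brute-force geometry check", {
  g <- make_genome(small_config(n = 300L, seed = 7L))
  tss_by_chrom <- split(g$tss$start, g$tss$chrom)
  ok <- vapply(seq_len(nrow(g$cgis)), function(i)
    oracle_is_promoter(g$cgis$start[i], g$cgis$end[i],
                       tss_by_chrom[[g$cgis$chrom[i]]]), logical(1L))
  expect_true(all(ok))
  expect_equal(nrow(g$cgis), 300L)
  # each CGI contains its own TSS
  expect_true(all(g$tss$start >= g$cgis$start & g$tss$start < g$cgis$end))
})

test_that("infeasible packing errors name the required minimum length", {
  cfg <- synthetic_config(n_promoters = 100L, n_chroms = 1L,
                          chrom_length = 50000L, seed = 1L)
  expect_error(make_genome(cfg), "infeasible packing.*at least [0-9]+ bp")
})

test_that("the noiseless limit reproduces configured amplitudes exactly", {
  cfg <- small_config(n = 60L, seed = 3L, noise_size = Inf)
  g <- make_genome(cfg)
  tr <- make_tracks(g, marks = "H3K4me3", conditions = "WT")$H3K4me3$WT
  act <- which(g$truth$class == "active")
  centres <- (g$cgis$start[act] + g$cgis$end[act]) / 2
  for (i in seq_along(act)) {
    run <- tr[tr$chrom == g$cgis$chrom[act[i]] &
              tr$start <= centres[i] & tr$end > centres[i], ]
    expect_equal(run$value, 10)   # configured active-class H3K4me3 body amplitude
  }
})

test_that("bivalent promoters lose H3K27me3 to baseline in the KO condition", {
  cfg <- synthetic_config(n_promoters = 625L, seed = 5L,
                          class_proportions = c(low = 0.1, bivalent = 0.8,
                                                active = 0.1))
  g <- make_genome(cfg)
  tr <- make_tracks(g, marks = "H3K27me3", conditions = "KO")$H3K27me3$KO
  biv <- g$truth$class == "bivalent"
  expect_gte(sum(biv), 500L)
  cg <- g$cgis[biv, ]; cg$name <- cg$name
  means <- summarize_intervals(tr, cg)
  se <- sd(means) / sqrt(length(means))
  expect_lte(mean(means), cfg$baseline + 3 * se)
})

test_that("count noise is negative binomial around the shape: empirical mean matches a constant field", {
  sp <- default_shape_params(); sp$body <- 5; sp$shore <- 5
  cfg <- synthetic_config(n_promoters = 400L, seed = 9L, baseline = 5,
                          shape_params = sp,
                          enhancer_amps = list(H3K4me1 = c(base = 5, gain = 5),
                                               H3K27ac = c(base = 5, gain = 5)))
  g <- make_genome(cfg)
  tr <- make_tracks(g, marks = "H3K4me1", conditions = "WT")$H3K4me1$WT
  w <- tr$end - tr$start
  expect_gte(sum(w), 1e6)   # at least a megabase of covered positions
  expect_lt(abs(sum(tr$value * w) / sum(w) - 5) / 5, 0.02)
  expect_true(all(tr$value >= 0 & tr$value == round(tr$value)))
})

test_that("requesting a mark without amplitude parameters is a configuration error", {
  g <- make_genome(small_config(n = 60L, seed = 2L))
  expect_error(make_tracks(g, marks = "H3K9me3"), "H3K9me3")
})

test_that("planted tissue-specific genes are rank 1 in their target tissue (noiseless)", {
  g <- make_genome(small_config(n = 300L, seed = 7L))
  ex <- make_expression(g)
  spec <- ex$gene_truth[ex$gene_truth$tissue_specific, ]
  for (i in seq_len(nrow(spec))) {
    row <- ex$expression[spec$gene_id[i], ]
    expect_identical(names(which.max(row)), spec$target_tissue[i])
    expect_equal(unname(rank(-row, ties.method = "min")[spec$target_tissue[i]]), 1)
  }
})

test_that("planted strong down-regulation survives the knockout DE filter as down", {
  cfg <- small_config(n = 300L, seed = 7L,
                      de_means = c(biloss = -2, bigain = 2,
                                   bivalent_other = 1, other = 0),
                      de_sd = 0)
  g <- make_genome(cfg)
  ex <- make_expression(g)
  biloss_genes <- g$truth$gene_id[g$truth$transition == "biloss"]
  sets <- filter_de(ex$de$KO_vs_WT, 1.2, 0.1)
  expect_true(all(biloss_genes %in% sets$down))
  expect_false(any(biloss_genes %in% sets$up))
})

test_that("noiseless KO-vs-WT shore delta sign identifies exactly the planted transition sets", {
  cfg <- small_config(n = 200L, seed = 4L, noise_size = Inf)
  g <- make_genome(cfg)
  tr <- make_tracks(g, marks = "H3K4me1")
  p <- define_promoter_cgis(g$cgis, g$tss)
  m1 <- bin_signal(tr$H3K4me1$WT, p); m2 <- bin_signal(tr$H3K4me1$KO, p)
  delta <- summarize_region(m2, "shores") - summarize_region(m1, "shores")
  truth <- g$truth[match(names(delta), g$truth$cgi_id), ]
  # below numerical precision the delta is zero; planted deltas are O(1)
  expect_setequal(names(delta)[delta < -1e-6],
                  truth$cgi_id[truth$transition == "biloss"])
  expect_setequal(names(delta)[delta > 1e-6],
                  truth$cgi_id[truth$transition == "bigain"])
})
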