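pattern_setup <- function(n = 300L, seed = 7L, noise = Inf) {
  g <- make_genome(small_config(n = n, seed = seed, noise_size = noise))
  tr <- make_tracks(g, marks = c("H3K4me1", "H3K27me3"))
  p <- define_promoter_cgis(g$cgis, g$tss)
  mats <- lapply(c(H3K4me1 = "H3K4me1", H3K27me3 = "H3K27me3"), function(mk)
    lapply(c(WT = "WT", KO = "KO"), function(cond)
      bin_signal(tr[[mk]][[cond]], p, mark = mk, condition = cond)))
  list(genome = g, mats = mats, promoters = p,
       truth = g$truth[match(p$cgi_id, g$truth$cgi_id), ])
}

test_that("noiseless planted shapes map to the expected patterns", {
  s <- pattern_setup(noise = Inf)
  calls <- classify_pattern(s$mats$H3K4me1$WT, seed = 1L)
  expect_identical(calls$pattern, s$truth$pattern_cond1)
  expect_identical(calls$shore_level,
                   ifelse(s$truth$shore_cond1 == "high", "high", "low"))
  # body-high promoters are untypical_unimodal regardless of shore level
  expect_true(all(calls$pattern[calls$body_level == "high"] == "untypical_unimodal"))
})

test_that("pattern calls are invariant to positive rescaling of the matrix", {
  s <- pattern_setup(n = 150L, seed = 3L)
  m <- s$mats$H3K4me1$WT
  scaled <- m; scaled$values <- m$values * 37.5
  expect_identical(classify_pattern(m, seed = 1L),
                   classify_pattern(scaled, seed = 1L))
})

test_that("constant summaries are refused as degenerate", {
  s <- pattern_setup(n = 60L, seed = 2L)
  flat <- s$mats$H3K4me1$WT; flat$values[] <- 2
  expect_error(classify_pattern(flat), "constant")
})

test_that("identical conditions give zero deltas and no transitions", {
  s <- pattern_setup(n = 150L, seed = 3L)
  calls <- classify_pattern(s$mats$H3K4me1$WT, seed = 1L)
  tc <- call_transitions(calls, calls,
                         k27_pair = list(s$mats$H3K27me3$WT, s$mats$H3K27me3$WT),
                         k4me1_pair = list(s$mats$H3K4me1$WT, s$mats$H3K4me1$WT),
                         loss_threshold = 1)
  expect_true(all(tc$h3k27me3_delta == 0))
  expect_true(all(tc$group == "none"))
  expect_false(any(tc$transition))
})

test_that("planted transition groups are recovered and counts conserve", {
  s <- pattern_setup()  # default NB noise
  c1 <- classify_pattern(s$mats$H3K4me1$WT, seed = 1L)
  c2 <- classify_pattern(s$mats$H3K4me1$KO, seed = 1L)
  tc <- call_transitions(c1, c2,
                         k27_pair = list(s$mats$H3K27me3$WT, s$mats$H3K27me3$KO),
                         k4me1_pair = list(s$mats$H3K4me1$WT, s$mats$H3K4me1$KO))
  expect_equal(sum(tc$group == "biloss") + sum(tc$group == "bigain") +
               sum(tc$group == "none"), nrow(tc))
  for (grp in c("biloss", "bigain")) {
    called <- tc$cgi_id[tc$group == grp]
    planted <- s$truth$cgi_id[s$truth$transition == grp]
    expect_gte(length(intersect(called, planted)) / length(called), 0.95)
    expect_gte(length(intersect(called, planted)) / length(planted), 0.95)
  }
  # every planted transition promoter also lost H3K27me3 (bivalent class)
  flagged <- tc$cgi_id[tc$transition]
  expect_gte(mean(s$truth$transition[match(flagged, s$truth$cgi_id)] != "none"), 0.95)
})

test_that("a globally abolished KO H3K27me3 flags every bivalent promoter as loss", {
  s <- pattern_setup(n = 150L, seed = 3L)
  zero <- s$mats$H3K27me3$KO; zero$values[] <- 0
  c1 <- classify_pattern(s$mats$H3K4me1$WT, seed = 1L)
  c2 <- classify_pattern(s$mats$H3K4me1$KO, seed = 1L)
  tc <- call_transitions(c1, c2, k27_pair = list(s$mats$H3K27me3$WT, zero))
  biv <- s$truth$cgi_id[s$truth$class == "bivalent"]
  expect_true(all(tc$h3k27me3_loss[match(biv, tc$cgi_id)]))
})

mk_transitions <- function(groups) {
  structure(data.frame(cgi_id = names(groups), group = unname(groups),
                       transition = groups != "none", stringsAsFactors = FALSE),
            class = c("transition_calls", "data.frame"))
}

test_that("the group contrast recovers a planted expression effect", {
  ids <- sprintf("c%03d", 1:400)
  groups <- setNames(rep(c("biloss", "bigain"), each = 200L), ids)
  prom <- data.frame(cgi_id = ids, gene_id = sub("c", "g", ids),
                     stringsAsFactors = FALSE)
  withr::with_seed(99L, {
    de <- data.frame(gene = prom$gene_id,
                     log2FoldChange = c(rnorm(200L, 0.5, 0.3), rnorm(200L, 2, 0.3)),
                     pvalue = 1e-6, stringsAsFactors = FALSE)
  })
  # no gene is down-regulated under these planted means, so the up/down
  # contingency degenerates and the chi-squared is flagged undefined
  expect_warning(gc <- group_expression_contrast(mk_transitions(groups), prom, de),
                 "empty margin")
  expect_lt(gc$medians[["biloss"]], gc$medians[["bigain"]])
  expect_equal(gc$direction, "biloss_lower")
  expect_lt(gc$wilcoxon_p, 1e-10)
})

test_that("identical group distributions give a Wilcoxon p of 1", {
  ids <- sprintf("c%03d", 1:20)
  groups <- setNames(rep(c("biloss", "bigain"), each = 10L), ids)
  prom <- data.frame(cgi_id = ids, gene_id = sub("c", "g", ids),
                     stringsAsFactors = FALSE)
  de <- data.frame(gene = prom$gene_id, log2FoldChange = rep(seq(0.1, 1, 0.1), 2L),
                   pvalue = 0.5, stringsAsFactors = FALSE)
  gc <- suppressWarnings(group_expression_contrast(mk_transitions(groups), prom, de))
  expect_equal(gc$wilcoxon_p, 1)
})

test_that("the up/down-by-group chi-squared equals the closed form", {
  # biloss: 10 up / 40 down; bigain: 40 up / 10 down -> chi-squared 36
  ids <- sprintf("c%03d", 1:100)
  groups <- setNames(rep(c("biloss", "bigain"), each = 50L), ids)
  prom <- data.frame(cgi_id = ids, gene_id = sub("c", "g", ids),
                     stringsAsFactors = FALSE)
  lfc <- c(rep(2, 10L), rep(-2, 40L), rep(2, 40L), rep(-2, 10L))
  de <- data.frame(gene = prom$gene_id, log2FoldChange = lfc, pvalue = 0.01,
                   stringsAsFactors = FALSE)
  gc <- group_expression_contrast(mk_transitions(groups), prom, de)
  expect_equal(unname(gc$contingency["biloss", ]), c(10L, 40L))
  expect_equal(unname(gc$contingency["bigain", ]), c(40L, 10L))
  expect_equal(gc$chisq$statistic, 36)
})

test_that("a group with fewer than 3 genes yields undefined statistics with a warning", {
  ids <- c("c1", "c2", "c3", "c4")
  groups <- setNames(c("biloss", "biloss", "bigain", "none"), ids)
  prom <- data.frame(cgi_id = ids, gene_id = paste0("g", 1:4),
                     stringsAsFactors = FALSE)
  de <- data.frame(gene = prom$gene_id, log2FoldChange = 1, pvalue = 0.5,
                   stringsAsFactors = FALSE)
  expect_warning(gc <- group_expression_contrast(mk_transitions(groups), prom, de),
                 "fewer than 3")
  expect_true(is.na(gc$wilcoxon_p))
})
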