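test_that("ANOVA F-score matches the closed form and handles degeneracy", {
  # groups [1,2] vs [3,4]: MSB = 4, MSE = 0.5, F = 8 exactly
  m <- matrix(c(1, 2, 3, 4), 1)
  labels <- factor(c("a", "a", "b", "b"))
  expect_equal(breakclock:::f_scores_matrix(m, labels), 8.0)

  # identical values -> F = 0; equal group means -> F = 0 exactly
  expect_equal(breakclock:::f_scores_matrix(matrix(5, 1, 4), labels), 0)
  expect_equal(
    breakclock:::f_scores_matrix(matrix(c(1, 3, 3, 1), 1), labels), 0
  )
  # perfect separation with zero within-group variance -> Inf
  expect_equal(
    breakclock:::f_scores_matrix(matrix(c(1, 1, 2, 2), 1), labels), Inf
  )
})

test_that("F-scores agree with stats::oneway.test on random data", {
  withr::with_seed(11, {
    labels <- factor(rep(1:5, each = 6))
    m <- matrix(rnorm(200 * 30), 200, 30)
    f <- breakclock:::f_scores_matrix(m, labels)
    oracle <- apply(m, 1, function(v) {
      unname(stats::oneway.test(v ~ labels, var.equal = TRUE)$statistic)
    })
    expect_equal(f, oracle, tolerance = 1e-9)
  })
})

test_that("gene ranking is a permutation with deterministic tie-breaks", {
  md <- balanced_metadata()
  fm <- random_fm(md, n_genes = 40, seed = 2)
  # force an exact tie by duplicating a gene's values under two ids
  fm[2, -1] <- fm[1, -1]
  rk <- anova_f_scores(fm, md, target = "age")
  expect_setequal(rk$rank, seq_len(nrow(fm)))
  expect_true(all(diff(rk$f_score) <= 0))
  tied <- rk[rk$gene_id %in% c("g001", "g002"), ]
  expect_equal(tied$gene_id, c("g001", "g002"))  # ascending id on ties
  expect_equal(diff(tied$rank), 1L)

  # F-scores invariant under positive rescaling of a gene
  fm2 <- fm
  fm2[5, -1] <- fm2[5, -1] * 1000
  rk2 <- anova_f_scores(fm2, md, target = "age")
  expect_equal(rk2$gene_id, rk$gene_id)
})

test_that("Spearman screen calls signs and is monotone-invariant", {
  md <- balanced_metadata()
  fm <- random_fm(md, n_genes = 10, seed = 4)
  m <- as.matrix(fm[, -1])
  m[1, ] <- rank(md$age_months, ties.method = "first")   # increasing with age
  m[2, ] <- -m[1, ]
  m[3, ] <- 7                                            # constant
  fm[, -1] <- m
  scr <- spearman_age_screen(fm, md)
  expect_gt(scr$rho[1], 0.9)
  expect_equal(scr$sign[1:3], c("positive", "negative", "none"))
  expect_equal(scr$p[3], 1)

  # strictly monotone transform leaves rho unchanged
  fm_t <- fm
  fm_t[, -1] <- exp(as.matrix(fm[, -1]) / 50)
  scr_t <- spearman_age_screen(fm_t, md)
  expect_equal(scr_t$rho, scr$rho)

  # rho matches the mid-rank Spearman computed by stats::cor
  expect_equal(scr$rho[4], cor(m[4, ], md$age_months, method = "spearman"))
})

test_that("per-tissue correlation ranges are max minus min", {
  md <- balanced_metadata(tissues = c("t1", "t2", "t3"), n_per_cell = 2)
  fm <- random_fm(md, n_genes = 12, seed = 5)
  res <- per_tissue_correlation_range(fm, md)
  rho_cols <- as.matrix(res[, grep("^rho_", names(res))])
  expect_equal(res$range, apply(rho_cols, 1, max) - apply(rho_cols, 1, min))
  expect_true(all(res$range >= 0))
  expect_true(all(abs(rho_cols) <= 1))

  # a gene tracking age identically in every tissue has range ~0
  fm2 <- fm
  fm2[1, -1] <- as.list(as.numeric(rank(md$age_months, ties.method = "average")) +
    seq_len(nrow(md)) * 1e-9)
  res2 <- per_tissue_correlation_range(fm2, md)
  expect_lt(res2$range[1], 1e-6)

  md1 <- dplyr::mutate(md, tissue = "t1")
  expect_warning(res1 <- per_tissue_correlation_range(fm, md1), "single tissue")
  expect_true(all(res1$range == 0))
})

test_that("range comparison reproduces the closed-form ANOVA oracle", {
  # groups {1,2},{3,4},{5,6}: MSB = 8, MSE = 0.5, F = 16
  out <- compare_ranges(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
  expect_equal(out$anova_f, 16.0)
  expect_equal(nrow(out$tukey), 3L)
  expect_true(all(out$tukey$p_adj >= 0 & out$tukey$p_adj <= 1))

  # identical groups -> degenerate convention
  same <- compare_ranges(list(a = c(1, 2), b = c(1, 2)))
  expect_equal(same$anova_f, 0)
  expect_equal(same$anova_p, 1)
  expect_equal(same$tukey$p_adj, 1)

  # argument order does not change the pairwise p-values
  o1 <- compare_ranges(list(x = c(1, 2, 3), y = c(4, 5, 7)))
  o2 <- compare_ranges(list(y = c(4, 5, 7), x = c(1, 2, 3)))
  expect_equal(sort(o1$tukey$p_adj), sort(o2$tukey$p_adj))
  expect_equal(o1$anova_p, o2$anova_p)
})

test_that("top-k gene sets are nested and bounded", {
  md <- balanced_metadata()
  fm <- random_fm(md, n_genes = 60, seed = 6)
  rk <- anova_f_scores(fm, md, "age")
  sets <- top_k_gene_sets(rk, sizes = c(5, 15, 40))
  expect_equal(lengths(sets), c(top_5 = 5L, top_15 = 15L, top_40 = 40L))
  expect_true(all(sets$top_5 %in% sets$top_15))
  expect_true(all(sets$top_15 %in% sets$top_40))
  expect_equal(top_k_gene_sets(rk, sizes = 60)$top_60, rk$gene_id)
  expect_error(top_k_gene_sets(rk, sizes = c(10, 100)), "exceeds")
})

test_that("hypergeometric overlap test matches brute-force enumeration", {
  expect_equal(overlap_test(c("a", "b"), c("c", "d"), 100)$p, 1)

  a <- sprintf("g%02d", 1:10)
  res <- overlap_test(a, a, 100)
  expect_equal(res$overlap, 10L)
  expect_equal(res$p, 1 / choose(100, 10))

  # brute-force upper tail: |A| = 4 draws, |B| = 6 marked, universe 20
  brute <- sum(vapply(2:4, function(x) {
    choose(6, x) * choose(14, 4 - x) / choose(20, 4)
  }, numeric(1)))
  res2 <- overlap_test(c("m1", "m2", "n1", "n2"),
                       c("m1", "m2", "m3", "m4", "m5", "m6"), 20)
  expect_equal(res2$overlap, 2L)
  expect_equal(res2$p, brute)

  # A = universe: overlap = |B|, p = 1
  universe <- sprintf("u%02d", 1:15)
  res3 <- overlap_test(universe, universe[1:4], 15)
  expect_equal(res3$overlap, 4L)
  expect_equal(res3$p, 1)
})
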