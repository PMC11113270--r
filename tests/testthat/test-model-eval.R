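test_that("regression adapter maps predictions to nearest classes", {
  cv <- c(3, 12, 19, 22, 24)
  s <- regression_adapter(c(12, 15.5, 23.9), cv)
  expect_equal(colnames(s), as.character(cv))
  expect_equal(rowSums(s), rep(1, 3))
  pred <- attr(s, "predicted")
  expect_equal(pred[1], 2L)           # exact class value
  expect_equal(pred[2], 2L)           # equidistant 12/19 -> lower class
  expect_equal(pred[3], 5L)
  expect_equal(apply(s, 1, which.max)[1], 2L)

  # monotone predictions off-scale still order the classes correctly
  truth <- factor(c(3, 12, 19, 22, 24), levels = cv)
  s2 <- regression_adapter(c(4, 11, 18, 22.4, 30), cv)
  metrics <- compute_classification_metrics(
    truth, s2, cv, predicted = attr(s2, "predicted")
  )
  expect_equal(metrics$spearman, 1)
})

test_that("classification metrics match hand-computable cases", {
  truth <- factor(c("a", "a", "b", "c"), levels = c("a", "b", "c"))
  perfect <- diag(3)[c(1, 1, 2, 3), ]
  colnames(perfect) <- c("a", "b", "c")
  m <- compute_classification_metrics(truth, perfect)
  expect_equal(m$auc, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$mae, 0)
  expect_equal(m$spearman, 1)

  # uniform scores: AUC 0.5 for every class under mid-rank ties
  uniform <- matrix(1 / 3, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(compute_classification_metrics(truth, uniform)$auc, 0.5)
})

test_that("binary AUC equals the brute-force Mann-Whitney statistic", {
  withr::with_seed(9, {
    for (i in 1:10) {
      scores <- round(rnorm(30), 1)  # rounding forces ties
      pos <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(.4, .6))
      if (!any(pos) || all(pos)) next
      brute <- mean(outer(scores[pos], scores[!pos], function(a, b) {
        (a > b) + 0.5 * (a == b)
      }))
      expect_equal(breakclock:::binary_auc(scores, pos), brute)
    }
  })
})

test_that("MAE of zero implies perfect macro F1 under class-index encoding", {
  withr::with_seed(21, {
    for (i in 1:20) {
      k <- sample(3:5, 1)
      truth <- factor(sample(letters[1:k], 40, replace = TRUE),
                      levels = letters[1:k])
      scores <- matrix(runif(40 * k), 40, k,
                       dimnames = list(NULL, letters[1:k]))
      m <- compute_classification_metrics(truth, scores)
      if (m$mae == 0) expect_equal(m$f1, 1)
      expect_true(m$auc >= 0 && m$auc <= 1)
      expect_true(m$f1 >= 0 && m$f1 <= 1)
      expect_gte(m$mae, 0)
    }
  })
})

test_that("stratified splits keep every class in train and test", {
  labels <- factor(rep(letters[1:5], times = c(7, 7, 6, 6, 4)))
  withr::with_seed(2, {
    for (i in 1:20) {
      tr <- breakclock:::draw_split(labels, 0.8, "stratified")
      te <- setdiff(seq_along(labels), tr)
      expect_setequal(unique(labels[tr]), levels(labels))
      expect_setequal(unique(labels[te]), levels(labels))
    }
    trp <- breakclock:::draw_split(labels, 0.8, "plain")
    expect_setequal(unique(labels[trp]), levels(labels))
  })
})

test_that("evaluation is bit-reproducible from the master seed", {
  md <- balanced_metadata()
  fm <- random_fm(md, n_genes = 40, n_signal = 0, seed = 7)
  cfg <- eval_config(method_id = "rf", target = "age", n_iterations = 4,
                     seed = 99)
  r1 <- run_evaluation(fm, md, gene_set = fm$gene_id[1:20], config = cfg)
  r2 <- run_evaluation(fm, md, gene_set = fm$gene_id[1:20], config = cfg)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(glance(r1), glance(r2))

  cfg2 <- eval_config(method_id = "rf", target = "age", n_iterations = 4,
                      seed = 100)
  r3 <- run_evaluation(fm, md, gene_set = fm$gene_id[1:20], config = cfg2)
  expect_false(identical(tidy(r1), tidy(r3)))
})

test_that("every model family runs and separates a strong signal", {
  md <- balanced_metadata(ages = c(3, 12, 24), tissues = c("t1", "t2"),
                          n_per_cell = 4)
  fm <- random_fm(md, n_genes = 25, n_signal = 20, effect = 4, seed = 13)
  for (meth in model_families()) {
    cfg <- eval_config(method_id = meth, target = "age", n_iterations = 3,
                       seed = 5)
    g <- glance(run_evaluation(fm, md, gene_set = fm$gene_id, config = cfg))
    expect_true(is.finite(g$mean_auc), info = meth)
    expect_true(g$mean_auc >= 0 && g$mean_auc <= 1, info = meth)
    expect_gte(g$mean_mae, 0)
  }
  # a strongly separable signal is found by the flagship classifier
  cfg <- eval_config(method_id = "logreg", target = "age", n_iterations = 5,
                     seed = 5)
  g <- glance(run_evaluation(fm, md, gene_set = fm$gene_id, config = cfg))
  expect_gte(g$mean_auc, 0.9)
})

test_that("months encoding changes MAE scale but not AUC", {
  md <- balanced_metadata()
  fm <- random_fm(md, n_genes = 30, n_signal = 15, effect = 3, seed = 17)
  cfg_i <- eval_config("logreg", "age", n_iterations = 5, seed = 1)
  cfg_m <- eval_config("logreg", "age", n_iterations = 5, seed = 1,
                       label_encoding = "months")
  gi <- glance(run_evaluation(fm, md, fm$gene_id, cfg_i))
  gm <- glance(run_evaluation(fm, md, fm$gene_id, cfg_m))
  expect_equal(gi$mean_auc, gm$mean_auc)
  expect_gte(gm$mean_mae, gi$mean_mae)  # months gaps are >= index gaps
})

test_that("evaluation grid reports tiers and max mean AUC per method", {
  md <- balanced_metadata()
  fm <- random_fm(md, n_genes = 40, n_signal = 10, effect = 3, seed = 23)
  rk <- anova_f_scores(fm, md, "age")
  grid <- evaluate_grid(
    list(LPKM_SSB = fm), md, rankings = list(LPKM_SSB = rk),
    sizes = c(10, 30), methods = c("logreg", "gnb"),
    config = eval_config(n_iterations = 3, seed = 12)
  )
  expect_equal(nrow(grid$results), 2 * 3 * 1)  # 2 methods x 3 sets
  expect_equal(nrow(grid$tiers), 2L)
  expect_true(all(grid$tiers$tier %in% c("I", "II")))
  expect_equal(
    sort(unique(grid$results$set_name)),
    sort(c("top_10", "top_30", "all"))
  )
  by_m <- dplyr::filter(grid$results, set_name != "all") |>
    dplyr::group_by(method_id) |>
    dplyr::summarise(mx = max(mean_auc))
  expect_equal(
    dplyr::arrange(grid$tiers, method_id)$max_mean_auc,
    dplyr::arrange(by_m, method_id)$mx
  )
})

test_that("fixed-set comparison beats random sets on planted signal", {
  md <- balanced_metadata()
  fm <- random_fm(md, n_genes = 60, n_signal = 10, effect = 3, seed = 31)
  planted <- fm$gene_id[1:10]
  cfg <- eval_config("logreg", "age", n_iterations = 4, seed = 3)
  cmp <- ddr_comparison(fm, md, planted, config = cfg, n_random_sets = 4)
  expect_gt(cmp$t_test$mean_a, cmp$t_test$mean_b)
  expect_true(cmp$t_test$p >= 0 && cmp$t_test$p <= 1)
  expect_warning(
    ddr_comparison(fm, md, planted, config = cfg, n_random_sets = 1),
    "power"
  )
  expect_error(
    ddr_comparison(fm, md, c("nope"), config = cfg, n_random_sets = 2),
    "absent"
  )
})

test_that("t-test comparison handles degenerate and symmetric input", {
  expect_equal(compare_metric_performance(rep(0.8, 10), rep(0.8, 10))$p, 1)
  expect_equal(compare_metric_performance(rep(0.9, 10), rep(0.5, 10))$p, 0)
  withr::with_seed(3, {
    a <- 0.9 + rnorm(50, 0, 1e-3)
    b <- 0.5 + rnorm(50, 0, 1e-3)
    res <- compare_metric_performance(a, b)
    expect_lt(res$p, 1e-10)
    res_swap <- compare_metric_performance(b, a)
    expect_equal(res$p, res_swap$p)
    expect_equal(res$t, -res_swap$t)
  })
})
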