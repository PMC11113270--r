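# The ten model families used for age / tissue prediction.
#
# Each family is a list(fit = function(x, y_factor, y_numeric), predict =
# function(fit, x) -> samples x classes score matrix with columns in
# levels(y_factor) order). Classifiers return class probabilities;
# regressors return continuous predictions that run_evaluation turns into
# class scores with regression_adapter(). All stochastic fits consume the
# iteration RNG stream, so results are reproducible from the master seed.

#' Supported model family identifiers
#'
#' `logreg` ridge-penalized multinomial logistic regression (glmnet,
#' alpha = 0, lambda = 1/n); `rf` random forest; `gnb` Gaussian naive Bayes;
#' `hist_gbm` histogram gradient boosting (xgboost, `tree_method = "hist"`);
#' `reg_gbm` regularized gradient boosting (xgboost, exact splits);
#' `adaboost` multiclass AdaBoost (SAMME) over decision stumps; `lasso` / `enet` L1 /
#' mixed-penalty linear regression on the encoded label; `dtree_reg` /
#' `dtree_clf` fully grown decision trees.
#'
#' @return character vector of the ten method ids.
#' @export
model_families <- function() {
  c("logreg", "rf", "gnb", "hist_gbm", "reg_gbm",
    "adaboost", "lasso", "enet", "dtree_reg", "dtree_clf")
}

is_regressor <- function(method_id) {
  method_id %in% c("lasso", "enet", "dtree_reg")
}

fit_model <- function(method_id, x, y_factor, y_numeric) {
  k <- nlevels(y_factor)
  switch(method_id,
    logreg = withCallingHandlers(
      glmnet::glmnet(
        x, y_factor, family = "multinomial",
        alpha = 0, lambda = 1 / nrow(x), standardize = TRUE
      ),
      # small per-class counts are inherent to the 83-sample design;
      # glmnet warns about them on every fit
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    ),
    rf = randomForest::randomForest(x, y_factor),
    gnb = fit_gnb(x, y_factor),
    hist_gbm = fit_xgb(x, y_factor, tree_method = "hist", eta = 0.1),
    reg_gbm = fit_xgb(x, y_factor, tree_method = "exact", eta = 0.3),
    adaboost = fit_samme(x, y_factor, n_estimators = 50L),
    lasso = glmnet::glmnet(
      x, y_numeric, family = "gaussian",
      alpha = 1, lambda = 1, standardize = TRUE
    ),
    enet = glmnet::glmnet(
      x, y_numeric, family = "gaussian",
      alpha = 0.5, lambda = 1, standardize = TRUE
    ),
    dtree_reg = fit_rpart(x, y_numeric, method = "anova"),
    dtree_clf = fit_rpart(x, y_factor, method = "class"),
    abort(paste0("unknown method_id: ", method_id))
  )
}

predict_model <- function(method_id, fit, x, class_levels) {
  out <- switch(method_id,
    logreg = {
      p <- predict(fit, x, type = "response")[, , 1, drop = FALSE]
      dim(p) <- dim(p)[1:2]
      colnames(p) <- fit$classnames
      p[, class_levels, drop = FALSE]
    },
    rf = {
      p <- predict(fit, x, type = "prob")
      p[, class_levels, drop = FALSE]
    },
    gnb = predict_gnb(fit, x)[, class_levels, drop = FALSE],
    hist_gbm = ,
    reg_gbm = {
      p <- predict(fit$booster, xgboost::xgb.DMatrix(x))
      colnames(p) <- fit$class_levels
      p[, class_levels, drop = FALSE]
    },
    adaboost = predict_samme(fit, x)[, class_levels, drop = FALSE],
    lasso = ,
    enet = as.vector(predict(fit, x)),
    dtree_reg = unname(predict(fit$tree, as.data.frame(x))),
    dtree_clf = {
      p <- predict(fit$tree, as.data.frame(x), type = "prob")
      p[, class_levels, drop = FALSE]
    },
    abort(paste0("unknown method_id: ", method_id))
  )
  out
}

fit_xgb <- function(x, y_factor, tree_method, eta) {
  k <- nlevels(y_factor)
  d <- xgboost::xgb.DMatrix(x, label = as.integer(y_factor) - 1L)
  booster <- xgboost::xgb.train(
    params = list(
      objective = "multi:softprob", num_class = k,
      tree_method = tree_method, eta = eta, max_depth = 6,
      nthread = 1, seed = sample.int(1e6, 1)
    ),
    data = d, nrounds = 100, verbose = 0
  )
  list(booster = booster, class_levels = levels(y_factor))
}

# rpart grown without pruning or size floors (cp = 0, minsplit = 2,
# minbucket = 1, no cross-validation) so a tree can isolate every class.
fit_rpart <- function(x, y, method) {
  df <- as.data.frame(x)
  df$.y <- y
  list(tree = rpart::rpart(
    .y ~ ., data = df, method = method,
    control = rpart::rpart.control(
      minsplit = 2, minbucket = 1, cp = 0, xval = 0
    )
  ))
}

# Gaussian naive Bayes in log space. Per-class feature variances get the
# larger of an absolute 1e-9 floor and 1e-9 x the largest feature variance,
# so constant features within a class cannot produce degenerate densities.
fit_gnb <- function(x, y_factor) {
  lv <- levels(y_factor)
  mu <- vapply(lv, function(l) colMeans(x[y_factor == l, , drop = FALSE]),
               numeric(ncol(x)))
  v <- vapply(lv, function(l) {
    xs <- x[y_factor == l, , drop = FALSE]
    colMeans(sweep(xs, 2, colMeans(xs))^2)
  }, numeric(ncol(x)))
  eps <- max(1e-9, 1e-9 * max(v))
  list(
    class_levels = lv,
    prior = as.vector(table(y_factor)) / length(y_factor),
    mu = mu, var = v + eps
  )
}

predict_gnb <- function(fit, x) {
  ll <- vapply(seq_along(fit$class_levels), function(j) {
    mu <- fit$mu[, j]
    v <- fit$var[, j]
    rowSums(-0.5 * (log(2 * pi * v[col(x)]) +
                      (sweep(x, 2, mu))^2 / v[col(x)]))
  }, numeric(nrow(x)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = nrow(x))
  ll <- ll + matrix(log(fit$prior), nrow(x), length(fit$prior), byrow = TRUE)
  p <- exp(ll - apply(ll, 1, max))
  p <- p / rowSums(p)
  colnames(p) <- fit$class_levels
  p
}

# Multiclass AdaBoost (discrete SAMME) over decision stumps. Each round
# fits a one-threshold stump by weighted Gini, reweights misclassified
# samples by exp(alpha) with alpha = log((1-err)/err) + log(K-1), and the
# ensemble scores are softmaxed alpha-weighted votes. Boosting stops early
# when a stump is perfect (it then carries the whole vote) or no better
# than chance.
fit_samme <- function(x, y_factor, n_estimators = 50L) {
  n <- nrow(x)
  k <- nlevels(y_factor)
  lv <- levels(y_factor)
  y_idx <- as.integer(y_factor)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric()
  for (b in seq_len(n_estimators)) {
    stump <- fit_stump(x, y_idx, k, w)
    pred <- predict_stump(stump, x)
    err <- sum(w[pred != y_idx])
    if (err <= 0) {
      stumps <- list(stump)
      alphas <- 1
      break
    }
    if (err >= 1 - 1 / k) break
    alpha <- log((1 - err) / err) + log(k - 1)
    stumps[[length(stumps) + 1L]] <- stump
    alphas[length(alphas) + 1L] <- alpha
    w <- w * exp(alpha * (pred != y_idx))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, class_levels = lv,
       fallback = as.integer(names(which.max(table(y_idx)))))
}

predict_samme <- function(fit, x) {
  lv <- fit$class_levels
  k <- length(lv)
  score <- matrix(0, nrow(x), k, dimnames = list(NULL, lv))
  if (length(fit$stumps) == 0) {
    score[, fit$fallback] <- 1
  } else {
    for (b in seq_along(fit$stumps)) {
      pred <- predict_stump(fit$stumps[[b]], x)
      score[cbind(seq_len(nrow(x)), pred)] <-
        score[cbind(seq_len(nrow(x)), pred)] + fit$alphas[b]
    }
  }
  p <- exp(sweep(score, 1, apply(score, 1, max)))
  p / rowSums(p)
}

# Best single-feature threshold split by weighted Gini (maximizing
# sum_k w_k^2 / w_side over both sides); each side predicts its
# weighted-majority class. Falls back to a no-split majority stump when no
# feature has two distinct values.
fit_stump <- function(x, y_idx, k, w) {
  n <- nrow(x)
  onehot <- matrix(0, n, k)
  onehot[cbind(seq_len(n), y_idx)] <- w
  total <- colSums(onehot)
  best <- list(score = -Inf, feature = NA_integer_, threshold = NA_real_)
  # random feature order so exact ties break randomly across boosting
  # rounds; otherwise boosting can lock into a short cycle of stumps
  for (j in sample.int(ncol(x))) {
    xj <- x[, j]
    ord <- order(xj)
    xs <- xj[ord]
    valid <- which(diff(xs) > 0)          # cuts between distinct values
    if (length(valid) == 0) next
    cl <- apply(onehot[ord, , drop = FALSE], 2, cumsum)
    wl <- rowSums(cl)[valid]
    left2 <- rowSums(cl^2)[valid]
    right2 <- rowSums(sweep(cl, 2, total, function(a, b) (b - a)^2))[valid]
    sc <- left2 / wl + right2 / (sum(total) - wl)
    i <- which.max(sc)
    if (sc[i] > best$score) {
      cut <- valid[i]
      best <- list(
        score = sc[i], feature = j,
        threshold = (xs[cut] + xs[cut + 1]) / 2,
        left_counts = cl[cut, ],
        right_counts = total - cl[cut, ]
      )
    }
  }
  if (!is.finite(best$score)) {
    maj <- which.max(total)
    return(list(feature = 1L, threshold = Inf,
                left_class = maj, right_class = maj))
  }
  list(
    feature = best$feature,
    threshold = best$threshold,
    left_class = which.max(best$left_counts),
    right_class = which.max(best$right_counts)
  )
}

predict_stump <- function(stump, x) {
  ifelse(x[, stump$feature] <= stump$threshold,
         stump$left_class, stump$right_class)
}
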