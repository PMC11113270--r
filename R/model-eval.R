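#' Configuration for the repeated random-split evaluation
#'
#' The study protocol: draw a random 80/20 train/test split of the samples,
#' fit one model family on the training columns restricted to a gene set,
#' score the held-out samples, compute one-vs-rest macro AUC, macro F1, MAE
#' and Spearman correlation, and repeat (default 100 times), reporting
#' per-iteration values and their means.
#'
#' @param method_id one of [model_families()].
#' @param target `"age"` or `"tissue"`.
#' @param train_fraction fraction of samples used for training, default 0.8.
#' @param n_iterations number of random splits, default 100.
#' @param seed master seed; every iteration derives its split and model seed
#'   from it, so results are reproducible bit-for-bit.
#' @param label_encoding `"class_index"` (0, 1, ...; default) or `"months"`
#'   (numeric labels) for MAE and Spearman.
#' @param split_mode `"stratified"` (default; every class appears in train
#'   and test) or `"plain"` (the literal protocol: simple random 80%;
#'   degenerate splits are re-drawn, at most 100 times).
#' @param selection_mode `"full_data"` (default; gene set fixed upfront from
#'   a ranking on all samples, mirroring the study's order of operations) or
#'   `"within_train"` (the leakage-free alternative: the ANOVA ranking and
#'   top-k selection are recomputed inside every training split).
#' @return an `eval_config` list.
#' @export
eval_config <- function(method_id = "logreg",
                        target = c("age", "tissue"),
                        train_fraction = 0.8,
                        n_iterations = 100L,
                        seed = 1L,
                        label_encoding = c("class_index", "months"),
                        split_mode = c("stratified", "plain"),
                        selection_mode = c("full_data", "within_train")) {
  stopifnot(method_id %in% model_families())
  stopifnot(train_fraction > 0, train_fraction < 1, n_iterations >= 1)
  structure(
    list(
      method_id = method_id,
      target = match.arg(target),
      train_fraction = train_fraction,
      n_iterations = as.integer(n_iterations),
      seed = as.integer(seed),
      label_encoding = match.arg(label_encoding),
      split_mode = match.arg(split_mode),
      selection_mode = match.arg(selection_mode)
    ),
    class = "eval_config"
  )
}

# One train/test split over sample indices, given class labels.
draw_split <- function(labels, train_fraction, split_mode) {
  n <- length(labels)
  if (split_mode == "stratified") {
    train <- unlist(lapply(levels(labels), function(l) {
      idx <- which(labels == l)
      n_tr <- min(max(round(train_fraction * length(idx)), 1L),
                  length(idx) - 1L)
      idx[sample.int(length(idx), n_tr)]
    }))
    return(sort(train))
  }
  for (attempt in seq_len(100L)) {
    train <- sort(sample.int(n, round(train_fraction * n)))
    test <- setdiff(seq_len(n), train)
    if (all(levels(labels) %in% labels[train]) &&
        all(levels(labels) %in% labels[test])) {
      return(train)
    }
  }
  abort("could not draw a plain split containing every class in 100 attempts")
}

#' Turn continuous predictions into class scores
#'
#' Regression model families predict a continuous value; classification
#' metrics need per-class scores. The score for class k is
#' `-|prediction - class_value_k|` passed through a row softmax; the
#' predicted class is the nearest class value, ties resolved to the lower
#' class.
#'
#' @param predictions numeric vector of continuous predictions.
#' @param class_values ascending numeric values encoding the classes.
#' @return samples x classes score matrix (rows sum to 1), with a
#'   `"predicted"` attribute holding the nearest-class index per sample.
#' @export
regression_adapter <- function(predictions, class_values) {
  stopifnot(!is.unsorted(class_values, strictly = TRUE))
  d <- abs(outer(predictions, class_values, "-"))
  pred_idx <- apply(d, 1, which.min)  # which.min takes the first (lower) tie
  s <- exp(-d - apply(-d, 1, max))
  s <- s / rowSums(s)
  colnames(s) <- as.character(class_values)
  attr(s, "predicted") <- pred_idx
  s
}

#' Classification metrics from class scores
#'
#' One-vs-rest macro-averaged multiclass AUC (rank-based, mid-rank tie
#' handling, so uniform scores give 0.5), macro F1 on argmax predictions,
#' MAE and Spearman correlation between encoded predictions and truth.
#' Classes absent from the truth are skipped in the macro averages.
#'
#' @param true_labels factor (or vector) of true classes.
#' @param class_scores samples x classes score matrix; column order must
#'   match `label_values`.
#' @param label_values numeric encoding of the classes (ascending), used for
#'   MAE/Spearman; defaults to the 0-based class index.
#' @param predicted optional integer vector of predicted class indices;
#'   defaults to the per-row argmax of `class_scores` (ties to the lower
#'   class).
#' @return one-row tibble with `auc`, `f1`, `mae`, `spearman`.
#' @export
compute_classification_metrics <- function(true_labels, class_scores,
                                           label_values = NULL,
                                           predicted = NULL) {
  k <- ncol(class_scores)
  if (is.null(label_values)) label_values <- seq_len(k) - 1
  stopifnot(length(label_values) == k)
  true_idx <- if (is.factor(true_labels)) {
    as.integer(true_labels)
  } else {
    match(true_labels, colnames(class_scores))
  }
  if (anyNA(true_idx)) abort("true labels not aligned with score columns")
  if (is.null(predicted)) {
    predicted <- apply(class_scores, 1, which.max)  # first max = lower class
  }

  present <- sort(unique(true_idx))
  aucs <- map_dbl(present, function(j) {
    pos <- true_idx == j
    if (all(pos)) return(NA_real_)
    binary_auc(class_scores[, j], pos)
  })
  f1s <- map_dbl(present, function(j) {
    tp <- sum(predicted == j & true_idx == j)
    fp <- sum(predicted == j & true_idx != j)
    fn <- sum(predicted != j & true_idx == j)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  })
  enc_true <- label_values[true_idx]
  enc_pred <- label_values[predicted]
  sp <- if (sd(enc_true) == 0 || sd(enc_pred) == 0) {
    0
  } else {
    cor(enc_pred, enc_true, method = "spearman")
  }
  tibble(
    auc = mean(aucs, na.rm = TRUE),
    f1 = mean(f1s),
    mae = mean(abs(enc_pred - enc_true)),
    spearman = sp
  )
}

# Rank-based (Mann-Whitney) binary AUC with mid-rank ties.
binary_auc <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run the repeated random-split evaluation
#'
#' @param fm feature-matrix tibble.
#' @param metadata metadata tibble.
#' @param gene_set character vector of gene ids to use as features
#'   (`selection_mode = "full_data"`), or `NULL` with `gene_set_size` under
#'   `"within_train"`.
#' @param config an [eval_config()].
#' @param gene_set_size top-k size for within-train ANOVA selection; `"all"`
#'   uses every gene.
#' @return a `break_eval` object; see [tidy()] / [glance()] for per-iteration
#'   values and aggregates.
#' @export
run_evaluation <- function(fm, metadata, gene_set = NULL, config = eval_config(),
                           gene_set_size = NULL) {
  stopifnot(inherits(config, "eval_config"))
  m <- fm_values(fm)
  md <- metadata[match(colnames(m), metadata$sample_id), ]
  if (anyNA(md$sample_id)) abort("metadata missing for some samples")
  raw <- if (config$target == "age") md$age_months else md$tissue
  class_values <- sort(unique(raw))
  labels <- factor(raw, levels = class_values)
  if (any(table(labels) < 2)) abort("every class needs >= 2 samples")
  label_values <- if (config$label_encoding == "months") {
    if (!is.numeric(class_values)) {
      abort("label_encoding = 'months' requires a numeric target")
    }
    as.numeric(class_values)
  } else {
    seq_along(class_values) - 1
  }

  if (config$selection_mode == "full_data") {
    if (is.null(gene_set)) abort("gene_set required under full_data selection")
    miss <- setdiff(gene_set, rownames(m))
    if (length(miss) > 0) {
      abort(paste0("gene_set not in matrix: ", paste(head(miss, 5), collapse = ", ")))
    }
  } else if (is.null(gene_set_size)) {
    abort("gene_set_size required under within_train selection")
  }

  iter_seeds <- withr::with_seed(
    config$seed,
    sample.int(.Machine$integer.max - 1L, config$n_iterations)
  )
  iterations <- map(seq_len(config$n_iterations), function(i) {
    withr::with_seed(iter_seeds[i], {
      train <- draw_split(labels, config$train_fraction, config$split_mode)
      test <- setdiff(seq_along(labels), train)
      genes_used <- if (config$selection_mode == "full_data") {
        gene_set
      } else if (identical(gene_set_size, "all")) {
        rownames(m)
      } else {
        f <- f_scores_matrix(m[, train, drop = FALSE], labels[train])
        ord <- order(-f, rownames(m))
        rownames(m)[ord][seq_len(gene_set_size)]
      }
      x_tr <- t(m[genes_used, train, drop = FALSE])
      x_te <- t(m[genes_used, test, drop = FALSE])
      y_tr <- droplevels(labels[train])
      fit <- fit_model(config$method_id, x_tr, y_tr,
                       label_values[as.integer(labels[train])])
      out <- predict_model(config$method_id, fit, x_te,
                           class_levels = levels(y_tr))
      if (is_regressor(config$method_id)) {
        scores <- regression_adapter(out, label_values)
        # scores span all configured classes, not just those in train
        metrics <- compute_classification_metrics(
          labels[test], scores, label_values,
          predicted = attr(scores, "predicted")
        )
      } else {
        # map trained-class scores back into the full class set
        scores <- matrix(0, nrow(x_te), length(class_values),
                         dimnames = list(NULL, as.character(class_values)))
        scores[, colnames(out)] <- out
        metrics <- compute_classification_metrics(labels[test], scores,
                                                  label_values)
      }
      mutate(metrics, iteration = i, .before = 1)
    })
  }) |> list_rbind()

  structure(
    list(
      iterations = iterations,
      config = config,
      provenance = list(
        gene_set_size = if (!is.null(gene_set)) length(gene_set) else gene_set_size,
        n_samples = ncol(m),
        n_classes = length(class_values)
      )
    ),
    class = "break_eval"
  )
}

#' @export
print.break_eval <- function(x, ...) {
  g <- glance(x)
  cat(
    "<break_eval> ", x$config$method_id, " / ", x$config$target,
    ", ", nrow(x$iterations), " iterations, gene set size ",
    x$provenance$gene_set_size %||% NA, "\n",
    sprintf(
      "  mean AUC %.3f | F1 %.3f | MAE %.3f | Spearman %.3f\n",
      g$mean_auc, g$mean_f1, g$mean_mae, g$mean_spearman
    ),
    sep = ""
  )
  invisible(x)
}

#' Tidy per-iteration evaluation results
#' @param x a `break_eval` object.
#' @param ... unused.
#' @return tibble with one row per iteration (`auc`, `f1`, `mae`,
#'   `spearman`).
#' @method tidy break_eval
#' @export
tidy.break_eval <- function(x, ...) {
  x$iterations
}

#' One-row evaluation summary
#' @param x a `break_eval` object.
#' @param ... unused.
#' @return one-row tibble with the method, target, gene set size and the
#'   means of the four metrics over iterations.
#' @method glance break_eval
#' @export
glance.break_eval <- function(x, ...) {
  tibble(
    method_id = x$config$method_id,
    target = x$config$target,
    gene_set_size = as.character(x$provenance$gene_set_size %||% NA),
    n_iterations = nrow(x$iterations),
    mean_auc = mean(x$iterations$auc),
    mean_f1 = mean(x$iterations$f1),
    mean_mae = mean(x$iterations$mae),
    mean_spearman = mean(x$iterations$spearman)
  )
}

#' Factorial evaluation over metrics, gene sets and methods
#'
#' Runs [run_evaluation()] for every (metric, gene set, method) combination,
#' appends the "all genes" set, and reports per (method, metric) the maximum
#' over gene sets of the mean AUC together with a tier flag: Tier I methods
#' peak at the largest ranked gene set, Tier II methods peak at an interior
#' size.
#'
#' @param matrices named list of feature-matrix tibbles (one per metric).
#' @param metadata metadata tibble.
#' @param rankings named list of [anova_f_scores()] tibbles aligned with
#'   `matrices` (for the configured target).
#' @param sizes gene-set sizes (see [top_k_gene_sets()]).
#' @param methods method ids to run, default all ten.
#' @param config base [eval_config()]; its `method_id` is overridden.
#' @param include_all_genes append the 11th "all genes" set, default TRUE.
#' @return list with `results` (one row per metric x method x gene set, the
#'   [glance()] columns) and `tiers` (per metric x method: `max_mean_auc`,
#'   `best_size`, `tier`).
#' @export
evaluate_grid <- function(matrices, metadata, rankings,
                          sizes = c(15, 25, 50, 75, 100, 150, 200, 300, 400, 500),
                          methods = model_families(),
                          config = eval_config(),
                          include_all_genes = TRUE) {
  stopifnot(is.list(matrices), !is.null(names(matrices)))
  stopifnot(all(names(matrices) %in% names(rankings)))
  results <- imap(matrices, function(fm, metric) {
    sets <- top_k_gene_sets(rankings[[metric]], sizes)
    if (include_all_genes) sets <- c(sets, list(all = fm$gene_id))
    imap(sets, function(gs, set_name) {
      map(methods, function(meth) {
        cfg <- config
        cfg$method_id <- meth
        res <- run_evaluation(fm, metadata, gene_set = gs, config = cfg)
        glance(res) |>
          mutate(
            metric = metric, set_name = set_name,
            set_size = length(gs), .before = 1
          )
      }) |> list_rbind()
    }) |> list_rbind()
  }) |> list_rbind()

  ranked <- filter(results, .data$set_name != "all")
  tiers <- ranked |>
    group_by(.data$metric, .data$method_id) |>
    summarise(
      max_mean_auc = max(.data$mean_auc),
      best_size = .data$set_size[which.max(.data$mean_auc)],
      tier = if_else(.data$best_size == max(.data$set_size), "I", "II"),
      .groups = "drop"
    )
  list(results = results, tiers = tiers)
}

#' Compare a fixed gene set against random gene sets of equal size
#'
#' Evaluates a user-supplied gene set (for example DNA damage response
#' genes) with the configured method, then draws `n_random_sets` random gene
#' sets of the same size from the matrix's (expressed) genes, evaluates
#' each, and compares the per-iteration AUC of the fixed set against the
#' pooled AUCs of the random sets with a two-tailed t-test.
#'
#' @param fm feature-matrix tibble (already filtered to expressed genes).
#' @param metadata metadata tibble.
#' @param gene_set the fixed gene set (subset of `fm$gene_id`).
#' @param config [eval_config()].
#' @param n_random_sets number of random gene sets, default 100.
#' @return list with `fixed` (break_eval), `random_auc` (per random set x
#'   iteration tibble), `t_test` (tibble: mean difference and p).
#' @export
ddr_comparison <- function(fm, metadata, gene_set, config = eval_config(),
                           n_random_sets = 100L) {
  miss <- setdiff(gene_set, fm$gene_id)
  if (length(miss) > 0) {
    abort(paste0(
      "gene set members absent from the matrix: ",
      paste(head(miss, 5), collapse = ", ")
    ))
  }
  if (n_random_sets < 2) {
    warn("fewer than 2 random sets gives the t-test very little power")
  }
  fixed <- run_evaluation(fm, metadata, gene_set = gene_set, config = config)
  set_seeds <- withr::with_seed(
    config$seed + 1L,
    sample.int(.Machine$integer.max - 1L, n_random_sets)
  )
  random_auc <- map(seq_len(n_random_sets), function(s) {
    rs <- withr::with_seed(
      set_seeds[s],
      sample(fm$gene_id, length(gene_set))
    )
    cfg <- config
    cfg$seed <- set_seeds[s]
    res <- run_evaluation(fm, metadata, gene_set = rs, config = cfg)
    tibble(random_set = s, iteration = res$iterations$iteration,
           auc = res$iterations$auc)
  }) |> list_rbind()
  tt <- compare_metric_performance(fixed$iterations$auc, random_auc$auc)
  list(fixed = fixed, random_auc = random_auc, t_test = tt)
}

#' Two-tailed t-test between two AUC distributions
#'
#' Standard two-sample two-tailed Student/Welch t-test on per-iteration AUC
#' vectors. If both vectors are constant: p = 1 when the means are equal,
#' p = 0 otherwise (degenerate convention).
#'
#' @param auc_a,auc_b numeric vectors of per-iteration AUC values.
#' @return tibble with `mean_a`, `mean_b`, `t`, `p`.
#' @export
compare_metric_performance <- function(auc_a, auc_b) {
  stopifnot(length(auc_a) > 0, length(auc_b) > 0)
  if (sd(auc_a) == 0 && sd(auc_b) == 0) {
    eq <- isTRUE(all.equal(mean(auc_a), mean(auc_b)))
    return(tibble(
      mean_a = mean(auc_a), mean_b = mean(auc_b),
      t = if (eq) 0 else Inf, p = if (eq) 1 else 0
    ))
  }
  tt <- t.test(auc_a, auc_b, alternative = "two.sided")
  tibble(
    mean_a = mean(auc_a), mean_b = mean(auc_b),
    t = unname(tt$statistic), p = tt$p.value
  )
}
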