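#' Spearman screen for age-associated genes
#'
#' Per gene, the Spearman correlation between the feature values and numeric
#' age in months, with a two-sided p-value from the t approximation on
#' mid-rank correlations. A gene is called `positive`/`negative` when
#' `p < alpha` with the matching sign of rho; genes with zero variance get
#' `rho = 0`, `p = 1`, `sign = "none"`.
#'
#' @param fm feature-matrix tibble.
#' @param metadata metadata tibble with `sample_id`, `age_months`.
#' @param alpha significance level for the sign call, default 0.05.
#' @return tibble with `gene_id`, `rho`, `p`, `sign`.
#' @export
spearman_age_screen <- function(fm, metadata, alpha = 0.05) {
  m <- fm_values(fm)
  md <- metadata[match(colnames(m), metadata$sample_id), ]
  if (anyNA(md$sample_id)) abort("metadata missing for some samples")
  age <- md$age_months
  if (ncol(m) < 3) abort("need at least 3 samples for the Spearman screen")
  if (length(unique(age)) < 3) abort("need at least 3 distinct age values")
  res <- spearman_vs_covariate(m, age)
  tibble(
    gene_id = fm$gene_id,
    rho = res$rho,
    p = res$p,
    sign = case_when(
      res$constant ~ "none",
      res$p < alpha & res$rho > 0 ~ "positive",
      res$p < alpha & res$rho < 0 ~ "negative",
      TRUE ~ "none"
    )
  )
}

# Vectorized mid-rank Spearman of each matrix row against a covariate, with
# the two-sided t-approximation p-value. Constant rows get rho 0 / p 1.
spearman_vs_covariate <- function(m, x) {
  n <- ncol(m)
  rx <- rank(x)
  rm_ <- t(apply(m, 1, rank))
  constant <- apply(m, 1, function(v) length(unique(v)) == 1L) |
    (length(unique(x)) == 1L)
  rx_c <- rx - mean(rx)
  rm_c <- rm_ - rowMeans(rm_)
  denom <- sqrt(rowSums(rm_c^2) * sum(rx_c^2))
  rho <- ifelse(denom > 0, as.vector(rm_c %*% rx_c) / denom, 0)
  rho <- pmin(1, pmax(-1, rho))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(rho) == 1] <- 0
  rho[constant] <- 0
  p[constant] <- 1
  list(rho = rho, p = p, constant = constant)
}

#' Per-tissue range of the age correlation
#'
#' For each gene, the Spearman correlation with age is computed in every
#' tissue separately and the range (maximum minus minimum across tissues) is
#' reported. A large range means the direction/strength of the age
#' association depends on the tissue. Genes constant within a tissue
#' contribute rho = 0 for that tissue so gene sets stay comparable across
#' metrics.
#'
#' @param fm feature-matrix tibble.
#' @param metadata metadata tibble with `sample_id`, `age_months`, `tissue`.
#' @return tibble with `gene_id`, one `rho_<tissue>` column per tissue, and
#'   `range`.
#' @export
per_tissue_correlation_range <- function(fm, metadata) {
  m <- fm_values(fm)
  md <- metadata[match(colnames(m), metadata$sample_id), ]
  if (anyNA(md$sample_id)) abort("metadata missing for some samples")
  tissues <- sort(unique(md$tissue))
  if (length(tissues) == 1L) {
    warn("single tissue in metadata; all correlation ranges are 0")
  }
  n_const <- 0L
  rhos <- map(tissues, function(tt) {
    cols <- md$tissue == tt
    if (sum(cols) < 3 || length(unique(md$age_months[cols])) < 2) {
      abort(paste0(
        "tissue ", tt, " needs >= 3 samples with >= 2 distinct ages"
      ))
    }
    res <- spearman_vs_covariate(m[, cols, drop = FALSE], md$age_months[cols])
    n_const <<- n_const + sum(res$constant)
    res$rho
  })
  if (n_const > 0) {
    inform(paste0(
      n_const, " constant gene-within-tissue case(s) contributed rho = 0"
    ))
  }
  rho_mat <- do.call(cbind, rhos)
  colnames(rho_mat) <- paste0("rho_", tissues)
  bind_cols(
    tibble(gene_id = fm$gene_id),
    as_tibble(rho_mat),
    tibble(range = apply(rho_mat, 1, max) - apply(rho_mat, 1, min))
  )
}

#' Compare correlation-range distributions across metrics
#'
#' One-way ANOVA across the groups followed by Tukey's HSD for all pairwise
#' comparisons. Degenerate input (zero within-group variance and equal group
#' means) returns p = 1 by convention.
#'
#' @param ranges named list of numeric vectors (one per metric).
#' @return list with `anova_p`, `anova_f` and a `tukey` tibble
#'   (`comparison`, `diff`, `p_adj`).
#' @export
compare_ranges <- function(ranges) {
  stopifnot(is.list(ranges), length(ranges) >= 2)
  if (is.null(names(ranges))) names(ranges) <- paste0("group", seq_along(ranges))
  df <- tibble(
    value = unlist(ranges, use.names = FALSE),
    group = factor(rep(names(ranges), lengths(ranges)))
  )
  if (any(table(df$group) < 2)) abort("each group needs >= 2 values")
  pairs_idx <- utils::combn(levels(df$group), 2)
  comparison <- paste(pairs_idx[2, ], pairs_idx[1, ], sep = "-")
  gm <- tapply(df$value, df$group, mean)
  if (stats::var(df$value) == 0 ||
      (all(tapply(df$value, df$group, stats::var) == 0) &&
       length(unique(gm)) == 1L)) {
    return(list(
      anova_p = 1, anova_f = 0,
      tukey = tibble(comparison = comparison, diff = 0, p_adj = 1)
    ))
  }
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  list(
    anova_p = an[["Pr(>F)"]][1],
    anova_f = an[["F value"]][1],
    tukey = tibble(
      comparison = rownames(tk),
      diff = tk[, "diff"],
      p_adj = tk[, "p adj"]
    )
  )
}

#' Rank genes by the one-way ANOVA F-score
#'
#' For each gene, F = MSB / MSE where MSB is the between-group mean square of
#' the feature across the label's groups (age group or tissue) and MSE the
#' within-group mean square. Genes are ranked by descending F (rank 1 = the
#' gene that differs most across groups); ties are broken by ascending
#' `gene_id`. Genes that separate the groups perfectly (MSE = 0, MSB > 0)
#' get `F = Inf` and rank above all finite scores; fully constant genes get
#' `F = 0`.
#'
#' @param fm feature-matrix tibble.
#' @param metadata metadata tibble.
#' @param target `"age"` (groups = age_months as categories) or `"tissue"`.
#' @return tibble with `gene_id`, `f_score`, `rank`, sorted by rank.
#' @export
anova_f_scores <- function(fm, metadata, target = c("age", "tissue")) {
  target <- match.arg(target)
  m <- fm_values(fm)
  md <- metadata[match(colnames(m), metadata$sample_id), ]
  if (anyNA(md$sample_id)) abort("metadata missing for some samples")
  labels <- if (target == "age") factor(md$age_months) else factor(md$tissue)
  f <- f_scores_matrix(m, labels)
  ord <- order(-f, fm$gene_id)
  tibble(
    gene_id = fm$gene_id[ord],
    f_score = f[ord],
    rank = seq_along(ord)
  )
}

# Vectorized one-way ANOVA F over matrix rows for a factor of group labels.
f_scores_matrix <- function(m, labels) {
  labels <- droplevels(factor(labels))
  c_groups <- nlevels(labels)
  if (c_groups < 2) abort("need at least 2 groups for the F-score")
  n_r <- length(labels)
  if (n_r <= c_groups) abort("need more samples than groups")
  n_j <- as.vector(table(labels))
  g <- vapply(levels(labels), function(l) {
    rowMeans(m[, labels == l, drop = FALSE])
  }, numeric(nrow(m)))                    # genes x groups matrix of means
  grand <- rowMeans(m)
  ssb <- as.vector((g - grand)^2 %*% n_j)
  sst <- rowSums((m - grand)^2)
  sse <- pmax(sst - ssb, 0)
  msb <- ssb / (c_groups - 1)
  mse <- sse / (n_r - c_groups)
  f <- ifelse(mse > 0, msb / mse, ifelse(msb > 0, Inf, 0))
  unname(f)
}

#' Nested top-k gene sets from a ranking
#'
#' @param ranking tibble from [anova_f_scores()].
#' @param sizes ascending set sizes; default the study schedule
#'   `c(15, 25, 50, 75, 100, 150, 200, 300, 400, 500)`. Sets are nested by
#'   construction; the "all genes" set is appended by the caller.
#' @return named list (`top_15`, ...) of gene-id character vectors.
#' @export
top_k_gene_sets <- function(ranking,
                            sizes = c(15, 25, 50, 75, 100, 150, 200, 300, 400, 500)) {
  stopifnot(!is.unsorted(sizes, strictly = TRUE))
  if (max(sizes) > nrow(ranking)) {
    abort(paste0(
      "requested set size ", max(sizes), " exceeds ", nrow(ranking), " genes"
    ))
  }
  sets <- map(sizes, function(k) ranking$gene_id[seq_len(k)])
  names(sets) <- paste0("top_", sizes)
  sets
}

#' Hypergeometric overlap test for two gene sets
#'
#' Upper-tail probability of observing at least the realized overlap when
#' `length(set_a)` genes are drawn without replacement from a universe of
#' `universe_size` genes of which `length(set_b)` are marked.
#'
#' @param set_a,set_b character vectors of gene ids (subsets of the universe).
#' @param universe_size number of genes in the universe.
#' @return tibble with `overlap` and `p`.
#' @export
overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  stopifnot(length(set_a) <= universe_size, length(set_b) <= universe_size)
  ov <- length(intersect(set_a, set_b))
  p <- phyper(ov - 1, length(set_b), universe_size - length(set_b),
              length(set_a), lower.tail = FALSE)
  tibble(overlap = ov, p = min(p, 1))
}
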