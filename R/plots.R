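#' Plot mean AUC against gene-set size
#'
#' One line per method, faceted by metric, from the `results` table of
#' [evaluate_grid()]. The "all genes" set is drawn as a separate point at the
#' right edge.
#'
#' @param grid result of [evaluate_grid()].
#' @return a ggplot object.
#' @export
plot_gene_set_performance <- function(grid) {
  res <- grid$results
  ranked <- filter(res, .data$set_name != "all")
  allg <- filter(res, .data$set_name == "all")
  p <- ggplot2::ggplot(
    ranked,
    ggplot2::aes(x = .data$set_size, y = .data$mean_auc,
                 colour = .data$method_id)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::labs(
      x = "gene-set size (top-k by ANOVA F-score)",
      y = "mean AUC over iterations",
      colour = "method"
    ) +
    ggplot2::ylim(0, 1)
  if (nrow(allg) > 0) {
    p <- p + ggplot2::geom_point(
      data = mutate(allg, set_size = max(ranked$set_size) * 1.15),
      shape = 17
    )
  }
  p
}

#' Violin plot of per-tissue correlation ranges by metric
#'
#' @param ranges named list of per-gene correlation-range vectors (one
#'   element per metric), e.g. the `range` column of
#'   [per_tissue_correlation_range()] for each feature matrix.
#' @return a ggplot object.
#' @export
plot_correlation_ranges <- function(ranges) {
  df <- tibble(
    metric = rep(names(ranges), lengths(ranges)),
    range = unlist(ranges, use.names = FALSE)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$range)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.1, outlier.size = 0.3) +
    ggplot2::labs(
      x = NULL,
      y = "per-gene range of per-tissue Spearman correlation with age"
    )
}

#' Boxplots of per-iteration AUC for an evaluation
#'
#' @param object a `break_eval` object.
#' @param ... unused.
#' @return a ggplot object showing the distribution of the four metrics over
#'   iterations.
#' @method autoplot break_eval
#' @export
autoplot.break_eval <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("auc", "f1", "mae", "spearman"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(
      x = NULL, y = "per-iteration value",
      title = paste0(object$config$method_id, " / ", object$config$target)
    )
}
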