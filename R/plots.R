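# ggplot2 displays for the result containers.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_histogram
#'   geom_boxplot labs theme_minimal autoplot scale_x_log10 facet_wrap
NULL

#' Plot per-run cross-validation metrics
#'
#' @param object a [cross_validate()] result.
#' @param ... unused.
#' @return A ggplot: AUC and AUPR per run.
#' @export
autoplot.pgx_cv <- function(object, ...) {
  as_tibble(object) |>
    tidyr::pivot_longer(c("auc", "aupr"), names_to = "metric") |>
    ggplot(aes(x = .data$metric, y = .data$value)) +
    geom_boxplot(outlier.shape = NA, width = 0.4) +
    geom_point(position = ggplot2::position_jitter(width = 0.08, seed = 1)) +
    labs(
      x = NULL, y = "score",
      title = sprintf("Cross-validation over %d runs (1:%s negatives)",
                      nrow(object), attr(object, "neg_ratio"))
    ) +
    theme_minimal()
}

#' Plot the class-imbalance sweep
#'
#' @param sweep tibble combining [glance()] rows of several
#'   [cross_validate()] results, one per `neg_ratio`.
#' @return A ggplot of mean AUC and AUPR against the negative ratio.
#' @export
plot_negative_sweep <- function(sweep) {
  assert_cols(sweep, c("neg_ratio", "auc_mean", "aupr_mean"), "sweep table")
  sweep |>
    select("neg_ratio", AUC = "auc_mean", AUPR = "aupr_mean") |>
    tidyr::pivot_longer(c("AUC", "AUPR"), names_to = "metric") |>
    ggplot(aes(x = .data$neg_ratio, y = .data$value, colour = .data$metric)) +
    geom_line() +
    geom_point() +
    scale_x_log10(breaks = unique(sweep$neg_ratio)) +
    labs(x = "negatives per positive", y = "mean score", colour = NULL) +
    theme_minimal()
}

#' Histogram of predicted associations per drug
#'
#' @param object a `pgx_predictions` tibble of called predictions.
#' @param ... unused.
#' @return A ggplot of the per-drug prediction-count distribution.
#' @export
autoplot.pgx_predictions <- function(object, ...) {
  count(object, .data$drug_id) |>
    ggplot(aes(x = .data$n)) +
    geom_histogram(bins = 30) +
    labs(x = "predicted associations per drug", y = "drugs") +
    theme_minimal()
}
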