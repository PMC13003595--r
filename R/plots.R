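# ggplot2 views of the result objects.

#' Plot an ROC curve
#'
#' @param object An `hibpn_roc` tibble from [roc_and_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hibpn_roc
#' @export
autoplot.hibpn_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "ROC curve") +
    ggplot2::theme_minimal()
}

#' Plot a model-comparison metrics table
#'
#' Bar chart of ACC / AUC / F1 per model, faceted by chain.
#'
#' @param object An `hibpn_metrics` tibble (see [run_experiment1()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hibpn_metrics
#' @export
autoplot.hibpn_metrics <- function(object, ...) {
  long <- object |>
    dplyr::select("model", "chain", "acc", "auc", "f1") |>
    tidyr::pivot_longer(c("acc", "auc", "f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$model, .data$value),
                                     y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~chain) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Metric value", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot grouped dimension importance
#'
#' @param object An `hibpn_importance` tibble from [dimension_importance()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hibpn_importance
#' @export
autoplot.hibpn_importance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = stats::reorder(.data$dimension, .data$weight_pct),
                                       y = .data$weight_pct)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~chain) +
    ggplot2::labs(x = NULL, y = "Importance weight (%)") +
    ggplot2::theme_minimal()
}

#' Plot intervention arm response rates
#'
#' @param object An `hibpn_intervention` tibble from [run_experiment2()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hibpn_intervention
#' @export
autoplot.hibpn_intervention <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$arm, y = .data$positive_response_rate)) +
    ggplot2::geom_col(width = 0.5, fill = "#41ab5d") +
    ggplot2::labs(x = NULL, y = "Positive response rate",
                  subtitle = sprintf("Difference: %.2f percentage points",
                                     attr(object, "difference_pct"))) +
    ggplot2::theme_minimal()
}
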