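#' Plot the top-k Mean Decrease Impurity shares for one comparison
#'
#' Horizontal bar chart of normalised MDI importance, the standard way one
#' classifier's predictor ranking is displayed.
#'
#' @param object a `sway_importance` from [feature_importance()].
#' @param top_k how many features to show (default 5).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sway_importance <- function(object, top_k = 5, ...) {
  d <- object[object$rank <= top_k, ]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$share * 100,
    y = stats::reorder(.data$feature, .data$share))) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(
      title = attr(object, "comparison"),
      x = "MDI importance (% of total)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sway_importance
#' @param x a `sway_importance`.
#' @export
plot_importance <- function(x, top_k = 5) autoplot.sway_importance(x, top_k)

#' Plot the diagnostic metrics of a full report
#'
#' Dot plot of accuracy, sensitivity and specificity (percent) for every
#' pairwise comparison, faceted by feature set.
#'
#' @param object a `sway_report` from [run_all_comparisons()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sway_report <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$results,
    cols = c("accuracy_pct", "sensitivity_pct", "specificity_pct"),
    names_to = "metric", values_to = "percent")
  d$metric <- sub("_pct$", "", d$metric)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$percent, y = .data$comparison,
                                  colour = .data$metric)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~feature_set) +
    ggplot2::labs(x = "Percent", y = NULL, colour = NULL) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot a preprocessed COP trial
#'
#' Statokinesigram (ML vs AP trajectory) of a trial; the standard visual
#' check of a posturography recording.
#'
#' @param object a `cop_trial`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cop_trial <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$ml, y = .data$ap)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ML (cm)", y = "AP (cm)",
                  title = attr(object, "participant_id")) +
    ggplot2::theme_minimal()
}
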