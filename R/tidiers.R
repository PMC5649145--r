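# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy an experiment result
#'
#' @param x An [run_experiment()] result.
#' @param ... Unused.
#' @return Per-iteration metrics as a tibble (one row per CV iteration).
#' @export
tidy.mci_experiment <- function(x, ...) x$metrics

#' Glance at an experiment result
#'
#' @inheritParams tidy.mci_experiment
#' @return A one-row tibble: task, feature set, mean accuracy, sensitivity,
#'   specificity and AUC over CV iterations, and the number of iterations.
#' @export
glance.mci_experiment <- function(x, ...) {
  dplyr::bind_cols(
    tibble(task = x$task, feature_set = x$feature_set),
    x$summary,
    tibble(n_iterations = nrow(x$metrics))
  )
}

#' Tidy a stability selection result
#'
#' @param x A [choose_optimal_set()] result.
#' @param ... Unused.
#' @return The optimal feature set as a tibble with selection frequency and
#'   Welch t-test p-value per feature (the ranked-biomarker report shape).
#' @export
tidy.mci_selection <- function(x, ...) {
  tibble(feature = x$optimal_features) %>%
    dplyr::left_join(x$frequencies, by = "feature") %>%
    dplyr::left_join(x$p_values[c("feature", "p_value")], by = "feature")
}

#' Glance at a stability selection result
#'
#' @inheritParams tidy.mci_selection
#' @return One row: chosen Nf, best mean recall, positive class.
#' @export
glance.mci_selection <- function(x, ...) {
  tibble(
    chosen_nf = x$chosen_nf,
    mean_recall = max(x$recall_summary$mean_recall),
    positive = x$positive
  )
}

#' Plot per-iteration metrics of an experiment
#'
#' @param object An [run_experiment()] result.
#' @param ... Unused.
#' @return A ggplot: one point per CV iteration and metric, with the
#'   per-metric mean marked.
#' @export
autoplot.mci_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics,
    cols = c("accuracy", "sensitivity", "specificity", "auc"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      title = sprintf("%s (%s features)", object$task, object$feature_set),
      x = NULL, y = "value per CV iteration"
    )
}

#' Plot aggregated selection frequencies
#'
#' @param x An [run_experiment()] result or a frequency tibble with columns
#'   `feature` and `frequency`.
#' @param top_n Number of top-ranked features to show (default 10).
#' @return A ggplot bar chart of selection frequencies, most frequent on top.
#' @export
plot_selection_frequencies <- function(x, top_n = 10) {
  freq <- if (inherits(x, "mci_experiment")) x$frequencies else as_tibble(x)
  cap <- if (inherits(x, "mci_experiment")) x$max_frequency else NA_integer_
  top <- freq %>%
    dplyr::arrange(dplyr::desc(.data$frequency)) %>%
    dplyr::slice_head(n = top_n)
  p <- ggplot2::ggplot(top, ggplot2::aes(
    x = .data$frequency,
    y = stats::reorder(.data$feature, .data$frequency)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "selection frequency", y = NULL)
  if (!is.na(cap)) {
    p <- p + ggplot2::expand_limits(x = cap) +
      ggplot2::geom_vline(xintercept = cap, linetype = "dashed")
  }
  p
}
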