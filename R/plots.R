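#' Plot a step function
#'
#' @param object a [survstep()] (cumulative hazard, survival curve, or
#'   prediction error curve).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.survstep <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Time (days)", y = "Value") +
    ggplot2::theme_minimal()
}

#' Plot the pruning error curve
#'
#' Held-out error `1 - C` against tree size for each candidate minimum
#' terminal-node size; the selected size is marked.
#'
#' @param object a [prune_tree()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pruned_survival_tree <- function(object, ...) {
  df <- object$curve
  sel <- df[df$min_node_size == object$min_node_size, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_leaves, y = .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = sel, colour = "red", size = 3) +
    ggplot2::labs(x = "Tree size (terminal nodes)",
                  y = "Test error (1 - C index)") +
    ggplot2::theme_minimal()
}

#' Plot prediction-error curves of a study
#'
#' Brier score over time on the training and test parts of the designated
#' replicate, one panel per construction method — the at-a-glance view of
#' each method's optimism gap.
#'
#' @param object a [run_study()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.optimism_study <- function(object, ...) {
  if (is.null(object$curves)) {
    abort("This study stored no prediction-error curves.")
  }
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$time, y = .data$brier,
                               colour = .data$set)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "Time (days)", y = "Brier score", colour = "Set") +
    ggplot2::theme_minimal()
}
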