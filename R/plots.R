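#' Plot estimated temporal response functions
#'
#' One panel per regressor, kernel time course per channel.
#'
#' @param object a `trf_model`.
#' @param regressors optional subset of regressor names.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.trf_model <- function(object, regressors = NULL, ...) {
  td <- tidy(object)
  if (!is.null(regressors)) td <- dplyr::filter(td, .data$regressor %in% regressors)
  ggplot2::ggplot(td, ggplot2::aes(.data$lag, .data$estimate,
                                   group = .data$channel, colour = .data$channel)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70", linetype = 2) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~regressor, scales = "free_y") +
    ggplot2::labs(x = "lag (s)", y = "coefficient (a.u.)",
                  title = "Temporal response functions") +
    ggplot2::theme_minimal()
}

#' Plot cross-validated predictive correlations
#'
#' Per-channel r, folds as points, with the across-fold median.
#'
#' @param object a `trf_cv`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.trf_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds, ggplot2::aes(.data$channel, .data$r)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::stat_summary(fun = median, geom = "point", colour = "red", size = 3) +
    ggplot2::labs(y = "cross-validated r",
                  title = paste0("Predictive performance: ", object$label)) +
    ggplot2::theme_minimal()
}

#' Plot per-note surprise for an evaluated model
#'
#' @param object a `surprise_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.surprise_eval <- function(object, ...) {
  ggplot2::ggplot(object$notes,
                  ggplot2::aes(.data$note_index, .data$surprise)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~composition_id, scales = "free_x") +
    ggplot2::labs(x = "note", y = "surprise (nats)",
                  title = sprintf("%s (context length %d)",
                                  object$model_name, object$context_length)) +
    ggplot2::theme_minimal()
}

#' Plot a context-length sweep
#'
#' Dual view of the sweep: music predictive accuracy and incremental neural
#' predictive correlation (delta r over the baseline model) against context
#' length.
#'
#' @param sweep the `sweep` tibble from [context_sweep()].
#' @return a ggplot object.
#' @export
plot_context_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, c("accuracy", "mean_delta_r"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$k, .data$value, colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "context length k", y = NULL) +
    ggplot2::theme_minimal()
}
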