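#' Plot a supervised learning curve
#'
#' Mean test-set accuracy (correlation and MSE panels) against labeled
#' training-set size, with 95% confidence-interval error bars.
#'
#' @param object A `learning_curve` from [learning_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.learning_curve <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$n_labeled, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper), size = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Animals with measured phenotypes",
                  y = "Mean over replicates (95% CI)",
                  title = "Supervised learning curve") +
    ggplot2::theme_minimal()
}

#' Plot a labeled/unlabeled ratio sweep
#'
#' Mean paired accuracy change (`R_SSL - R_SL`) against the number of
#' self-trained animals, one line per labeled training-set size, with 95%
#' confidence intervals.
#'
#' @param object A `ratio_sweep` from [ratio_sweep()].
#' @param metric `"correlation_gain"` (default) or `"mse_change"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ratio_sweep <- function(object, metric = "correlation_gain", ...) {
  df <- dplyr::filter(object$summary, .data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_unlabeled, y = .data$mean,
                                   colour = factor(.data$n_labeled))) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper),
                             position = ggplot2::position_dodge(width = 20)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Animals with self-trained phenotypes",
                  y = metric, colour = "Labeled animals",
                  title = "Semi-supervised vs supervised accuracy") +
    ggplot2::theme_minimal()
}

#' Plot plateau-search results
#'
#' Mean stopping ratio (self-trained to measured animals) and mean maximum
#' improvement per labeled training-set size, with 95% confidence intervals.
#'
#' @param object A `plateau_search` from [plateau_search()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.plateau_search <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = factor(.data$n_labeled), y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper), width = 0.2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Animals with measured phenotypes", y = "Mean (95% CI)",
                  title = "Optimal self-trained/measured ratio and maximum gain") +
    ggplot2::theme_minimal()
}
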