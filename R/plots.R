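#' Plot spend-choice probability by sequence progress
#'
#' @param cp output of [choice_probability_by_progress()].
#' @return a ggplot.
#' @export
plot_choice_probability <- function(cp) {
  ggplot2::ggplot(cp, ggplot2::aes(.data$step, .data$p_spend,
                                   color = factor(.data$interest_rate))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Sequence progress (trials)",
                  y = "P(spend | reached step)",
                  color = "Interest rate") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-saveseq
#' @exportS3Method ggplot2::autoplot
autoplot.adaptation_result <- function(object, ...) {
  bl <- object$by_length
  ggplot2::ggplot(bl, ggplot2::aes(1 / .data$sequence_length, .data$slope)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$slope - .data$se,
                                        ymax = .data$slope + .data$se),
                           width = 0) +
    ggplot2::geom_abline(intercept = object$inv_length_fit$intercept,
                         slope = object$inv_length_fit$slope,
                         linetype = 2) +
    ggplot2::labs(x = "1 / sequence length",
                  y = "Population progress slope") +
    ggplot2::theme_minimal()
}

#' Autoplot methods for saveseq result objects
#'
#' `autoplot.adaptation_result` shows per-length progress slopes against
#' inverse sequence length with the fitted line; `autoplot.decoding_result`
#' shows the distribution of per-matching accuracies against chance (and the
#' shuffled-label null when present).
#'
#' @param object a result object.
#' @param ... unused.
#' @return a ggplot.
#' @name autoplot-saveseq
#' @exportS3Method ggplot2::autoplot
autoplot.decoding_result <- function(object, ...) {
  real <- tibble(accuracy = object$accuracies, which = "real")
  dat <- if (!is.null(object$null_accuracies)) {
    bind_rows(real, tibble(accuracy = object$null_accuracies,
                           which = "shuffled"))
  } else real
  ggplot2::ggplot(dat, ggplot2::aes(.data$which, .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = object$chance, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Decoding accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Plot a sliding-window significance series
#'
#' @param sw output of [sliding_window_regression()] (one or more neurons).
#' @param alpha significance level drawn as a reference line.
#' @return a ggplot of -log10 p across windows, faceted by segment.
#' @export
plot_sliding_windows <- function(sw, alpha = 0.05) {
  ggplot2::ggplot(sw, ggplot2::aes(.data$window_start,
                                   -log10(pmax(.data$p_value, 1e-16)),
                                   group = .data$neuron_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::facet_grid(. ~ segment, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Window start (s, event-aligned)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
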