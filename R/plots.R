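# ggplot2 visualisations for simulation and concordance results.

#' Plot a parameter-recovery experiment
#'
#' Per-replicate estimates as jittered points with the true value as a
#' horizontal line, one panel per recovered parameter.
#'
#' @param object an `ncr_recovery` summary from
#'   [parameter_recovery_experiment()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ncr_recovery <- function(object, ...) {
  est <- attr(object, "estimates")
  long <- est |>
    dplyr::filter(!.data$failed) |>
    dplyr::select(dplyr::any_of(c("rep", object$parameter))) |>
    tidyr::pivot_longer(-"rep", names_to = "parameter",
                        values_to = "estimate")
  truth <- dplyr::select(as_tibble(object), "parameter", "true")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter,
                                     y = .data$estimate)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::geom_errorbar(
      data = truth,
      ggplot2::aes(y = NULL, ymin = .data$true, ymax = .data$true),
      color = "red", linewidth = 0.6, width = 0.5
    ) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "estimate",
                  title = "Parameter recovery (red = truth)") +
    ggplot2::theme_bw()
}

#' Scatter plot of ML versus count-model lambda estimates
#'
#' @param data data frame with columns `lambda_ml` and `lambda_count`.
#' @return A ggplot object on log-log axes with the identity line.
#' @export
plot_lambda_concordance <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$lambda_count,
                                     y = .data$lambda_ml)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(lambda ~ "(count model)"),
                  y = expression(hat(lambda) ~ "(maximum likelihood)"),
                  title = "ML vs count-model concordance") +
    ggplot2::theme_bw()
}
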