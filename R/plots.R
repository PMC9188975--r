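#' Plot predicted versus true age with the fitted age bias
#'
#' Scatter of predictions against chronological age with the identity line
#' (dashed) and the ordinary-least-squares bias fit (solid). The gap between
#' the two lines is the age bias the corrections remove.
#'
#' @param object A prediction tibble.
#' @param corrected Plot the corrected predictions instead.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prediction_result <- function(object, corrected = FALSE, ...) {
  yhat <- resolve_predictions(object, corrected)
  df <- tibble::tibble(true_age = object$true_age, predicted_age = yhat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true_age, y = .data$predicted_age)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "orange") +
    ggplot2::labs(
      x = "Chronological age (years)",
      y = if (corrected) "Corrected predicted age (years)" else "Predicted age (years)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an experiment result grid
#'
#' Seed-averaged metric values against the manipulated factor of the design
#' (age range, sample fraction or shuffle fraction), uncorrected and
#' corrected side by side, one facet per metric.
#'
#' @param object An `experiment_result`.
#' @param metrics Which metrics to facet over.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_result <- function(object, metrics = c("r", "R2", "RMSE", "MAE"),
                                       ...) {
  summary <- summarise_experiment(object)
  xvar <- if ("shuffle_fraction" %in% names(summary)) {
    "shuffle_fraction"
  } else if ("range_lo" %in% names(summary)) {
    summary$cell <- sprintf("%g-%g", summary$range_lo, summary$range_hi)
    "cell"
  } else if ("fraction" %in% names(summary)) {
    "fraction"
  } else if ("cohort" %in% names(summary)) {
    "cohort"
  } else {
    "direction"
  }
  long <- summary |>
    tidyr::pivot_longer(
      cols = dplyr::any_of(c(metrics, paste0(metrics, "_corr"))),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::mutate(
      correction = ifelse(grepl("_corr$", .data$metric), "corrected", "uncorrected"),
      metric = sub("_corr$", "", .data$metric)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[xvar]], y = .data$value,
                                     colour = .data$correction,
                                     group = .data$correction)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = xvar, y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
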