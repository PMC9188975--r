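#' Fit the age bias of a prediction model
#'
#' Age-prediction models systematically overestimate young subjects and
#' underestimate old ones: least squares pulls predictions toward the central
#' age of the training sample. The bias is modelled by ordinary least squares
#' on chronological age, via either of two equivalent routes:
#'
#' * `route = "prediction"`: regress predicted age on age, `Y = alpha*age + beta`;
#' * `route = "delta"`: regress the brain-age delta (predicted minus true age)
#'   on age. Because delta = prediction - age, the two routes are related by
#'   `alpha_delta = alpha_prediction - 1` and equal intercepts.
#'
#' With `quadratic = TRUE` a squared-age term is added; age is centred before
#' squaring to reduce collinearity, and the centring constant is recorded in
#' the fit.
#'
#' @param result A prediction tibble ([crossval_predict()] etc.) with at least
#'   3 subjects and nonzero age variance.
#' @param route `"prediction"` or `"delta"`: which quantity is regressed on age.
#' @param quadratic Add a (centred) quadratic age term.
#' @param fit_source Provenance label: `"in_sample"` if the fit comes from the
#'   same data it will correct, `"train_derived"` if it will be applied to an
#'   independent set.
#' @return An object of class `bias_fit` with elements `alpha` (slope),
#'   `beta` (intercept), `gamma` (quadratic coefficient or `NULL`), `center`
#'   (age centring constant for the quadratic term), `route`, `fit_source`, `n`.
#' @examples
#' pred <- generate_predictions_direct(runif(500, 45, 82), 0.7, seed = 1)
#' fit_bias(pred, route = "prediction")
#' @export
fit_bias <- function(result, route = c("prediction", "delta"),
                     quadratic = FALSE, fit_source = c("in_sample", "train_derived")) {
  route <- match.arg(route)
  fit_source <- match.arg(fit_source)
  check_prediction_result(result)
  if (nrow(result) < 3) abort_invalid("Need at least 3 subjects to fit the age bias.")
  age <- result$true_age
  if (pop_sd(age) == 0) abort_degenerate("Zero age variance; bias fit is undefined.")
  y <- if (route == "prediction") result$predicted_age else result$predicted_age - age

  if (quadratic) {
    center <- mean(age)
    age_c2 <- (age - center)^2
    fit <- lm(y ~ age + age_c2)
    gamma <- unname(coef(fit)[["age_c2"]])
  } else {
    center <- 0
    fit <- lm(y ~ age)
    gamma <- NULL
  }
  structure(
    list(
      alpha = unname(coef(fit)[["age"]]),
      beta = unname(coef(fit)[["(Intercept)"]]),
      gamma = gamma,
      center = center,
      route = route,
      fit_source = fit_source,
      n = length(age)
    ),
    class = "bias_fit"
  )
}

#' Construct a bias fit from known coefficients
#'
#' Builds a `bias_fit` directly from slope and intercept values, e.g. to
#' apply coefficients estimated elsewhere (a training set, a published model)
#' to new predictions.
#'
#' @param alpha Slope (years per year).
#' @param beta Intercept (years).
#' @param gamma Optional quadratic coefficient (per year).
#' @param route `"prediction"` or `"delta"`.
#' @param fit_source Provenance label.
#' @param center Age centring constant used by the quadratic term.
#' @param n Number of subjects behind the fit, if known.
#' @return A `bias_fit` object.
#' @examples
#' bias_fit(alpha = 0.5, beta = 2)
#' @export
bias_fit <- function(alpha, beta, gamma = NULL, route = c("prediction", "delta"),
                     fit_source = c("train_derived", "in_sample"),
                     center = 0, n = NA_integer_) {
  route <- match.arg(route)
  fit_source <- match.arg(fit_source)
  check_number(alpha, "alpha")
  check_number(beta, "beta")
  if (!is.null(gamma)) check_number(gamma, "gamma")
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, center = center,
         route = route, fit_source = fit_source, n = n),
    class = "bias_fit"
  )
}

#' @export
print.bias_fit <- function(x, ...) {
  cat(sprintf("<bias_fit> route = %s, source = %s, n = %d\n",
              x$route, x$fit_source, x$n))
  cat(sprintf("  alpha (slope)     = %.6f\n", x$alpha))
  cat(sprintf("  beta  (intercept) = %.6f\n", x$beta))
  if (!is.null(x$gamma)) {
    cat(sprintf("  gamma (quadratic) = %.6g  (age centred at %.3f)\n",
                x$gamma, x$center))
  }
  invisible(x)
}

# Evaluate the fitted bias model at given ages.
predict_bias <- function(fit, age) {
  out <- fit$alpha * age + fit$beta
  if (!is.null(fit$gamma)) out <- out + fit$gamma * (age - fit$center)^2
  out
}

#' Apply an age-bias correction
#'
#' Applies the additive correction with coefficients from [fit_bias()]:
#'
#' * prediction-route fit: `corrected = predicted + (age - (alpha*age + beta))`
#'   (minus the quadratic term when present);
#' * delta-route fit: `corrected delta = delta - (alpha_d*age + beta_d)`, then
#'   `corrected predicted = corrected delta + age`.
#'
#' When both fits come from the same data the two routes give identical
#' corrected deltas. The input is not mutated: a new prediction tibble is
#' returned with a `corrected_predicted_age` column and the fit attached as an
#' attribute.
#'
#' @param result A prediction tibble.
#' @param fit A `bias_fit`.
#' @return The prediction tibble with a `corrected_predicted_age` column; the
#'   fit used is stored in `attr(, "bias_fit")`.
#' @export
apply_correction <- function(result, fit) {
  check_prediction_result(result)
  if (!inherits(fit, "bias_fit")) abort_invalid("`fit` must be a bias_fit.")
  age <- result$true_age
  if (fit$route == "prediction") {
    corrected <- result$predicted_age + (age - predict_bias(fit, age))
  } else {
    delta <- result$predicted_age - age
    corrected <- (delta - predict_bias(fit, age)) + age
  }
  out <- result
  out$corrected_predicted_age <- corrected
  attr(out, "bias_fit") <- fit
  out
}

#' Slope-division (Cole-style) age-bias correction
#'
#' Rescales predictions without using each subject's chronological age in the
#' additive step: `corrected = (predicted - beta) / alpha`. The map is
#' strictly monotone for `alpha > 0`, so prediction ranks are preserved, but
#' delta variance is inflated by `1 / alpha^2`. For example, with an intercept
#' of 2 and a slope of 0.5, a predicted age of 50 becomes 96 and a predicted
#' age of 60 becomes 116; a 40-year-old predicted at 50 sees their delta go
#' from 10 to 56.
#'
#' @param result A prediction tibble.
#' @param fit A linear `bias_fit` (prediction route) with nonzero slope.
#' @return The prediction tibble with a `corrected_predicted_age` column.
#' @export
cole_correct <- function(result, fit) {
  check_prediction_result(result)
  if (!inherits(fit, "bias_fit")) abort_invalid("`fit` must be a bias_fit.")
  if (!is.null(fit$gamma)) {
    abort_invalid("Slope-division correction is defined for linear fits only.")
  }
  if (fit$route != "prediction") {
    abort_invalid("Slope-division correction requires a prediction-route fit.")
  }
  if (fit$alpha == 0) {
    abort(
      "Slope is 0: slope-division correction is undefined.",
      class = "brainagekit_division_degenerate"
    )
  }
  out <- result
  out$corrected_predicted_age <- (result$predicted_age - fit$beta) / fit$alpha
  attr(out, "bias_fit") <- fit
  out
}

#' Brain-age delta
#'
#' The per-subject difference between predicted and chronological age
#' (corrected predicted age when `corrected = TRUE`).
#'
#' @param result A prediction tibble.
#' @param corrected Use the `corrected_predicted_age` column.
#' @return A tibble with columns `subject_id`, `true_age`, `delta`, `corrected`.
#' @export
compute_delta <- function(result, corrected = FALSE) {
  check_prediction_result(result)
  pred <- if (corrected) {
    if (is.null(result$corrected_predicted_age)) {
      abort_invalid("No `corrected_predicted_age` column; apply a correction first.")
    }
    result$corrected_predicted_age
  } else {
    result$predicted_age
  }
  tibble::tibble(
    subject_id = result$subject_id,
    true_age = result$true_age,
    delta = pred - result$true_age,
    corrected = corrected
  )
}

#' Serialise a bias fit to and from JSON
#'
#' Coefficients are stored at full precision for train-to-test reuse.
#'
#' @param fit A `bias_fit`.
#' @param path JSON file path.
#' @return `bias_fit_from_json()` returns a `bias_fit`.
#' @export
bias_fit_to_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(fit)
}

#' @rdname bias_fit_to_json
#' @export
bias_fit_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(alpha = x$alpha, beta = x$beta, gamma = x$gamma,
         center = x$center %||% 0, route = x$route,
         fit_source = x$fit_source, n = x$n %||% NA_integer_),
    class = "bias_fit"
  )
}

#' Broom-style tidiers for bias fits
#'
#' @param x A `bias_fit`.
#' @param ... Unused.
#' @return `tidy()` returns one row per coefficient; `glance()` a one-row
#'   summary.
#' @export
tidy.bias_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$beta, x$alpha)
  )
  if (!is.null(x$gamma)) {
    out <- dplyr::bind_rows(
      out, tibble::tibble(term = "quadratic", estimate = x$gamma)
    )
  }
  out
}

#' @rdname tidy.bias_fit
#' @export
glance.bias_fit <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, beta = x$beta,
    gamma = if (is.null(x$gamma)) NA_real_ else x$gamma,
    route = x$route, fit_source = x$fit_source, n = x$n
  )
}
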