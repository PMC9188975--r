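new_metric_report <- function(...) {
  out <- tibble::tibble(...)
  class(out) <- c("metric_report", class(out))
  out
}

resolve_predictions <- function(result, corrected) {
  check_prediction_result(result)
  if (corrected) {
    if (is.null(result$corrected_predicted_age)) {
      abort_invalid("No `corrected_predicted_age` column; apply a correction first.")
    }
    result$corrected_predicted_age
  } else {
    result$predicted_age
  }
}

#' Core performance metrics: r, R-squared, RMSE, MAE
#'
#' The four standard metrics for an age-prediction model, with `y` the true
#' ages and `yhat` the predictions:
#'
#' * `r`: Pearson's correlation between predictions and true age;
#' * `R2 = 1 - sum((yhat - y)^2) / sum((mean(y) - y)^2)` -- the proportion of
#'   true-age variance explained. Not the square of `r`; it can be negative
#'   when predictions fit worse than the test-set mean age;
#' * `RMSE = sqrt(mean((yhat - y)^2))` (divide-by-N convention);
#' * `MAE = mean(abs(yhat - y))`.
#'
#' With zero prediction variance `r` is undefined and reported as `NA` with
#' `r_defined = FALSE` (never silently 0); the other metrics are still
#' computed.
#'
#' @param result A prediction tibble with at least 3 subjects and nonzero
#'   true-age variance.
#' @param corrected Evaluate the `corrected_predicted_age` column instead of
#'   the raw predictions.
#' @return A one-row `metric_report` tibble with columns `r`, `r_defined`,
#'   `R2`, `RMSE`, `MAE`, `n_subjects`.
#' @examples
#' core_metrics(generate_predictions_direct(runif(200, 45, 82), 0.8, seed = 1))
#' @export
core_metrics <- function(result, corrected = FALSE) {
  yhat <- resolve_predictions(result, corrected)
  y <- result$true_age
  if (length(y) < 3) abort_invalid("Need at least 3 subjects.")
  if (pop_sd(y) == 0) abort_degenerate("Zero variance of true age.")
  err <- yhat - y
  ss_res <- sum(err^2)
  ss_tot <- sum((mean(y) - y)^2)
  r_defined <- pop_sd(yhat) > 0
  new_metric_report(
    r = if (r_defined) cor(y, yhat) else NA_real_,
    r_defined = r_defined,
    R2 = 1 - ss_res / ss_tot,
    RMSE = sqrt(mean(err^2)),
    MAE = mean(abs(err)),
    n_subjects = length(y)
  )
}

#' Alternative error metrics: RSE, RAE, MedAE, weighted MAE
#'
#' * `RSE = sum((yhat - y)^2) / sum((mean(y) - y)^2)` (relative squared
#'   error; identically `1 - R2`);
#' * `RAE = sum(|yhat - y|) / sum(|mean(y) - y|)` (relative absolute error);
#' * `MedAE = median(|yhat - y|)`;
#' * `wMAE`: MAE with subject weights inversely proportional to the subject's
#'   age-bin count (default 2-year bins), flattening the influence of the age
#'   distribution. The bin width is recorded in the output; the weighting is a
#'   package convention (`wmae_definition` column) since no single standard
#'   exists.
#'
#' @inheritParams core_metrics
#' @param bin_width Age-bin width in years for the wMAE weights.
#' @return A one-row `metric_report` tibble with columns `RSE`, `RAE`,
#'   `MedAE`, `wMAE`, `wmae_definition`, `n_subjects`.
#' @export
alt_metrics <- function(result, corrected = FALSE, bin_width = 2) {
  yhat <- resolve_predictions(result, corrected)
  y <- result$true_age
  if (length(y) < 3) abort_invalid("Need at least 3 subjects.")
  check_number(bin_width, "bin_width")
  if (bin_width <= 0) abort_invalid("`bin_width` must be > 0.")
  err <- yhat - y
  ss_tot <- sum((mean(y) - y)^2)
  sa_tot <- sum(abs(mean(y) - y))
  bins <- floor((y - min(y)) / bin_width)
  w <- 1 / as.numeric(table(bins)[as.character(bins)])
  new_metric_report(
    RSE = if (ss_tot > 0) sum(err^2) / ss_tot else NA_real_,
    RAE = if (sa_tot > 0) sum(abs(err)) / sa_tot else NA_real_,
    MedAE = median(abs(err)),
    wMAE = sum(w * abs(err)) / sum(w),
    wmae_definition = sprintf("inverse %g-year age-bin frequency weights", bin_width),
    n_subjects = length(y)
  )
}

#' Bootstrap uncertainties for the performance metrics
#'
#' Resamples subject (true age, prediction) pairs with replacement `n_boot`
#' times (default 200) and reports the SD of each metric over the resamples
#' as its uncertainty. Point estimates are the full-sample values. Resamples
#' in which `r` is undefined (zero variance) are skipped for `r` and counted
#' in `n_degenerate`.
#'
#' @inheritParams core_metrics
#' @param n_boot Number of bootstrap resamples (default 200).
#' @param seed Integer seed.
#' @return A one-row `metric_report` with columns `r`, `R2`, `RMSE`, `MAE`
#'   and matching `*_se` bootstrap SDs, plus `n_boot`, `n_degenerate`,
#'   `n_subjects`.
#' @export
bootstrap_metrics <- function(result, n_boot = 200, seed, corrected = FALSE) {
  n_boot <- check_count(n_boot, "n_boot", min = 2L)
  seed <- check_count(seed, "seed", min = 0L)
  yhat <- resolve_predictions(result, corrected)
  y <- result$true_age
  n <- length(y)
  if (n < 10) abort_invalid("Need at least 10 subjects for bootstrap uncertainties.")
  point <- core_metrics(result, corrected = corrected)
  stats <- withr::with_seed(seed, {
    purrr::map(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- y[idx]; pb <- yhat[idx]
      err <- pb - yb
      ss_tot <- sum((mean(yb) - yb)^2)
      c(
        r = if (pop_sd(pb) > 0 && pop_sd(yb) > 0) cor(yb, pb) else NA_real_,
        R2 = if (ss_tot > 0) 1 - sum(err^2) / ss_tot else NA_real_,
        RMSE = sqrt(mean(err^2)),
        MAE = mean(abs(err))
      )
    })
  })
  mat <- do.call(rbind, stats)
  new_metric_report(
    r = point$r, r_se = sd(mat[, "r"], na.rm = TRUE),
    R2 = point$R2, R2_se = sd(mat[, "R2"], na.rm = TRUE),
    RMSE = point$RMSE, RMSE_se = sd(mat[, "RMSE"]),
    MAE = point$MAE, MAE_se = sd(mat[, "MAE"]),
    n_boot = n_boot,
    n_degenerate = sum(is.na(mat[, "r"])),
    n_subjects = n
  )
}

#' Per-individual prediction uncertainty via training-set bootstrap
#'
#' Creates `n_models` bootstrap resamples of the training set (sampling
#' subjects with replacement), fits one model per resample, and predicts the
#' test set with each, yielding a distribution of predicted ages per test
#' subject. Reports the mean `mu` and SD `sigma` of each subject's
#' distribution -- `sigma` is the uncertainty of that person's brain-predicted
#' age -- together with the proportion of the subject's delta draws
#' (prediction minus true age) exceeding `threshold`, interpretable as a
#' per-individual risk probability.
#'
#' @param train,test Disjoint cohort tibbles with identical feature schemas.
#' @param regressor A regressor object.
#' @param n_models Number of bootstrap models (default 500).
#' @param threshold Delta threshold in years for the risk proportion.
#' @param seed Integer seed.
#' @return A tibble with one row per test subject: `subject_id`, `true_age`,
#'   `mu`, `sigma`, `risk_proportion`.
#' @export
individual_uncertainty <- function(train, test, regressor = ridge_regressor(),
                                   n_models = 500, threshold = 5, seed) {
  n_models <- check_count(n_models, "n_models", min = 2L)
  seed <- check_count(seed, "seed", min = 0L)
  check_number(threshold, "threshold")
  if (length(intersect(train$subject_id, test$subject_id)) > 0) {
    abort_invalid("Train and test subject sets must be disjoint.")
  }
  x_train <- cohort_features(train)
  x_test <- cohort_features(test)
  n_train <- nrow(x_train)
  preds <- matrix(NA_real_, nrow(x_test), n_models)
  withr::with_seed(seed, {
    for (b in seq_len(n_models)) {
      idx <- sample.int(n_train, n_train, replace = TRUE)
      run <- function() {
        scaled <- robust_scale(x_train[idx, , drop = FALSE])
        fit <- fit_regressor(regressor, scaled$scaled, train$age[idx])
        predict_regressor(
          fit, robust_scale(x_test, params = scaled$params)$scaled
        )
      }
      preds[, b] <- tryCatch(
        suppressWarnings(run()),
        error = function(e) {
          # one retry with a fresh resample, then abort
          idx <<- sample.int(n_train, n_train, replace = TRUE)
          tryCatch(suppressWarnings(run()), error = function(e2) {
            abort_invalid(sprintf("Regressor failed twice on resample %d: %s",
                                  b, conditionMessage(e2)))
          })
        }
      )
    }
  })
  delta <- preds - test$age
  tibble::tibble(
    subject_id = test$subject_id,
    true_age = test$age,
    mu = rowMeans(preds),
    sigma = apply(preds, 1, sd),
    risk_proportion = rowMeans(delta > threshold)
  )
}

#' Tidiers and serialisation for metric reports
#'
#' `tidy()` returns the report in long format (one row per metric, with its
#' bootstrap SD when present); `glance()` returns the one-row wide form.
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @export
tidy.metric_report <- function(x, ...) {
  metric_names <- intersect(
    c("r", "R2", "RMSE", "MAE", "RSE", "RAE", "MedAE", "wMAE"), names(x)
  )
  purrr::map_dfr(metric_names, function(m) {
    se_col <- paste0(m, "_se")
    tibble::tibble(
      metric = m,
      value = x[[m]][1],
      uncertainty = if (se_col %in% names(x)) x[[se_col]][1] else NA_real_
    )
  })
}

#' @rdname tidy.metric_report
#' @export
glance.metric_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "metric_report")
  out
}

#' Write a metric report as JSON or one-row CSV
#'
#' @param report A `metric_report`.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @export
write_metric_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(as.data.frame(report)), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(as.data.frame(report), path, progress = FALSE)
  }
  invisible(report)
}
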