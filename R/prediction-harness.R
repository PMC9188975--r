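new_prediction_result <- function(subject_id, true_age, predicted_age,
                                  fold = NA_integer_, set_label = "cv") {
  out <- tibble::tibble(
    subject_id = subject_id,
    true_age = true_age,
    predicted_age = predicted_age,
    fold = as.integer(fold),
    set_label = set_label
  )
  class(out) <- c("prediction_result", class(out))
  out
}

check_prediction_result <- function(result) {
  required <- c("subject_id", "true_age", "predicted_age")
  missing <- setdiff(required, names(result))
  if (length(missing) > 0) {
    abort_invalid(paste0("Prediction result is missing columns: ",
                         paste(missing, collapse = ", ")))
  }
  invisible(result)
}

#' Out-of-fold cross-validated age predictions
#'
#' Splits the cohort into `k` folds by random permutation followed by
#' contiguous chunking, and predicts each fold from a model trained on the
#' remaining folds. Robust scaling is fitted on the training folds only and
#' applied to the held-out fold, so no information leaks from test to train.
#' Every subject is predicted exactly once.
#'
#' @param cohort A cohort tibble.
#' @param regressor A regressor object (default [ridge_regressor()]).
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @return A prediction tibble with columns `subject_id`, `true_age`,
#'   `predicted_age`, `fold`, `set_label = "cv"`.
#' @examples
#' cohort <- generate_cohort(200, age_dist_ukb(),
#'                           signal_profile(n_features = 20, target_model_r = 0.9),
#'                           seed = 1)
#' pred <- crossval_predict(cohort, k = 5, seed = 1)
#' cor(pred$true_age, pred$predicted_age)
#' @export
crossval_predict <- function(cohort, regressor = ridge_regressor(), k = 10, seed) {
  k <- check_count(k, "k", min = 2L)
  seed <- check_count(seed, "seed", min = 0L)
  n <- nrow(cohort)
  if (n < k) abort_invalid("Cohort must have at least `k` subjects.")
  features <- cohort_features(cohort)
  fold_of <- withr::with_seed(seed, {
    perm <- sample.int(n)
    # contiguous chunks of the permutation; sizes differ by at most 1
    sizes <- diff(floor(seq(0, n, length.out = k + 1)))
    fold <- integer(n)
    fold[perm] <- rep(seq_len(k), times = sizes)
    fold
  })
  predicted <- numeric(n)
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    scaled <- robust_scale(features[train_idx, , drop = FALSE])
    fit <- tryCatch(
      fit_regressor(regressor, scaled$scaled, cohort$age[train_idx]),
      error = function(e) {
        abort_invalid(sprintf("Regressor failed on fold %d: %s", f, conditionMessage(e)))
      }
    )
    test_scaled <- robust_scale(features[test_idx, , drop = FALSE], params = scaled$params)
    predicted[test_idx] <- predict_regressor(fit, test_scaled$scaled)
  }
  new_prediction_result(cohort$subject_id, cohort$age, predicted,
                        fold = fold_of, set_label = "cv")
}

#' Train on one cohort, predict another
#'
#' Fits preprocessing (robust scaling) and the regressor on `train` only and
#' returns predictions for the subjects of `test`.
#'
#' @param train,test Cohort tibbles with identical feature schemas and
#'   disjoint subject sets.
#' @param regressor A regressor object.
#' @return A prediction tibble for the test subjects, `set_label = "test"`.
#' @export
train_test_predict <- function(train, test, regressor = ridge_regressor()) {
  f_train <- feature_cols(train)
  f_test <- feature_cols(test)
  if (!identical(f_train, f_test)) {
    abort_invalid("Train and test cohorts have different feature schemas.")
  }
  if (length(intersect(train$subject_id, test$subject_id)) > 0) {
    abort_invalid("Train and test subject sets must be disjoint.")
  }
  scaled <- robust_scale(cohort_features(train))
  fit <- fit_regressor(regressor, scaled$scaled, train$age)
  test_scaled <- robust_scale(cohort_features(test), params = scaled$params)
  new_prediction_result(
    test$subject_id, test$age,
    predict_regressor(fit, test_scaled$scaled),
    fold = NA_integer_, set_label = "test"
  )
}

#' Random split-half of a cohort
#'
#' Splits a cohort into random disjoint halves A and B whose sizes differ by
#' at most one, deterministically given the seed.
#'
#' @param cohort A cohort tibble with at least 4 subjects.
#' @param seed Integer seed.
#' @return A list with cohort tibbles `A` and `B`.
#' @export
split_half <- function(cohort, seed) {
  seed <- check_count(seed, "seed", min = 0L)
  n <- nrow(cohort)
  if (n < 4) abort_invalid("Need at least 4 subjects to split in half.")
  withr::with_seed(seed, {
    idx_a <- sort(sample.int(n, ceiling(n / 2)))
    list(
      A = cohort[idx_a, , drop = FALSE],
      B = cohort[-idx_a, , drop = FALSE]
    )
  })
}

#' Read or write prediction results as CSV
#'
#' @param result A prediction tibble.
#' @param path File path.
#' @return `read_predictions_csv()` returns a prediction tibble.
#' @export
read_predictions_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_prediction_result(out)
  class(out) <- c("prediction_result", class(out))
  out
}

#' @rdname read_predictions_csv
#' @export
write_predictions_csv <- function(result, path) {
  readr::write_csv(result, path, progress = FALSE)
  invisible(result)
}
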