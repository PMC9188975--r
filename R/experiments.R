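#' Default age-range grids
#'
#' The standard grid narrows the range by raising the lower limit while the
#' upper limit stays fixed (`fix = "upper"`): 45--82, 50--82, 55--82, 60--82,
#' 65--82 years. The cross-check grid instead holds the lower limit constant
#' (`fix = "lower"`): 45--82, 45--77, ..., 45--62.
#'
#' @param fix Which limit is held constant while the other narrows.
#' @return A list of `c(lo, hi)` pairs.
#' @export
default_age_ranges <- function(fix = c("upper", "lower")) {
  fix <- match.arg(fix)
  if (fix == "upper") {
    lapply(seq(45, 65, by = 5), function(lo) c(lo, 82))
  } else {
    lapply(seq(82, 62, by = -5), function(hi) c(45, hi))
  }
}

#' Specify an experiment design
#'
#' Bundles the factors an experiment manipulates: the age-range grid, the
#' sample-fraction grid, the shuffle-fraction grid, the number of CV folds,
#' the number of independent seeds each cell is repeated over, and the
#' correction whose metrics are reported alongside the uncorrected ones.
#'
#' Defaults follow the study conditions: five age ranges narrowing from the
#' top (45--82 down to 65--82), sample fractions 2.5, 5, 10, 25, 50, 75 and
#' 100 percent, shuffle fractions 0, 10, 25, 50 and 75 percent, and 10-fold
#' cross-validation.
#'
#' @param design One of `"full_cv"`, `"vary_test_range"`, `"vary_train_range"`,
#'   `"equal_ranges"`, `"range_by_size"`, `"shuffle"`,
#'   `"split_half_correction"`.
#' @param age_ranges List of `c(lo, hi)` pairs in years.
#' @param sample_fractions Fractions in (0, 1\] (used by `range_by_size`).
#' @param shuffle_fractions Fractions in \[0, 1\] (used by `shuffle`).
#' @param k_folds Number of CV folds.
#' @param n_seeds Number of seeds each cell is repeated over.
#' @param correction `"in_sample"` (default), `"train_derived"`, `"cole"`, or
#'   `"quadratic"` -- the corrected metrics reported next to the uncorrected.
#' @param n_boot Bootstrap resamples per cell for metric uncertainties
#'   (0 disables; 200 is the reporting convention).
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(design = c("full_cv", "vary_test_range",
                                       "vary_train_range", "equal_ranges",
                                       "range_by_size", "shuffle",
                                       "split_half_correction"),
                            age_ranges = default_age_ranges(),
                            sample_fractions = c(0.025, 0.05, 0.1, 0.25, 0.5, 0.75, 1),
                            shuffle_fractions = c(0, 0.1, 0.25, 0.5, 0.75),
                            k_folds = 10,
                            n_seeds = 5,
                            correction = c("in_sample", "train_derived",
                                           "cole", "quadratic"),
                            n_boot = 0) {
  design <- match.arg(design)
  correction <- match.arg(correction)
  if (length(age_ranges) == 0) abort_invalid("`age_ranges` must be non-empty.")
  for (rg in age_ranges) {
    if (length(rg) != 2 || rg[1] >= rg[2]) {
      abort_invalid("Each age range must be c(lo, hi) with lo < hi.")
    }
  }
  if (any(sample_fractions <= 0 | sample_fractions > 1)) {
    abort_invalid("`sample_fractions` must be in (0, 1].")
  }
  if (any(shuffle_fractions < 0 | shuffle_fractions > 1)) {
    abort_invalid("`shuffle_fractions` must be in [0, 1].")
  }
  k_folds <- check_count(k_folds, "k_folds", min = 2L)
  n_seeds <- check_count(n_seeds, "n_seeds", min = 1L)
  n_boot <- check_count(n_boot, "n_boot", min = 0L)
  structure(
    list(design = design, age_ranges = age_ranges,
         sample_fractions = sample_fractions,
         shuffle_fractions = shuffle_fractions,
         k_folds = k_folds, n_seeds = n_seeds, correction = correction,
         n_boot = n_boot),
    class = "experiment_spec"
  )
}

# Deterministic derived seeds kept within 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i) %% 2147483629)
}

# Subsample a cohort to exactly n subjects, uniformly without replacement.
sample_to_n <- function(cohort, n, seed) {
  if (nrow(cohort) < n) abort_invalid("Cohort smaller than requested n.")
  if (nrow(cohort) == n) return(cohort)
  withr::with_seed(seed, cohort[sort(sample.int(nrow(cohort), n)), , drop = FALSE])
}

narrowest_range <- function(age_ranges) {
  widths <- vapply(age_ranges, function(r) r[2] - r[1], numeric(1))
  age_ranges[[which.min(widths)]]
}

# Fit the preprocessing + regressor once so several test sets can reuse it.
fit_model <- function(train, regressor) {
  scaled <- robust_scale(cohort_features(train))
  list(
    fit = fit_regressor(regressor, scaled$scaled, train$age),
    params = scaled$params,
    train_mean_age = mean(train$age)
  )
}

predict_cohort <- function(model, cohort, set_label = "test") {
  scaled <- robust_scale(cohort_features(cohort), params = model$params)
  new_prediction_result(
    cohort$subject_id, cohort$age,
    predict_regressor(model$fit, scaled$scaled),
    fold = NA_integer_, set_label = set_label
  )
}

# One experiment cell: uncorrected and corrected metrics from the same
# predictions, plus the diagnostics (prediction SD, mean delta before and
# after correction) that explain the metric patterns. With n_boot >= 2,
# bootstrap SDs of the metrics are appended as *_se columns.
cell_report <- function(pred, correction = "in_sample", ext_fit = NULL,
                        n_boot = 0, boot_seed = 1) {
  un <- core_metrics(pred)
  corrected <- switch(
    correction,
    in_sample = apply_correction(pred, fit_bias(pred, route = "prediction")),
    quadratic = apply_correction(
      pred, fit_bias(pred, route = "prediction", quadratic = TRUE)
    ),
    cole = cole_correct(pred, ext_fit %||% fit_bias(pred, route = "prediction")),
    train_derived = {
      if (is.null(ext_fit)) {
        abort_invalid("train_derived correction needs an external bias fit.")
      }
      apply_correction(pred, ext_fit)
    }
  )
  co <- core_metrics(corrected, corrected = TRUE)
  out <- tibble::tibble(
    r = un$r, r_defined = un$r_defined, R2 = un$R2,
    RMSE = un$RMSE, MAE = un$MAE,
    r_corr = co$r, R2_corr = co$R2, RMSE_corr = co$RMSE, MAE_corr = co$MAE,
    mean_delta = mean(pred$predicted_age - pred$true_age),
    mean_delta_corr = mean(corrected$corrected_predicted_age - pred$true_age),
    sd_pred = sd(pred$predicted_age),
    n_cell = nrow(pred)
  )
  if (n_boot >= 2) {
    bu <- bootstrap_metrics(pred, n_boot = n_boot, seed = boot_seed)
    bc <- bootstrap_metrics(corrected, n_boot = n_boot, seed = boot_seed,
                            corrected = TRUE)
    out <- dplyr::bind_cols(out, tibble::tibble(
      r_se = bu$r_se, R2_se = bu$R2_se, RMSE_se = bu$RMSE_se, MAE_se = bu$MAE_se,
      r_corr_se = bc$r_se, R2_corr_se = bc$R2_se,
      RMSE_corr_se = bc$RMSE_se, MAE_corr_se = bc$MAE_se
    ))
  }
  out
}

as_experiment_result <- function(rows, spec) {
  out <- dplyr::bind_rows(rows)
  attr(out, "spec") <- spec
  class(out) <- c("experiment_result", class(out))
  out
}

#' Full-sample cross-validated comparison of two cohorts
#'
#' Runs k-fold CV with the full age range and sample size of each cohort and
#' reports uncorrected and corrected metrics side by side. With identical
#' per-feature signal, the wide-age-range cohort shows larger r *and* larger
#' RMSE than the narrow one -- errors scale with the age spread, not with
#' model quality.
#'
#' @param cohort_a,cohort_b Cohort tibbles (e.g. a narrow-range and a
#'   wide-range cohort).
#' @param spec An [experiment_spec()].
#' @param regressor A regressor object.
#' @param seed Base integer seed; each repeat uses a derived seed.
#' @return An `experiment_result` tibble, one row per cohort and seed.
#' @export
run_full_cv <- function(cohort_a, cohort_b, spec = experiment_spec("full_cv"),
                        regressor = ridge_regressor(), seed = 1) {
  rows <- purrr::map(seq_len(spec$n_seeds), function(s) {
    s_seed <- derive_seed(seed, s)
    purrr::imap(list(A = cohort_a, B = cohort_b), function(cohort, label) {
      pred <- crossval_predict(cohort, regressor, k = spec$k_folds, seed = s_seed)
      dplyr::bind_cols(
        tibble::tibble(design = "full_cv", cohort = label, seed = s_seed),
        cell_report(pred, spec$correction, n_boot = spec$n_boot, boot_seed = s_seed)
      )
    })
  })
  as_experiment_result(purrr::flatten(rows), spec)
}

#' Varying test-set age range under a fixed full-range training set
#'
#' Splits the cohort 50/50, trains once on the full-range half (subsampled to
#' the constant cell size), and evaluates on test sets restricted to each age
#' range. The constant cell size is the number of subjects available in the
#' narrowest range of the test half. As the test range narrows, uncorrected r
#' falls (range restriction); RMSE/MAE first fall with the shrinking range and
#' then rise as the train--test mean-age difference grows; R-squared can turn
#' negative in the narrowest range.
#'
#' @param cohort A cohort tibble.
#' @inheritParams run_full_cv
#' @return An `experiment_result`, one row per age range and seed.
#' @export
run_vary_test_range <- function(cohort, spec = experiment_spec("vary_test_range"),
                                regressor = ridge_regressor(), seed = 1) {
  narrow <- narrowest_range(spec$age_ranges)
  rows <- purrr::map(seq_len(spec$n_seeds), function(s) {
    s_seed <- derive_seed(seed, s)
    halves <- split_half(cohort, s_seed)
    n_min <- nrow(subset_by_age(halves$B, narrow[1], narrow[2]))
    if (n_min < 10) abort_invalid("Too few subjects in the narrowest test range.")
    train <- sample_to_n(halves$A, min(n_min, nrow(halves$A)), derive_seed(s_seed, 1))
    model <- fit_model(train, regressor)
    purrr::imap(spec$age_ranges, function(rg, i) {
      test <- subset_by_age(halves$B, rg[1], rg[2])
      test <- sample_to_n(test, n_min, derive_seed(s_seed, 100 + i))
      pred <- predict_cohort(model, test)
      dplyr::bind_cols(
        tibble::tibble(design = "vary_test_range", range_lo = rg[1],
                       range_hi = rg[2], seed = s_seed,
                       mean_age_diff = model$train_mean_age - mean(test$age)),
        cell_report(pred, spec$correction, n_boot = spec$n_boot, boot_seed = s_seed)
      )
    })
  })
  as_experiment_result(purrr::flatten(rows), spec)
}

#' Varying training-set age range against a fixed narrow test set
#'
#' Splits the cohort 50/50; one half supplies training sets restricted to
#' each age range (all subsampled to the constant cell size), the other half
#' supplies a single test set restricted to the narrowest range. Uncorrected
#' r stays roughly constant across training ranges (it is set by the test
#' range), while R-squared rises and RMSE/MAE fall as the training range
#' approaches the test range.
#'
#' @inheritParams run_vary_test_range
#' @return An `experiment_result`, one row per training range and seed.
#' @export
run_vary_train_range <- function(cohort, spec = experiment_spec("vary_train_range"),
                                 regressor = ridge_regressor(), seed = 1) {
  narrow <- narrowest_range(spec$age_ranges)
  rows <- purrr::map(seq_len(spec$n_seeds), function(s) {
    s_seed <- derive_seed(seed, s)
    halves <- split_half(cohort, s_seed)
    n_min <- min(
      nrow(subset_by_age(halves$A, narrow[1], narrow[2])),
      nrow(subset_by_age(halves$B, narrow[1], narrow[2]))
    )
    if (n_min < 10) abort_invalid("Too few subjects in the narrowest range.")
    test <- subset_by_age(halves$B, narrow[1], narrow[2])
    test <- sample_to_n(test, n_min, derive_seed(s_seed, 2))
    purrr::imap(spec$age_ranges, function(rg, i) {
      train <- subset_by_age(halves$A, rg[1], rg[2])
      train <- sample_to_n(train, n_min, derive_seed(s_seed, 200 + i))
      model <- fit_model(train, regressor)
      pred <- predict_cohort(model, test)
      dplyr::bind_cols(
        tibble::tibble(design = "vary_train_range", range_lo = rg[1],
                       range_hi = rg[2], seed = s_seed,
                       mean_age_diff = model$train_mean_age - mean(test$age)),
        cell_report(pred, spec$correction, n_boot = spec$n_boot, boot_seed = s_seed)
      )
    })
  })
  as_experiment_result(purrr::flatten(rows), spec)
}

#' Cross-validation within equal-range subsets (optionally crossed with size)
#'
#' Runs k-fold CV within subsets whose training and test age ranges are equal
#' (no mean-age differences by construction), each subsampled to the constant
#' cell size; with a `sample_fractions` grid the cells are further crossed
#' with sample size. All four metrics fall as the range narrows, and improve
#' with sample size within each range.
#'
#' Cells too small for the fold count are skipped with a warning.
#'
#' @inheritParams run_vary_test_range
#' @return An `experiment_result`, one row per range (and fraction) and seed.
#' @export
run_equal_ranges <- function(cohort, spec = experiment_spec("equal_ranges",
                                                            sample_fractions = 1),
                             regressor = ridge_regressor(), seed = 1) {
  narrow <- narrowest_range(spec$age_ranges)
  n_min <- nrow(subset_by_age(cohort, narrow[1], narrow[2]))
  rows <- purrr::map(seq_len(spec$n_seeds), function(s) {
    s_seed <- derive_seed(seed, s)
    purrr::imap(spec$age_ranges, function(rg, i) {
      sub <- subset_by_age(cohort, rg[1], rg[2])
      sub <- sample_to_n(sub, n_min, derive_seed(s_seed, 300 + i))
      purrr::imap(spec$sample_fractions, function(f, j) {
        cell <- if (f < 1) sample_fraction(sub, f, derive_seed(s_seed, 400 + 10 * i + j)) else sub
        if (nrow(cell) < 2 * spec$k_folds) {
          warn(sprintf("Cell range [%g, %g] fraction %g too small; skipped.",
                       rg[1], rg[2], f))
          return(NULL)
        }
        pred <- crossval_predict(cell, regressor, k = spec$k_folds, seed = s_seed)
        dplyr::bind_cols(
          tibble::tibble(design = spec$design, range_lo = rg[1],
                         range_hi = rg[2], fraction = f, seed = s_seed,
                         mean_age_diff = 0),
          cell_report(pred, spec$correction, n_boot = spec$n_boot, boot_seed = s_seed)
        )
      })
    })
  })
  as_experiment_result(purrr::flatten(purrr::flatten(rows)), spec)
}

#' Label-shuffling degradation of the age signal
#'
#' For each shuffle fraction, permutes the ages of that fraction of subjects,
#' runs k-fold CV, and reports uncorrected and corrected metrics. As the
#' fraction grows the model degrades toward predicting the central training
#' age for everyone: prediction SD falls and uncorrected r falls, while the
#' corrected metrics stay high -- the post-correction improvement is largest
#' for the worst models.
#'
#' @inheritParams run_vary_test_range
#' @return An `experiment_result`, one row per shuffle fraction and seed.
#' @export
run_shuffle <- function(cohort, spec = experiment_spec("shuffle"),
                        regressor = ridge_regressor(), seed = 1) {
  rows <- purrr::map(seq_len(spec$n_seeds), function(s) {
    s_seed <- derive_seed(seed, s)
    purrr::imap(spec$shuffle_fractions, function(f, i) {
      shuffled <- shuffle_ages(cohort, f, derive_seed(s_seed, 500 + i))
      pred <- crossval_predict(shuffled, regressor, k = spec$k_folds, seed = s_seed)
      dplyr::bind_cols(
        tibble::tibble(design = "shuffle", shuffle_fraction = f, seed = s_seed),
        cell_report(pred, spec$correction, n_boot = spec$n_boot, boot_seed = s_seed)
      )
    })
  })
  as_experiment_result(purrr::flatten(rows), spec)
}

#' Split-half check of train-derived correction coefficients
#'
#' Splits the cohort into halves A and B; the model trained on A predicts B
#' and vice versa. For each direction the bias-fit coefficients estimated in
#' the *other* half's predictions are applied (train-derived, no leakage) and
#' compared with the in-sample correction of the same predictions. For large
#' samples the two corrections agree within sampling error.
#'
#' @inheritParams run_vary_test_range
#' @return An `experiment_result`, one row per direction and seed, with
#'   `*_corr` columns from the in-sample fit and `*_corr_td` columns from the
#'   train-derived fit.
#' @export
run_split_half_correction <- function(cohort,
                                      spec = experiment_spec("split_half_correction"),
                                      regressor = ridge_regressor(), seed = 1) {
  rows <- purrr::map(seq_len(spec$n_seeds), function(s) {
    s_seed <- derive_seed(seed, s)
    halves <- split_half(cohort, s_seed)
    pred_b <- train_test_predict(halves$A, halves$B, regressor)
    pred_a <- train_test_predict(halves$B, halves$A, regressor)
    purrr::map2(
      list(pred_b, pred_a), list(pred_a, pred_b),
      function(pred, other) {
        direction <- if (identical(pred, pred_b)) "A_to_B" else "B_to_A"
        td_fit <- fit_bias(other, route = "prediction", fit_source = "train_derived")
        base <- cell_report(pred, "in_sample", n_boot = spec$n_boot,
                            boot_seed = s_seed)
        td <- core_metrics(apply_correction(pred, td_fit), corrected = TRUE)
        dplyr::bind_cols(
          tibble::tibble(design = "split_half_correction",
                         direction = direction, seed = s_seed),
          base,
          tibble::tibble(r_corr_td = td$r, R2_corr_td = td$R2,
                         RMSE_corr_td = td$RMSE, MAE_corr_td = td$MAE)
        )
      }
    )
  })
  as_experiment_result(purrr::flatten(rows), spec)
}

#' Write an experiment result as long CSV and JSON summary
#'
#' The CSV holds one row per cell and seed; the JSON summary averages the
#' metric columns over seeds within each cell.
#'
#' @param result An `experiment_result`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return The seed-averaged summary tibble, invisibly.
#' @export
write_experiment_result <- function(result, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    readr::write_csv(as.data.frame(result), csv_path, progress = FALSE)
  }
  summary <- summarise_experiment(result)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.data.frame(summary), json_path, digits = NA, na = "null")
  }
  invisible(summary)
}

#' Average an experiment result over seeds
#'
#' @param result An `experiment_result`.
#' @return A tibble with one row per design cell, numeric columns averaged
#'   over seeds.
#' @export
summarise_experiment <- function(result) {
  factors <- intersect(
    c("design", "cohort", "direction", "range_lo", "range_hi",
      "fraction", "shuffle_fraction"),
    names(result)
  )
  result |>
    dplyr::group_by(dplyr::across(dplyr::all_of(factors))) |>
    dplyr::summarise(
      dplyr::across(dplyr::where(is.numeric) & !dplyr::any_of("seed"),
                    ~ mean(.x, na.rm = TRUE)),
      n_seeds = dplyr::n(),
      .groups = "drop"
    )
}
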