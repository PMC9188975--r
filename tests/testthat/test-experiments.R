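# Scaled-down experiment runs checking the qualitative structure; the
# full-scale study conditions are exercised in test-acceptance.R.

shared_profile <- function() {
  # identical per-feature signal for both cohorts: explicit noise, no
  # per-cohort calibration
  signal_profile(n_features = 40, slope_scale = 1, noise_scale = 35)
}

test_that("full CV: the wide-range cohort shows larger r AND larger RMSE", {
  narrow <- generate_cohort(1500, age_dist_ukb(), shared_profile(), seed = 1)
  wide <- generate_cohort(1500, age_dist_camcan(), shared_profile(), seed = 2)
  spec <- experiment_spec("full_cv", n_seeds = 3)
  res <- run_full_cv(narrow, wide, spec, seed = 3)
  avg <- summarise_experiment(res)
  r_narrow <- avg$r[avg$cohort == "A"]
  r_wide <- avg$r[avg$cohort == "B"]
  expect_gt(r_wide, r_narrow)
  expect_gt(avg$RMSE[avg$cohort == "B"], avg$RMSE[avg$cohort == "A"])
  # correction improves all four metrics for both cohorts
  expect_true(all(avg$r_corr > avg$r))
  expect_true(all(avg$R2_corr > avg$R2))
  expect_true(all(avg$RMSE_corr < avg$RMSE))
  expect_true(all(avg$MAE_corr < avg$MAE))
})

test_that("zero-noise cohorts give r = 1 and RMSE ~ 0 in full CV", {
  a <- noiseless_cohort(n = 300, seed = 4)
  b <- generate_cohort(300, age_dist_camcan(),
                       signal_profile(n_features = 5, noise_scale = 0), seed = 5)
  res <- run_full_cv(a, b, experiment_spec("full_cv", n_seeds = 1), seed = 6)
  expect_true(all(res$r > 0.999))
  expect_true(all(res$RMSE < 0.1))
})

test_that("narrowing the test range lowers r and flips the sign of mean delta", {
  cohort <- generate_cohort(8000, age_dist_ukb(),
                            small_profile(n_features = 40, target_r = 0.73),
                            seed = 7)
  spec <- experiment_spec("vary_test_range", n_seeds = 3)
  res <- run_vary_test_range(cohort, spec, seed = 8)
  avg <- summarise_experiment(res) |> dplyr::arrange(range_lo)
  expect_equal(nrow(avg), 5)
  expect_true(all(diff(avg$r) < 0))
  expect_lt(avg$mean_delta[avg$range_lo == 65], -1.5)
  # in-sample correction removes the mean shift in every cell
  expect_lt(max(abs(res$mean_delta_corr)), 1e-9)
  # prediction SD roughly constant across test sets (fixed training set)
  expect_lt(diff(range(avg$sd_pred)) / mean(avg$sd_pred), 0.35)
})

test_that("varying the training range moves R2 but hardly moves r", {
  cohort <- generate_cohort(8000, age_dist_ukb(),
                            small_profile(n_features = 40, target_r = 0.73),
                            seed = 9)
  spec <- experiment_spec("vary_train_range", n_seeds = 3)
  res <- run_vary_train_range(cohort, spec, seed = 10)
  avg <- summarise_experiment(res) |> dplyr::arrange(range_lo)
  r_spread <- diff(range(avg$r))
  R2_spread <- diff(range(avg$R2))
  expect_lt(r_spread, R2_spread / 5)
  # R2 is maximal where training range matches the test range
  expect_equal(which.max(avg$R2), nrow(avg))
  # narrowest training range: lowest prediction SD, biggest r improvement
  expect_equal(which.min(avg$sd_pred), nrow(avg))
  improvement <- avg$r_corr - avg$r
  expect_equal(which.max(improvement), nrow(avg))
  # RMSE and MAE fall as the training range narrows toward the test range
  expect_lt(avg$RMSE[nrow(avg)], avg$RMSE[1])
  expect_lt(avg$MAE[nrow(avg)], avg$MAE[1])
})

test_that("equal train/test ranges: every metric falls as the range narrows", {
  cohort <- generate_cohort(8000, age_dist_ukb(),
                            small_profile(n_features = 40, target_r = 0.73),
                            seed = 11)
  spec <- experiment_spec("equal_ranges", sample_fractions = 1, n_seeds = 3)
  res <- run_equal_ranges(cohort, spec, seed = 12)
  avg <- summarise_experiment(res) |> dplyr::arrange(range_lo)
  expect_true(all(diff(avg$r) < 0))
  expect_true(all(diff(avg$R2) < 0))
  expect_lt(avg$RMSE[nrow(avg)], avg$RMSE[1])
  expect_lt(avg$MAE[nrow(avg)], avg$MAE[1])
  # corrected errors also fall with the narrower range (lower prediction SD)
  expect_lt(avg$RMSE_corr[nrow(avg)], avg$RMSE_corr[1])
  # constant cell size enforced across ranges
  expect_equal(length(unique(res$n_cell)), 1L)
})

test_that("within each range, metrics improve with sample size", {
  cohort <- generate_cohort(6000, age_dist_ukb(),
                            small_profile(n_features = 40, target_r = 0.73),
                            seed = 13)
  spec <- experiment_spec("range_by_size",
                          age_ranges = list(c(45, 82), c(60, 82)),
                          sample_fractions = c(0.1, 1), n_seeds = 3)
  res <- run_equal_ranges(cohort, spec, seed = 14)
  avg <- summarise_experiment(res)
  for (lo in c(45, 60)) {
    cell <- avg[avg$range_lo == lo, ]
    expect_gte(cell$r[cell$fraction == 1], cell$r[cell$fraction == 0.1])
  }
})

test_that("cells too small for the fold count are skipped with a warning", {
  cohort <- generate_cohort(300, age_dist_ukb(), small_profile(), seed = 15)
  spec <- experiment_spec("range_by_size", age_ranges = list(c(45, 82)),
                          sample_fractions = c(0.05, 1), k_folds = 10,
                          n_seeds = 1)
  expect_warning(res <- run_equal_ranges(cohort, spec, seed = 16), "skipped")
  expect_equal(nrow(res), 1)
})

test_that("label shuffling degrades r and prediction SD monotonically", {
  cohort <- generate_cohort(3000, age_dist_ukb(),
                            small_profile(n_features = 40, target_r = 0.73),
                            seed = 17)
  spec <- experiment_spec("shuffle", shuffle_fractions = c(0, 0.25, 0.75),
                          k_folds = 5, n_seeds = 3)
  res <- run_shuffle(cohort, spec, seed = 18)
  avg <- summarise_experiment(res) |> dplyr::arrange(shuffle_fraction)
  expect_true(all(diff(avg$r) < 0))
  expect_true(all(diff(avg$sd_pred) < 0))
  improvement <- avg$r_corr - avg$r
  expect_equal(which.max(improvement), nrow(avg))
  # corrected metrics stay high for every fraction
  expect_true(all(avg$r_corr > 0.85))
})

test_that("an unshuffled fraction reproduces the plain CV cell exactly", {
  cohort <- generate_cohort(600, age_dist_ukb(), small_profile(), seed = 19)
  spec <- experiment_spec("shuffle", shuffle_fractions = 0, k_folds = 5,
                          n_seeds = 1)
  res <- run_shuffle(cohort, spec, seed = 20)
  s_seed <- res$seed[1]
  direct <- crossval_predict(cohort, k = 5, seed = s_seed)
  expect_equal(res$r[1], core_metrics(direct)$r, tolerance = 1e-12)
})

test_that("the constant-predictor cell shows the inflation pathology exactly", {
  cohort <- constant_feature_cohort(n = 100, seed = 21)
  halves <- split_half(cohort, seed = 22)
  pred <- suppressWarnings(train_test_predict(halves$A, halves$B))
  cell <- brainagekit:::cell_report(pred)
  expect_false(cell$r_defined)
  expect_equal(cell$r_corr, 1)
  expect_equal(cell$RMSE_corr, 0, tolerance = 1e-9)

  # fold-wise CV on the same cohort is the near-exact analogue: each fold's
  # constant differs slightly, so the corrected metrics are close to perfect
  cv <- suppressWarnings(crossval_predict(cohort, k = 5, seed = 23))
  cv_cell <- brainagekit:::cell_report(cv)
  expect_lt(abs(cv_cell$r), 0.5)
  expect_gt(cv_cell$r_corr, 0.99)
})

test_that("train-derived coefficients match in-sample correction at scale", {
  cohort <- generate_cohort(6000, age_dist_ukb(),
                            small_profile(n_features = 40, target_r = 0.73),
                            seed = 23)
  spec <- experiment_spec("split_half_correction", n_seeds = 3)
  res <- run_split_half_correction(cohort, spec, seed = 24)
  avg <- summarise_experiment(res)
  expect_lt(max(abs(avg$r_corr - avg$r_corr_td)), 0.02)
  # symmetric in the two directions
  expect_lt(abs(avg$r[avg$direction == "A_to_B"] -
                  avg$r[avg$direction == "B_to_A"]), 0.05)
  # train-derived correction leaves corr(corrected delta, age) near but not
  # exactly zero (orthogonality is an in-sample property)
  halves <- split_half(cohort, seed = 25)
  pred_b <- train_test_predict(halves$A, halves$B)
  pred_a <- train_test_predict(halves$B, halves$A)
  td <- apply_correction(pred_b, fit_bias(pred_a, route = "prediction",
                                          fit_source = "train_derived"))
  d <- compute_delta(td, corrected = TRUE)$delta
  expect_lt(abs(cor(d, pred_b$true_age)), 0.1)
  expect_gt(abs(cor(d, pred_b$true_age)), 1e-12)
})

test_that("experiment results summarise, serialise and plot", {
  cohort <- generate_cohort(800, age_dist_ukb(), small_profile(), seed = 26)
  spec <- experiment_spec("shuffle", shuffle_fractions = c(0, 0.5),
                          k_folds = 5, n_seeds = 2)
  res <- run_shuffle(cohort, spec, seed = 27)
  expect_s3_class(res, "experiment_result")
  expect_equal(nrow(res), 4)

  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  summary <- write_experiment_result(res, csv, json)
  expect_equal(nrow(summary), 2)
  expect_true(file.exists(csv) && file.exists(json))

  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  p2 <- autoplot(crossval_predict(cohort, k = 5, seed = 1))
  expect_s3_class(p2, "ggplot")
})
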