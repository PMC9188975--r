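# Independent oracle: the metric definitions written as explicit loops.
oracle_core <- function(y, yhat) {
  n <- length(y)
  ybar <- sum(y) / n
  yhatbar <- sum(yhat) / n
  num <- 0; dy <- 0; dyh <- 0; ss_res <- 0; ss_tot <- 0; sae <- 0
  for (i in seq_len(n)) {
    num <- num + (y[i] - ybar) * (yhat[i] - yhatbar)
    dy <- dy + (y[i] - ybar)^2
    dyh <- dyh + (yhat[i] - yhatbar)^2
    ss_res <- ss_res + (yhat[i] - y[i])^2
    ss_tot <- ss_tot + (ybar - y[i])^2
    sae <- sae + abs(yhat[i] - y[i])
  }
  list(
    r = num / sqrt(dy * dyh),
    R2 = 1 - ss_res / ss_tot,
    RMSE = sqrt(ss_res / n),
    MAE = sae / n
  )
}

test_that("perfect predictions give the textbook limits", {
  y <- runif(50, 45, 82)
  m <- core_metrics(make_predictions(y, y))
  expect_equal(m$r, 1)
  expect_equal(m$R2, 1)
  expect_equal(m$RMSE, 0)
  expect_equal(m$MAE, 0)
  a <- alt_metrics(make_predictions(y, y))
  expect_equal(a$RSE, 0)
  expect_equal(a$RAE, 0)
  expect_equal(a$MedAE, 0)
  expect_equal(a$wMAE, 0)
})

test_that("the mean predictor gives R2 = 0, RSE = RAE = 1, undefined r", {
  m <- core_metrics(make_predictions(c(1, 2, 3), c(2, 2, 2)))
  expect_equal(m$R2, 0)
  expect_equal(m$RMSE, sqrt(2 / 3))
  expect_equal(m$MAE, 2 / 3)
  expect_true(is.na(m$r))
  expect_false(m$r_defined)

  y <- runif(100, 45, 82)
  a <- alt_metrics(make_predictions(y, rep(mean(y), 100)))
  expect_equal(a$RSE, 1, tolerance = 1e-12)
  expect_equal(a$RAE, 1, tolerance = 1e-12)
  # RMSE of the mean predictor equals the population SD of true age, exactly
  m2 <- core_metrics(make_predictions(y, rep(mean(y), 100)))
  expect_equal(m2$RMSE, sqrt(mean((y - mean(y))^2)), tolerance = 1e-14)
})

test_that("negative R2 can coexist with a large positive r", {
  m <- core_metrics(make_predictions(c(1, 2, 3), c(3, 3, 4)))
  expect_equal(m$MAE, 4 / 3)
  expect_equal(m$RMSE, sqrt(2))
  expect_equal(m$R2, -2)
  expect_equal(m$r, sqrt(3) / 2)
  a <- alt_metrics(make_predictions(c(1, 2, 3), c(3, 3, 4)))
  expect_equal(a$RSE, 3)
  expect_equal(a$RAE, 2)
  expect_equal(a$MedAE, 1)
})

test_that("metrics match a brute-force evaluation on 1000 random instances", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    y <- rnorm(n, 60, 10)
    yhat <- rnorm(n, 60, 10)
    m <- core_metrics(make_predictions(y, yhat))
    o <- oracle_core(y, yhat)
    expect_equal(m$r, o$r, tolerance = 1e-10)
    expect_equal(m$R2, o$R2, tolerance = 1e-10)
    expect_equal(m$RMSE, o$RMSE, tolerance = 1e-10)
    expect_equal(m$MAE, o$MAE, tolerance = 1e-10)
  }
})

test_that("R2 and RSE are exact complements", {
  set.seed(5)
  for (i in 1:20) {
    y <- rnorm(50, 60, 8)
    yhat <- rnorm(50, 60, 8)
    pred <- make_predictions(y, yhat)
    expect_equal(core_metrics(pred)$R2, 1 - alt_metrics(pred)$RSE,
                 tolerance = 1e-12)
  }
})

test_that("r is affine-invariant in the predictions but RMSE is not", {
  pred <- generate_predictions_direct(runif(300, 45, 82), 0.7, seed = 1)
  squeezed <- pred
  squeezed$predicted_age <- 0.3 * pred$predicted_age + 40
  m0 <- core_metrics(pred)
  m1 <- core_metrics(squeezed)
  expect_equal(m0$r, m1$r, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(m0$RMSE, m1$RMSE)))
})

test_that("restricting the age range attenuates r in expectation", {
  diffs <- vapply(1:50, function(s) {
    ages <- runif(1000, 18, 87)
    pred <- generate_predictions_direct(ages, 0.9, seed = 200 + s)
    full_r <- cor(pred$true_age, pred$predicted_age)
    sub <- pred[pred$true_age >= 60, ]
    full_r - cor(sub$true_age, sub$predicted_age)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("weighted MAE flattens the age distribution's influence", {
  # two age bins, 90/10 split; errors differ by bin
  y <- c(rep(50, 90), rep(70, 10))
  yhat <- y + c(rep(1, 90), rep(11, 10))
  a <- alt_metrics(make_predictions(y, yhat), bin_width = 2)
  # plain MAE is dominated by the common bin, wMAE weights the bins equally
  expect_equal(core_metrics(make_predictions(y, yhat))$MAE, 2)
  expect_equal(a$wMAE, 6)
})

test_that("bootstrap uncertainties behave like sampling theory says", {
  y <- runif(200, 45, 82)
  perfect <- bootstrap_metrics(make_predictions(y, y), n_boot = 50, seed = 1)
  expect_equal(perfect$RMSE_se, 0)
  expect_equal(perfect$MAE_se, 0)

  pred <- generate_predictions_direct(runif(400, 45, 82), 0.7, seed = 2)
  rep200 <- bootstrap_metrics(pred, seed = 3)
  expect_equal(rep200$n_boot, 200L)
  expect_gt(rep200$RMSE_se, 0)
  # uncertainty shrinks roughly as 1/sqrt(n)
  ratios <- vapply(1:10, function(s) {
    small <- generate_predictions_direct(runif(250, 45, 82), 0.7, seed = 400 + s)
    big <- generate_predictions_direct(runif(1000, 45, 82), 0.7, seed = 700 + s)
    bootstrap_metrics(small, n_boot = 200, seed = s)$RMSE_se /
      bootstrap_metrics(big, n_boot = 200, seed = s)$RMSE_se
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2), 0.5)
})

test_that("per-subject uncertainty is tight for a noise-free model", {
  cohort <- noiseless_cohort(n = 120, seed = 4)
  halves <- split_half(cohort, seed = 5)
  iu <- individual_uncertainty(halves$A, halves$B, n_models = 20,
                               threshold = 5, seed = 6)
  expect_equal(nrow(iu), nrow(halves$B))
  expect_lt(max(iu$sigma), 0.5)
  expect_lt(max(abs(iu$mu - iu$true_age)), 1)
  expect_true(all(iu$risk_proportion >= 0 & iu$risk_proportion <= 1))
})

test_that("mu +/- 2 sigma covers the truth for a well-specified noisy model", {
  coverage <- vapply(1:5, function(s) {
    cohort <- generate_cohort(400, age_dist_ukb(),
                              small_profile(n_features = 10, target_r = 0.9),
                              seed = 30 + s)
    halves <- split_half(cohort, seed = s)
    iu <- individual_uncertainty(halves$A, halves$B, n_models = 60,
                                 threshold = 5, seed = s)
    # sigma measures training-resampling spread; the relevant scale for
    # covering the truth adds the residual prediction error
    resid_sd <- sd(iu$mu - iu$true_age)
    mean(abs(iu$mu - iu$true_age) <= 2 * sqrt(iu$sigma^2 + resid_sd^2))
  }, numeric(1))
  expect_gt(mean(coverage), 0.90)
})

test_that("metric reports tidy into long format and serialise", {
  pred <- generate_predictions_direct(runif(100, 45, 82), 0.7, seed = 9)
  report <- bootstrap_metrics(pred, n_boot = 50, seed = 10)
  long <- tidy(report)
  expect_setequal(long$metric, c("r", "R2", "RMSE", "MAE"))
  expect_equal(long$value[long$metric == "RMSE"], report$RMSE)
  expect_equal(long$uncertainty[long$metric == "RMSE"], report$RMSE_se)

  json <- withr::local_tempfile(fileext = ".json")
  write_metric_report(report, json)
  back <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(back$RMSE, report$RMSE, tolerance = 1e-12)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(report, csv)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), 1)
})
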