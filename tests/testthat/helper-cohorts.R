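# Small cohorts and prediction sets built in code for the unit tests.

small_profile <- function(n_features = 20, target_r = NULL, noise = 10) {
  signal_profile(n_features = n_features, slope_scale = 1,
                 noise_scale = noise, target_model_r = target_r)
}

# Zero-noise linear cohort: features are exact affine functions of age.
noiseless_cohort <- function(n = 100, seed = 1, n_features = 5) {
  generate_cohort(n, age_dist_ukb(),
                  signal_profile(n_features = n_features, slope_scale = 1,
                                 noise_scale = 0),
                  seed = seed)
}

# Cohort whose features carry no signal at all (constant columns).
constant_feature_cohort <- function(n = 60, seed = 1) {
  cohort <- generate_cohort(n, age_dist_ukb(),
                            signal_profile(n_features = 3, slope_scale = 0,
                                           noise_scale = 0),
                            seed = seed)
  cohort
}

# A cohort with explicitly chosen ages and trivial features.
make_cohort_with_ages <- function(ages) {
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_along(ages)),
    age = ages,
    site = "site01",
    qc_value = 0,
    f0001 = ages,
    f0002 = -ages
  )
}

# A hand-built prediction tibble.
make_predictions <- function(true_age, predicted_age) {
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_along(true_age)),
    true_age = true_age,
    predicted_age = predicted_age,
    fold = NA_integer_,
    set_label = "test"
  )
}

# Analytic mean and SD of a normal truncated to [lo, hi].
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  m <- mu + sigma * (dnorm(a) - dnorm(b)) / z
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                    ((dnorm(a) - dnorm(b)) / z)^2)
  list(mean = m, sd = sqrt(v))
}
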