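#' Age distribution specifications
#'
#' An age distribution describes how subject ages are drawn when generating a
#' synthetic cohort. Two families are supported: a truncated normal (the shape
#' of a large mid-to-late-life population cohort) and a uniform distribution
#' over a wide lifespan range.
#'
#' `age_dist_ukb()` and `age_dist_camcan()` are convenience constructors with
#' the demographic parameters of the two reference cohorts the generator
#' emulates: a truncated normal with mean 64.15, SD 7.54 on 45--82 years, and
#' a uniform distribution on 18--87 years.
#'
#' @param kind Either `"truncated_normal"` or `"uniform"`.
#' @param mu Mean of the untruncated normal, in years (ignored for uniform).
#' @param sigma SD of the untruncated normal, in years (ignored for uniform).
#' @param lo,hi Lower and upper age limits in years; ages are restricted to
#'   the closed interval `[lo, hi]`.
#' @return An object of class `age_distribution`.
#' @examples
#' age_dist_ukb()
#' age_distribution("uniform", lo = 18, hi = 87)
#' @export
age_distribution <- function(kind = c("truncated_normal", "uniform"),
                             mu = NULL, sigma = NULL, lo, hi) {
  kind <- match.arg(kind)
  check_number(lo, "lo")
  check_number(hi, "hi")
  if (lo >= hi) abort_invalid("`lo` must be strictly less than `hi`.")
  if (kind == "truncated_normal") {
    check_number(mu, "mu")
    check_number(sigma, "sigma")
    if (sigma <= 0) abort_invalid("`sigma` must be > 0 for a truncated normal.")
  }
  structure(
    list(kind = kind, mu = mu, sigma = sigma, lo = lo, hi = hi),
    class = "age_distribution"
  )
}

#' @rdname age_distribution
#' @export
age_dist_ukb <- function() {
  age_distribution("truncated_normal", mu = 64.15, sigma = 7.54, lo = 45, hi = 82)
}

#' @rdname age_distribution
#' @export
age_dist_camcan <- function() {
  age_distribution("uniform", lo = 18, hi = 87)
}

#' @export
print.age_distribution <- function(x, ...) {
  if (x$kind == "truncated_normal") {
    cat(sprintf("<age_distribution> truncated normal, mu = %.2f, sigma = %.2f, range [%g, %g]\n",
                x$mu, x$sigma, x$lo, x$hi))
  } else {
    cat(sprintf("<age_distribution> uniform on [%g, %g]\n", x$lo, x$hi))
  }
  invisible(x)
}

# Rejection sampling from a normal restricted to [lo, hi]. The truncation is
# mild for the default parameters, so the acceptance rate is high.
sample_ages <- function(n, dist) {
  if (dist$kind == "uniform") {
    return(runif(n, dist$lo, dist$hi))
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(n, dist$mu, dist$sigma)
    out <- c(out, draw[draw >= dist$lo & draw <= dist$hi])
  }
  out[seq_len(n)]
}

#' Signal profile for synthetic brain features
#'
#' Describes the linear-in-age signal carried by each synthetic feature:
#' feature j is `slope_j * age + site offset + Gaussian noise`. Slopes have
#' magnitude `slope_scale` with alternating signs (brain measures both grow
#' and shrink with age); noise is i.i.d. Gaussian with SD `noise_scale`.
#'
#' Instead of picking `noise_scale` directly, `target_model_r` calibrates the
#' aggregate signal so that the best linear read-out of the features attains
#' approximately the requested correlation with age: with p features of equal
#' signal-to-noise, averaging the per-feature age estimates leaves residual
#' noise of SD `noise_scale / (slope_scale * sqrt(p))` on the age scale, and
#' the noise is chosen so that this residual yields the requested r given the
#' cohort's age SD. A well-fit regressor then approaches `target_model_r`
#' out of sample.
#'
#' @param n_features Number of features (default 180, the scale of a typical
#'   atlas-based morphometry feature set).
#' @param slope_scale Magnitude of each feature's slope on age
#'   (feature-units per year).
#' @param noise_scale SD of the additive Gaussian noise (feature-units);
#'   ignored when `target_model_r` is given.
#' @param target_model_r Optional target for the achievable model correlation,
#'   in (0, 1].
#' @return An object of class `signal_profile`.
#' @export
signal_profile <- function(n_features = 180, slope_scale = 1,
                           noise_scale = 10, target_model_r = NULL) {
  n_features <- check_count(n_features, "n_features", min = 1L)
  check_number(slope_scale, "slope_scale")
  check_number(noise_scale, "noise_scale", lo = 0)
  if (!is.null(target_model_r)) {
    check_number(target_model_r, "target_model_r")
    if (target_model_r <= 0 || target_model_r > 1) {
      abort_invalid("`target_model_r` must be in (0, 1].")
    }
  }
  structure(
    list(n_features = n_features, slope_scale = slope_scale,
         noise_scale = noise_scale, target_model_r = target_model_r),
    class = "signal_profile"
  )
}

#' Generate a synthetic cohort
#'
#' Draws `n` subjects with ages from `age_dist` and a feature matrix in which
#' each feature carries a linear age signal plus Gaussian noise, optionally
#' with additive per-site offsets and a quality-control covariate (a surrogate
#' for surface-reconstruction quality indices such as the Euler number) that
#' contains occasional outliers.
#'
#' @param n Number of subjects (at least 2).
#' @param age_dist An [age_distribution()].
#' @param profile A [signal_profile()].
#' @param n_sites Number of scanner sites; subjects are assigned uniformly.
#' @param seed Integer seed; the cohort is a deterministic function of all
#'   arguments.
#' @param site_offset_scale SD of the per-site, per-feature additive offset
#'   (0 by default, i.e. no site effect).
#' @param qc_outlier_prop Proportion of subjects whose QC value is an outlier.
#' @return A tibble with columns `subject_id`, `age`, `site`, `qc_value` and
#'   feature columns `f0001` ... `f<p>`.
#' @examples
#' cohort <- generate_cohort(200, age_dist_ukb(), signal_profile(n_features = 20), seed = 1)
#' dplyr::glimpse(cohort[, 1:6])
#' @export
generate_cohort <- function(n, age_dist, profile = signal_profile(),
                            n_sites = 1, seed,
                            site_offset_scale = 0, qc_outlier_prop = 0.01) {
  n <- check_count(n, "n", min = 2L)
  if (!inherits(age_dist, "age_distribution")) {
    abort_invalid("`age_dist` must be an age_distribution object.")
  }
  if (!inherits(profile, "signal_profile")) {
    abort_invalid("`profile` must be a signal_profile object.")
  }
  n_sites <- check_count(n_sites, "n_sites", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  check_number(site_offset_scale, "site_offset_scale", lo = 0)

  p <- profile$n_features
  withr::with_seed(seed, {
    age <- sample_ages(n, age_dist)

    # Alternating-sign slopes of fixed magnitude keep the aggregate
    # signal-to-noise analytically tractable for r-calibration.
    slopes <- profile$slope_scale * rep(c(1, -1), length.out = p)
    noise_scale <- profile$noise_scale
    if (!is.null(profile$target_model_r)) {
      r <- profile$target_model_r
      sigma_age <- sd(age)
      noise_scale <- if (r >= 1) 0 else {
        profile$slope_scale * sqrt(p) * sigma_age * sqrt(1 / r^2 - 1)
      }
    }

    site <- sample.int(n_sites, n, replace = TRUE)
    offsets <- matrix(rnorm(n_sites * p, 0, site_offset_scale), n_sites, p)
    features <- outer(age, slopes) +
      offsets[site, , drop = FALSE] +
      matrix(rnorm(n * p, 0, noise_scale), n, p)
    colnames(features) <- sprintf("f%04d", seq_len(p))

    qc <- rnorm(n, mean = -100, sd = 20)
    n_out <- floor(qc_outlier_prop * n)
    if (n_out > 0) {
      idx <- sample.int(n, n_out)
      qc[idx] <- qc[idx] - 20 * runif(n_out, 5, 10)
    }

    dplyr::bind_cols(
      tibble::tibble(
        subject_id = sprintf("S%06d", seq_len(n)),
        age = age,
        site = sprintf("site%02d", site),
        qc_value = qc
      ),
      tibble::as_tibble(features)
    )
  })
}

#' Generate predictions directly from ages
#'
#' A bivariate surrogate for a fitted age-prediction model: predictions are
#' `mean(age) + target_r * (age - mean(age)) + noise`, with the noise SD set
#' so that the population correlation between prediction and age equals
#' `target_r`. Useful for testing metrics and corrections without running a
#' regressor.
#'
#' @param ages Numeric vector of true ages (at least 3, nonzero variance).
#' @param target_r Target correlation in \[0, 1\].
#' @param seed Integer seed.
#' @return A prediction tibble with columns `subject_id`, `true_age`,
#'   `predicted_age`, `fold`, `set_label`.
#' @examples
#' pred <- generate_predictions_direct(runif(100, 45, 82), target_r = 0.9, seed = 1)
#' cor(pred$true_age, pred$predicted_age)
#' @export
generate_predictions_direct <- function(ages, target_r, seed) {
  if (length(ages) < 3) abort_invalid("Need at least 3 ages.")
  check_number(target_r, "target_r", lo = 0, hi = 1)
  seed <- check_count(seed, "seed", min = 0L)
  sigma <- sd(ages)
  if (!is.finite(sigma) || sigma == 0) {
    abort_degenerate("Ages have zero variance; predictions would be undefined.")
  }
  withr::with_seed(seed, {
    m <- mean(ages)
    tau <- sigma * sqrt(1 - target_r^2)
    predicted <- m + target_r * (ages - m) + rnorm(length(ages), 0, tau)
    new_prediction_result(
      subject_id = sprintf("S%06d", seq_along(ages)),
      true_age = ages,
      predicted_age = predicted,
      fold = NA_integer_,
      set_label = "direct"
    )
  })
}

#' Shuffle a fraction of age labels
#'
#' Selects `floor(fraction * n)` subjects uniformly at random and permutes
#' their ages among themselves; features and all other columns are untouched,
#' and the multiset of ages is preserved. This degrades the learnable
#' age--feature association in proportion to the fraction shuffled.
#'
#' @param cohort A cohort tibble.
#' @param fraction Proportion of subjects to shuffle, in \[0, 1\].
#' @param seed Integer seed.
#' @return A cohort tibble of the same shape.
#' @export
shuffle_ages <- function(cohort, fraction, seed) {
  check_number(fraction, "fraction", lo = 0, hi = 1)
  seed <- check_count(seed, "seed", min = 0L)
  n <- nrow(cohort)
  m <- floor(fraction * n)
  if (m < 2) return(cohort)
  withr::with_seed(seed, {
    idx <- sample.int(n, m)
    perm <- sample.int(m)
    cohort$age[idx] <- cohort$age[idx][perm]
    cohort
  })
}

#' Subset a cohort by age range
#'
#' Retains exactly the subjects with `lo <= age <= hi` (closed interval),
#' preserving order.
#'
#' @param cohort A cohort tibble.
#' @param lo,hi Age limits in years, `lo < hi`.
#' @return The filtered cohort tibble.
#' @export
subset_by_age <- function(cohort, lo, hi) {
  check_number(lo, "lo")
  check_number(hi, "hi")
  if (lo >= hi) abort_invalid("`lo` must be strictly less than `hi`.")
  out <- dplyr::filter(cohort, .data$age >= lo, .data$age <= hi)
  if (nrow(out) == 0) {
    abort_empty(sprintf("No subjects with age in [%g, %g].", lo, hi))
  }
  out
}

#' Sample a fraction of a cohort
#'
#' Draws `floor(fraction * n)` subjects uniformly without replacement,
#' deterministic given the seed. Row order follows the original cohort.
#'
#' @param cohort A cohort tibble.
#' @param fraction Proportion to retain, in (0, 1\].
#' @param seed Integer seed.
#' @return The subsampled cohort tibble.
#' @export
sample_fraction <- function(cohort, fraction, seed) {
  check_number(fraction, "fraction")
  if (fraction <= 0 || fraction > 1) {
    abort_invalid("`fraction` must be in (0, 1].")
  }
  seed <- check_count(seed, "seed", min = 0L)
  n <- nrow(cohort)
  m <- floor(fraction * n)
  if (m < 2) abort_invalid("Resulting cohort would have fewer than 2 subjects.")
  withr::with_seed(seed, {
    idx <- sort(sample.int(n, m))
    cohort[idx, , drop = FALSE]
  })
}

#' Read or write a cohort as CSV
#'
#' Cohorts are stored as UTF-8 CSV with a header and the columns
#' `subject_id, age, site, qc_value, f0001, ...`.
#'
#' @param path File path.
#' @param cohort A cohort tibble.
#' @return `read_cohort_csv()` returns a cohort tibble; `write_cohort_csv()`
#'   returns `cohort` invisibly.
#' @export
read_cohort_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "age")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort_invalid(paste0("Cohort CSV is missing columns: ",
                         paste(missing, collapse = ", ")))
  }
  if (anyNA(out$age)) abort_invalid("Cohort CSV contains missing ages.")
  out
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(cohort)
}
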