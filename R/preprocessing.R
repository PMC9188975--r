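#' Robust scaling of a feature matrix
#'
#' Transforms each column to `(x - median) / (q75 - q25)`, the robust-scaler
#' convention: the median is removed and the data scaled by the interquartile
#' range, using linear-interpolation (type 7) quantiles. When `params` is
#' supplied the transform is applied with those (train-fitted) parameters;
#' otherwise parameters are fitted on `features` and returned, supporting the
#' train-fit / test-apply contract.
#'
#' Constant columns (zero quantile range) are scaled by 1 with a warning.
#'
#' @param features Numeric matrix (subjects by features) or a data frame of
#'   numeric columns.
#' @param params Optional `scale_params` from a previous fit.
#' @return A list with elements `scaled` (matrix) and `params` (a
#'   `scale_params` tibble with columns `feature`, `center`, `scale`).
#' @examples
#' robust_scale(cbind(x = c(1, 2, 3, 4, 100)))$scaled
#' @export
robust_scale <- function(features, params = NULL) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  if (is.null(params)) {
    if (nrow(x) < 2) abort_invalid("Need at least 2 rows to fit scale parameters.")
    center <- unname(apply(x, 2, median))
    qr <- unname(apply(x, 2, function(col) {
      diff(quantile(col, c(0.25, 0.75), names = FALSE, type = 7))
    }))
    if (any(qr == 0)) {
      warn(sprintf("%d constant feature(s) scaled by 1.", sum(qr == 0)))
      qr[qr == 0] <- 1
    }
    params <- tibble::tibble(feature = colnames(x), center = center, scale = qr)
    class(params) <- c("scale_params", class(params))
  } else {
    if (!all(colnames(x) %in% params$feature)) {
      abort_invalid("`params` does not cover all feature columns.")
    }
    params <- params[match(colnames(x), params$feature), ]
  }
  scaled <- sweep(sweep(x, 2, params$center, "-"), 2, params$scale, "/")
  list(scaled = scaled, params = params)
}

#' Invert a robust-scaling transform
#'
#' @param scaled Matrix returned by [robust_scale()].
#' @param params The `scale_params` used for scaling.
#' @return The matrix on the original scale.
#' @export
robust_unscale <- function(scaled, params) {
  x <- as.matrix(scaled)
  params <- params[match(colnames(x), params$feature), ]
  sweep(sweep(x, 2, params$scale, "*"), 2, params$center, "+")
}

#' Serialise scale parameters to and from JSON
#'
#' @param params A `scale_params` tibble.
#' @param path JSON file path.
#' @return `scale_params_from_json()` returns a `scale_params` tibble.
#' @export
scale_params_to_json <- function(params, path) {
  jsonlite::write_json(as.data.frame(params), path, digits = NA)
  invisible(params)
}

#' @rdname scale_params_to_json
#' @export
scale_params_from_json <- function(path) {
  out <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  class(out) <- c("scale_params", class(out))
  out
}

#' Residualise features with respect to scanner site
#'
#' Removes additive site effects: per feature, an ordinary-least-squares fit
#' on site indicator variables is computed and the output is the residuals
#' plus the grand mean, so the feature scale and overall level are retained.
#' After the transform, per-site means are equal for every feature. With a
#' single site the input is returned unchanged.
#'
#' @param features Numeric matrix (subjects by features).
#' @param site Character or factor vector of site labels, one per row.
#' @return A matrix of the same shape.
#' @export
residualise_site <- function(features, site) {
  x <- as.matrix(features)
  if (length(site) != nrow(x)) {
    abort_invalid("`site` must have one label per row of `features`.")
  }
  if (anyNA(site)) abort_invalid("`site` contains missing labels.")
  site <- as.factor(site)
  # OLS on site indicators reduces to subtracting per-site means.
  site_means <- apply(x, 2, function(col) tapply(col, site, mean))
  if (nlevels(site) == 1L) site_means <- matrix(site_means, nrow = 1)
  grand <- colMeans(x)
  out <- x - site_means[as.integer(site), , drop = FALSE] +
    matrix(grand, nrow(x), ncol(x), byrow = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Single-pass outlier exclusion
#'
#' Retains the indices of values within `k` standard deviations of the mean,
#' with mean and SD computed once on the full input (no iteration after
#' removals). This is the rule used for quality-control covariates such as
#' surface-reconstruction Euler numbers, where values 3 or more SDs from the
#' mean indicate poor-quality data. Zero SD retains everything.
#'
#' @param values Numeric vector (at least 2 values).
#' @param k Number of SDs (default 3).
#' @return Integer vector of retained indices.
#' @examples
#' exclude_outliers(c(0, 0, 0, 0, 100))
#' @export
exclude_outliers <- function(values, k = 3) {
  if (length(values) < 2) abort_invalid("Need at least 2 values.")
  check_number(k, "k")
  if (k <= 0) abort_invalid("`k` must be > 0.")
  s <- sd(values)
  if (!is.finite(s) || s == 0) return(seq_along(values))
  which(abs(values - mean(values)) < k * s)
}
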