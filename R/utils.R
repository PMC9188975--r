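#' @importFrom rlang abort warn .data %||%
#' @importFrom stats coef cor lm median predict quantile rnorm runif sd setNames
#' @importFrom utils head
NULL

abort_invalid <- function(msg) {
  abort(msg, class = "brainagekit_invalid_argument")
}

abort_degenerate <- function(msg) {
  abort(msg, class = "brainagekit_degenerate_input")
}

abort_empty <- function(msg) {
  abort(msg, class = "brainagekit_empty_subset")
}

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_invalid(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lo || x > hi) {
    abort_invalid(sprintf("`%s` must be in [%s, %s], got %s.", name, lo, hi, x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, lo = min)
  if (x != as.integer(x)) {
    abort_invalid(sprintf("`%s` must be a whole number.", name))
  }
  invisible(as.integer(x))
}

# Feature columns follow the f0001, f0002, ... naming convention.
feature_cols <- function(df) {
  grep("^f[0-9]+$", names(df), value = TRUE)
}

#' Extract the feature matrix of a cohort
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @return A numeric matrix, subjects by features.
#' @export
cohort_features <- function(cohort) {
  cols <- feature_cols(cohort)
  if (length(cols) == 0L) {
    abort_invalid("Cohort has no feature columns (expected names like 'f0001').")
  }
  as.matrix(cohort[, cols, drop = FALSE])
}

# Population (divide-by-N) standard deviation, the convention used throughout
# the metric definitions.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}
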