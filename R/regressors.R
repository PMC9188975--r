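#' Pluggable regressor contract
#'
#' A regressor is any object for which [fit_regressor()] and
#' [predict_regressor()] are defined. `fit_regressor(reg, x, y)` returns a
#' fitted model; `predict_regressor(fitted, x)` returns one finite predicted
#' age per row. Fits must be deterministic given the regressor's own seed.
#'
#' The default baseline, `ridge_regressor()`, is L2-regularised linear least
#' squares with an unpenalised intercept, solved in closed form: fast, exactly
#' deterministic, and sufficient because the phenomena under study are
#' properties of least-squares regression itself rather than of any particular
#' learning algorithm. A gradient-boosted tree regressor
#' (`xgboost_regressor()`) is available when the xgboost package is installed.
#'
#' @param regressor A regressor object.
#' @param x Numeric feature matrix.
#' @param y Numeric response (ages in years).
#' @param fitted A fitted model returned by `fit_regressor()`.
#' @name regressor
NULL

#' @rdname regressor
#' @export
fit_regressor <- function(regressor, x, y) {
  UseMethod("fit_regressor")
}

#' @rdname regressor
#' @export
predict_regressor <- function(fitted, x) {
  UseMethod("predict_regressor")
}

#' @rdname regressor
#' @param lambda Ridge penalty on the (scaled) features; default 1.
#' @export
ridge_regressor <- function(lambda = 1) {
  check_number(lambda, "lambda", lo = 0)
  structure(list(lambda = lambda), class = c("ridge_regressor", "brainage_regressor"))
}

#' @export
fit_regressor.ridge_regressor <- function(regressor, x, y) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) abort_invalid("`x` and `y` disagree on n.")
  xbar <- colMeans(x)
  ybar <- mean(y)
  xc <- sweep(x, 2, xbar)
  p <- ncol(x)
  xtx <- crossprod(xc) + diag(regressor$lambda, p)
  beta <- solve(xtx, crossprod(xc, y - ybar))
  structure(
    list(beta = drop(beta), intercept = ybar - sum(xbar * drop(beta))),
    class = "ridge_fit"
  )
}

#' @export
predict_regressor.ridge_fit <- function(fitted, x) {
  drop(as.matrix(x) %*% fitted$beta) + fitted$intercept
}

#' @rdname regressor
#' @param nrounds,max_depth,eta Gradient-boosting hyperparameters.
#' @param seed Seed for the boosting fit.
#' @export
xgboost_regressor <- function(nrounds = 100, max_depth = 3, eta = 0.1, seed = 1) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    abort_invalid("xgboost_regressor() requires the xgboost package.")
  }
  structure(
    list(nrounds = nrounds, max_depth = max_depth, eta = eta, seed = seed),
    class = c("xgboost_regressor", "brainage_regressor")
  )
}

#' @export
fit_regressor.xgboost_regressor <- function(regressor, x, y) {
  fit <- withr::with_seed(regressor$seed, {
    xgboost::xgboost(
      data = as.matrix(x), label = y,
      nrounds = regressor$nrounds,
      params = list(max_depth = regressor$max_depth, eta = regressor$eta,
                    objective = "reg:squarederror", nthread = 1),
      verbose = 0
    )
  })
  structure(list(booster = fit), class = "xgboost_fit")
}

#' @export
predict_regressor.xgboost_fit <- function(fitted, x) {
  predict(fitted$booster, as.matrix(x))
}
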