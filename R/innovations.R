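#' Autoregressive innovations with AIC lag selection
#'
#' Fits AR(p) predictors by ordinary least squares for p = 1..`max_lag` and
#' keeps the order minimizing the Akaike information criterion. The
#' residuals of the selected predictor are the series' innovations: for an
#' optimal predictor they are white, which is what licenses treating them as
#' an iid sample in the downstream mutual-information estimate.
#'
#' @param x numeric series.
#' @param max_lag largest order searched; defaults to `min(10, n %/% 10)`.
#' @return An object of class `innovation_series`: list with `residuals`
#'   (length `n - lag`), `lag`, `coef` (intercept first), `kind` (`"AR"`),
#'   `aic`, and `sigma2`.
#' @export
fit_ar_innovations <- function(x, max_lag = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(max_lag)) max_lag <- max(1L, min(10L, n %/% 10L))
  max_lag <- as.integer(max_lag)
  if (n < 3L * max_lag) stop("series too short (", n, ") for max_lag ", max_lag)
  if (sd(x) < 1e-12) stop("degenerate input: constant series (zero variance)")
  sw <- .ar_sweep(x, max_lag)
  structure(list(residuals = as.vector(sw$residuals), lag = sw$lag,
                 coef = as.vector(sw$coef), kind = "AR", aic = sw$aic,
                 sigma2 = sw$sigma2),
            class = "innovation_series")
}

#' Vector-autoregressive joint innovations with AIC lag selection
#'
#' Fits a bivariate VAR(p) by equation-wise least squares for
#' p = 1..`max_lag`, selecting p by AIC on the log determinant of the
#' residual covariance. The two residual columns are the joint innovations
#' of x and y given the past of both series. Near-collinear pairs
#' (|cor| > 1 - 1e-10) are fit with a small ridge penalty and a warning.
#'
#' @param x,y numeric series of equal length.
#' @param max_lag largest order searched; default as in
#'   [fit_ar_innovations()].
#' @return An `innovation_series` whose `residuals` is a 2-column matrix
#'   (columns: x-equation, y-equation) and `coef` a coefficient matrix with
#'   one column per equation.
#' @export
fit_var_innovations <- function(x, y, max_lag = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("series lengths differ: ", n, " vs ", length(y))
  if (is.null(max_lag)) max_lag <- max(1L, min(10L, n %/% 10L))
  max_lag <- as.integer(max_lag)
  if (n < 3L * max_lag) stop("series too short (", n, ") for max_lag ", max_lag)
  if (sd(x) < 1e-12 || sd(y) < 1e-12)
    stop("degenerate input: constant series (zero variance)")
  ridge <- 0
  if (abs(stats::cor(x, y)) > 1 - 1e-10) {
    warning("near-collinear pair; using ridge-regularized VAR fit")
    ridge <- 1e-8
  }
  sw <- .var_sweep(x, y, max_lag, ridge)
  structure(list(residuals = sw$residuals, lag = sw$lag, coef = sw$coef,
                 kind = "VAR", aic = sw$aic, sigma = sw$sigma),
            class = "innovation_series")
}

#' Ljung-Box whiteness diagnostic for innovations
#'
#' Optional check that selected-order innovations are serially uncorrelated
#' (the iid assumption behind the innovation MI estimator). Thin wrapper
#' over [stats::Box.test()].
#'
#' @param innov an `innovation_series` or numeric vector of residuals.
#' @param lag number of autocorrelations tested.
#' @return p-value of the Ljung-Box test.
#' @export
ljung_box_pvalue <- function(innov, lag = 10) {
  r <- if (inherits(innov, "innovation_series")) innov$residuals else innov
  r <- as.matrix(r)[, 1]
  stats::Box.test(r, lag = lag, type = "Ljung-Box")$p.value
}
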