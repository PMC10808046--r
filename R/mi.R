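#' Gaussian kernel density estimate
#'
#' One- or two-dimensional Gaussian-kernel density with per-dimension
#' Silverman rule-of-thumb bandwidths (`0.9 min(sd, IQR/1.34) n^{-1/5}` in
#' 1-D, `sd * n^{-1/6}` per dimension in 2-D, i.e. the d = 2 normal
#' reference rule with a diagonal bandwidth matrix). Returns a closure that
#' evaluates the density (or log density) at arbitrary points.
#'
#' @param samples numeric vector (1-D) or 2-column matrix (2-D) of support
#'   samples.
#' @param bandwidth optional bandwidth override (length 1 or 2).
#' @return An object of class `kde_estimate`: list with `dimension`,
#'   `bandwidth`, `samples`, and evaluators `logf(x[, y])` / `f(x[, y])`.
#' @export
kde_estimate <- function(samples, bandwidth = NULL) {
  samples <- as.matrix(samples)
  d <- ncol(samples)
  n <- nrow(samples)
  if (!d %in% 1:2) stop("only 1- or 2-dimensional KDEs are supported")
  if (is.null(bandwidth)) {
    bandwidth <- if (d == 1L) {
      silverman_bw(samples[, 1])
    } else {
      apply(samples, 2, sd) * n^(-1 / 6)
    }
  }
  bandwidth <- pmax(bandwidth, 1e-12)
  if (d == 1L) {
    s <- samples[, 1]
    h <- bandwidth[1]
    logf <- function(x) .kde_logf_1d(as.numeric(x), s, h)
  } else {
    s1 <- samples[, 1]; s2 <- samples[, 2]
    h1 <- bandwidth[1]; h2 <- bandwidth[2]
    logf <- function(x, y) .kde_logf_2d(as.numeric(x), as.numeric(y), s1, s2,
                                        h1, h2)
  }
  structure(list(dimension = d, kernel = "gaussian", bandwidth = bandwidth,
                 samples = samples, logf = logf,
                 f = function(...) exp(logf(...))),
            class = "kde_estimate")
}

silverman_bw <- function(z) {
  n <- length(z)
  spread <- min(sd(z), IQR(z) / 1.34)
  if (spread < 1e-12) spread <- sd(z) + 1e-12
  0.9 * spread * n^(-1 / 5)
}

#' Plug-in differential entropy of an innovation stream
#'
#' Resubstitution estimate `H = -mean(log f_hat(e_t))` where `f_hat` is the
#' 1-D Gaussian KDE built on the same samples. Innovations are standardized
#' to zero mean and unit variance first: mutual information is invariant to
#' marginal affine maps, and standardization keeps the differential
#' entropies positive so the entropy-normalized MI is well behaved.
#'
#' @param innov numeric vector of residuals (1-column innovations).
#' @param min_n minimum sample count (default 30).
#' @return Entropy in nats.
#' @export
estimate_entropy <- function(innov, min_n = 30L) {
  innov <- as.numeric(innov)
  if (length(innov) < min_n)
    stop("need at least ", min_n, " samples, got ", length(innov))
  z <- standardize(innov)
  kd <- kde_estimate(z)
  -mean(kd$logf(z))
}

standardize <- function(z) {
  s <- sd(z)
  if (s < 1e-12) stop("degenerate input: zero-variance residuals")
  (z - mean(z)) / s
}

#' Innovation-approach mutual information between two series
#'
#' Estimates the per-time-point mutual information I(X_t; Y_t) for
#' temporally correlated series by first whitening: AR innovations of each
#' series capture its own past, joint VAR innovations capture the shared
#' past, and for optimal predictors the innovations are iid, so the joint
#' density over the whole series factorizes per time point. Marginal (1-D)
#' and joint (2-D) innovation densities are estimated by Gaussian KDE and
#' the MI is the resubstitution sample average
#' `I = mean(log p2(e_x, e_y) - log p_x(e_x) - log p_y(e_y))`
#' over the time points where all three residual streams are defined.
#' The normalized value divides twice the (zero-floored) MI by the sum of
#' the marginal innovation entropies.
#'
#' @param x,y numeric series of equal length.
#' @param max_lag AIC search range for AR/VAR order (default
#'   `min(10, n %/% 10)`).
#' @param check_whiteness if `TRUE`, warn when a Ljung-Box test rejects
#'   whiteness of either AR innovation stream at alpha = 0.01.
#' @return An object of class `mi_result`: list with `mi` (nats, may be
#'   slightly negative from estimator noise), `mi_normalized`
#'   (`2 * max(mi, 0) / (entropy_x + entropy_y)`), `entropy_x`, `entropy_y`,
#'   `lags` (named: x, y, var), and `n` (aligned sample count).
#' @export
mutual_information <- function(x, y, max_lag = NULL,
                               check_whiteness = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("series lengths differ: ", length(x), " vs ", length(y))
  ax <- fit_ar_innovations(x, max_lag)
  ay <- fit_ar_innovations(y, max_lag)
  vv <- fit_var_innovations(x, y, max_lag)
  if (isTRUE(check_whiteness)) {
    if (ljung_box_pvalue(ax) < 0.01 || ljung_box_pvalue(ay) < 0.01)
      warning("AR innovations fail Ljung-Box whiteness at alpha = 0.01; ",
              "iid assumption of the MI estimator may be violated")
  }
  ex <- standardize(ax$residuals)
  ey <- standardize(ay$residuals)
  # deterministic-pair convention: if one series is exactly predictable from
  # the joint past (zero joint-innovation variance, e.g. an exact shifted
  # copy), the pair carries maximal shared information; its joint innovation
  # geometry is the diagonal, as for an identical pair
  vres <- vv$residuals
  degx <- sd(vres[, 1]) < 1e-8 * sd(x)
  degy <- sd(vres[, 2]) < 1e-8 * sd(y)
  if (degx && !degy) vres[, 1] <- vres[, 2]
  if (degy && !degx) vres[, 2] <- vres[, 1]
  if (degx && degy) stop("degenerate pair: both joint innovations are zero")
  evx <- standardize(vres[, 1])
  evy <- standardize(vres[, 2])
  # residual streams start at different offsets (their own lag); align on
  # the common trailing time points
  N <- min(length(ex), length(ey), length(evx))
  exa <- tail_n(ex, N); eya <- tail_n(ey, N)
  evxa <- tail_n(evx, N); evya <- tail_n(evy, N)

  kx <- kde_estimate(ex)
  ky <- kde_estimate(ey)
  kj <- kde_estimate(cbind(evx, evy))
  # the aligned AR-innovation points are the trailing subset of each full
  # stream, so their log densities are reused from the entropy evaluation
  lfx <- kx$logf(ex)
  lfy <- ky$logf(ey)
  mi <- mean(kj$logf(evxa, evya) - tail_n(lfx, N) - tail_n(lfy, N))
  hx <- -mean(lfx)
  hy <- -mean(lfy)
  structure(list(mi = mi,
                 mi_normalized = 2 * max(mi, 0) / (hx + hy),
                 entropy_x = hx, entropy_y = hy,
                 lags = c(x = ax$lag, y = ay$lag, var = vv$lag),
                 n = N),
            class = "mi_result")
}

tail_n <- function(z, n) z[(length(z) - n + 1L):length(z)]
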