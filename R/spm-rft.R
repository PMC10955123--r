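#' Estimate field smoothness (FWHM) from residual curves
#'
#' Random-field-theory inference needs the smoothness of the underlying
#' Gaussian field, expressed as the FWHM (in nodes) of the equivalent
#' Gaussian kernel that would produce the observed residual roughness from
#' white noise. The estimate uses the mean squared gradient of the
#' variance-normalized residuals: `v(q) = sum_i r_i'(q)^2 / sum_i r_i(q)^2`,
#' averaged over nodes, and `FWHM = sqrt(4 log 2 / vbar)`.
#'
#' @param residuals numeric matrix of residual curves, one row per curve.
#' @return FWHM in node units; `Inf` (with a warning) for effectively
#'   constant-gradient residuals.
#' @export
estimate_fwhm <- function(residuals) {
  R <- as.matrix(residuals)
  if (nrow(R) < 2L) stop("need at least 2 residual curves", call. = FALSE)
  Q <- ncol(R)
  ssq <- colSums(R^2)
  if (all(ssq <= .Machine$double.eps))
    stop("zero-variance residuals: smoothness undefined", call. = FALSE)
  # central-difference gradient along nodes (one-sided at ends)
  G <- t(apply(R, 1L, num_gradient))
  v <- colSums(G^2) / pmax(ssq, .Machine$double.xmin)
  vbar <- mean(v[ssq > .Machine$double.eps])
  if (vbar < 1e-12) {
    warning("residuals are effectively infinitely smooth (constant gradient)")
    return(Inf)
  }
  sqrt(4 * log(2) / vbar)
}

num_gradient <- function(x) {
  n <- length(x)
  g <- numeric(n)
  g[1] <- x[2] - x[1]
  g[n] <- x[n] - x[n - 1]
  if (n > 2L) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  g
}

# 1D Euler-characteristic density of an F field with df = (k, v) at height u
ec_density_f_1d <- function(u, k, v) {
  if (u <= 0) return(Inf)
  lg <- lgamma((v + k - 1) / 2) - lgamma(v / 2) - lgamma(k / 2)
  sqrt(4 * log(2) / pi) * exp(lg) *
    (k * u / v)^((k - 1) / 2) * (1 + k * u / v)^(-(v + k - 2) / 2)
}

# Expected suprathreshold Euler characteristic of a 1D F field over
# `resels` resolution elements (plus the point term)
expected_ec_f <- function(u, df, resels) {
  stats::pf(u, df[1], df[2], lower.tail = FALSE) +
    resels * ec_density_f_1d(u, df[1], df[2])
}

#' Random-field-theory critical F threshold for a 1D field
#'
#' The smallest height `u` at which the expected suprathreshold Euler
#' characteristic of a smooth F field of length `Q` nodes and smoothness
#' `fwhm` drops to `alpha`. With `resels = (Q - 1) / fwhm` the expectation is
#' the point exceedance probability plus `resels` times the 1D EC density of
#' the F field; the equation is solved by bisection to 1e-6. As
#' `resels -> 0` the threshold reduces to the ordinary F quantile (no
#' multiple-comparison problem left).
#'
#' @param df degrees of freedom `c(df1, df2)`.
#' @param fwhm field smoothness in nodes.
#' @param Q number of field nodes.
#' @param alpha familywise error level in (0, 1).
#' @return critical F value.
#' @export
rft_critical_threshold <- function(df, fwhm, Q, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (df[2] <= 0) stop("df2 must be positive", call. = FALSE)
  if (fwhm <= 0) stop("fwhm must be positive", call. = FALSE)
  resels <- (Q - 1) / fwhm
  lo <- stats::qf(1 - alpha, df[1], df[2])   # EC expectation >= alpha here
  hi <- lo + 1
  while (expected_ec_f(hi, df, resels) > alpha && hi < 1e8) hi <- hi * 2
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (expected_ec_f(mid, df, resels) > alpha) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
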