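#' Fractional anisotropy from tensor eigenvalues
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, the normalized
#' dispersion of the three diffusion-tensor eigenvalues: 0 for isotropic
#' diffusion, 1 for diffusion along a single axis.
#'
#' @param eigenvalues numeric triple (or matrix with 3 columns, one triple
#'   per row), all `>= 0` and not all zero.
#' @return FA in `[0, 1]`.
#' @examples
#' fractional_anisotropy(c(1.7, 0.2, 0.2) * 1e-3)  # 0.8704
#' @export
fractional_anisotropy <- function(eigenvalues) {
  ev <- if (is.matrix(eigenvalues)) eigenvalues else matrix(eigenvalues, ncol = 3)
  if (ncol(ev) != 3L) stop("need 3 eigenvalues", call. = FALSE)
  if (any(ev < -1e-12)) stop("eigenvalues must be >= 0", call. = FALSE)
  ev <- pmax(ev, 0)
  nrm2 <- rowSums(ev^2)
  if (any(nrm2 == 0)) stop("all-zero eigenvalues: FA undefined", call. = FALSE)
  mbar <- rowMeans(ev)
  fa <- sqrt(1.5 * rowSums((ev - mbar)^2) / nrm2)
  if (!is.matrix(eigenvalues)) fa <- as.numeric(fa)
  fa
}

# 6-vector (xx, xy, xz, yy, yz, zz) <-> symmetric 3x3
tensor6_to_mat <- function(d6) {
  matrix(c(d6[1], d6[2], d6[3],
           d6[2], d6[4], d6[5],
           d6[3], d6[5], d6[6]), 3, 3)
}

mat_to_tensor6 <- function(D) {
  c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
}

# DTI design matrix: rows g_x^2, 2 g_x g_y, 2 g_x g_z, g_y^2, 2 g_y g_z, g_z^2
dti_design <- function(gradients) {
  g <- as.matrix(gradients)
  cbind(g[, 1]^2, 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
        g[, 2]^2, 2 * g[, 2] * g[, 3], g[, 3]^2)
}

#' Log-linear least-squares diffusion tensor fit
#'
#' Solves `log(S_i / S0) = -b * g_i' D g_i` for the six unique elements of
#' the symmetric tensor `D` by ordinary least squares. Negative eigenvalues
#' of the solution are clamped to zero (with a warning), preserving
#' positive semi-definiteness.
#'
#' @param dwi_signals diffusion-weighted signals, one per gradient, > 0.
#' @param gradients matrix of unit gradient directions (rows), >= 6
#'   non-collinear directions.
#' @param b diffusion weighting in s/mm^2.
#' @param s0 non-weighted signal.
#' @return symmetric 3x3 tensor (mm^2/s).
#' @export
fit_tensor_lls <- function(dwi_signals, gradients, b, s0) {
  g <- as.matrix(gradients)
  if (nrow(g) < 6L)
    stop("need at least 6 gradient directions", call. = FALSE)
  if (any(dwi_signals <= 0) || s0 <= 0)
    stop("signals must be positive", call. = FALSE)
  X <- dti_design(g)
  if (qr(X)$rank < 6L)
    stop("rank-deficient gradient design: directions are collinear/coplanar",
         call. = FALSE)
  y <- -log(dwi_signals / s0) / b
  d6 <- qr.solve(X, y)
  D <- tensor6_to_mat(d6)
  e <- eigen(D, symmetric = TRUE)
  if (any(e$values < 0)) {
    warning("negative tensor eigenvalues clamped to 0")
    D <- e$vectors %*% diag(pmax(e$values, 0)) %*% t(e$vectors)
    D <- (D + t(D)) / 2
  }
  D
}

#' Quasi-uniform unit directions on the sphere
#'
#' Deterministic Fibonacci-spiral point set, the usual stand-in for an
#' optimized diffusion gradient table.
#'
#' @param n number of directions.
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
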