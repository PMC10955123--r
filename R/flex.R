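#' Average repeated passive torque-angle trials
#'
#' Resamples each trial's torque onto the common angle support (the
#' intersection of all trials' angle ranges) and averages pointwise. Passive
#' flexibility analysis conventionally averages five stretch trials per
#' direction before model fitting.
#'
#' @param curves list of trials, each a list/data.frame with `angle` and
#'   `torque` (or `angle_deg` / `torque_Nm`) elements.
#' @param n_expected expected number of trials; a differing count only warns.
#' @param n_grid number of nodes of the common angle grid (default: median
#'   trial length).
#' @return list with `angle` and `torque` of the averaged curve.
#' @export
average_passive_trials <- function(curves, n_expected = 5L, n_grid = NULL) {
  if (length(curves) < 2L) stop("need at least 2 trials to average", call. = FALSE)
  if (length(curves) != n_expected)
    warning(sprintf("expected %d trials, got %d", n_expected, length(curves)))
  get2 <- function(cv) {
    ang <- cv$angle %||% cv$angle_deg
    trq <- cv$torque %||% cv$torque_Nm
    if (is.null(ang) || is.null(trq)) stop("each trial needs angle and torque", call. = FALSE)
    o <- order(ang)
    list(angle = ang[o], torque = trq[o])
  }
  cs <- lapply(curves, get2)
  lo <- max(vapply(cs, function(z) min(z$angle), 0))
  hi <- min(vapply(cs, function(z) max(z$angle), 0))
  if (hi <= lo) stop("trials have disjoint angle supports", call. = FALSE)
  n_grid <- n_grid %||% stats::median(vapply(cs, function(z) length(z$angle), 0L))
  grid <- seq(lo, hi, length.out = n_grid)
  mat <- vapply(cs, function(z)
    stats::approx(z$angle, z$torque, xout = grid, ties = mean)$y,
    numeric(n_grid))
  list(angle = grid, torque = rowMeans(mat))
}

#' Fit the three-parameter exponential passive torque-angle model
#'
#' Fits `T(theta) = a * exp(b * theta) + c` by nonlinear least squares. The
#' start values are deterministic: the rate `b` comes from a log-linear
#' regression of the first differences of torque on angle (since
#' `dT/dtheta = a b exp(b theta)` is log-linear in angle), then `a` and `c`
#' from an ordinary linear solve given `b`. The fit is refined with
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]) to a parameter tolerance of
#' 1e-10; non-convergence is flagged, never silent.
#'
#' An alternative shifted form `T(theta) = a * (exp(b * (theta - theta0)) - 1)`
#' is available via `form = "shifted"` for sensitivity analyses.
#'
#' @param angle angles in degrees (>= 10 points spanning >= 20 degrees).
#' @param torque torques in Nm.
#' @param form `"offset"` (default) fits `a*exp(b*theta)+c`; `"shifted"` fits
#'   `a*(exp(b*(theta-theta0))-1)`.
#' @param threshold maximal-ROM torque criterion in Nm used to fill the
#'   derived ROM fields (default 9).
#' @param sub_threshold submaximal torque criterion in Nm (default 4.5).
#' @param angle_cap hard angle limit in degrees (default `Inf`).
#' @return an object of class `passive_fit` with coefficients `a`, `b`, `c`,
#'   `rmse`, convergence and conditioning flags, and derived `rom_max`,
#'   `rom_sub`.
#' @seealso [rom_at_torque()], [rom_submax()]
#' @export
fit_efunction <- function(angle, torque, form = c("offset", "shifted"),
                          threshold = 9, sub_threshold = 4.5, angle_cap = Inf) {
  form <- match.arg(form)
  stopifnot(length(angle) == length(torque))
  if (length(angle) < 10L) stop("need at least 10 points", call. = FALSE)
  if (diff(range(angle)) < 20)
    stop("angle range must span at least 20 degrees", call. = FALSE)
  o <- order(angle)
  th <- angle[o]; trq <- torque[o]

  # deterministic initialization
  dth <- diff(th); dtq <- diff(trq)
  ok <- dth > 0 & dtq > 0
  b0 <- if (sum(ok) >= 3L) {
    mid <- (th[-1] + th[-length(th)]) / 2
    cf <- stats::coef(stats::lm(log(dtq[ok] / dth[ok]) ~ mid[ok]))
    max(as.numeric(cf[2]), 1e-6)
  } else 1e-3
  X <- cbind(exp(b0 * th), 1)
  ac <- tryCatch(as.numeric(qr.solve(X, trq)), error = function(e) c(1, 0))
  start <- list(a = ac[1], b = b0, c = ac[2])

  # raw Levenberg-Marquardt with analytic Jacobian (robust to zero-residual
  # exact data, unlike the nls model wrapper)
  lm_fit <- function(par0, resid_fn, jac_fn) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) list(par = par0, converged = FALSE)
    else list(par = res$par, converged = res$info %in% 1:4)
  }
  if (form == "offset") {
    out <- lm_fit(unlist(start),
                  function(p) p[1] * exp(p[2] * th) + p[3] - trq,
                  function(p) cbind(exp(p[2] * th),
                                    p[1] * th * exp(p[2] * th),
                                    rep(1, length(th))))
    cf <- stats::setNames(out$par, c("a", "b", "c"))
    converged <- out$converged
    fitted_fun <- function(x) cf[["a"]] * exp(cf[["b"]] * x) + cf[["c"]]
  } else {
    out <- lm_fit(c(max(ac[1], 1e-3), b0, th[1]),
                  function(p) p[1] * (exp(p[2] * (th - p[3])) - 1) - trq,
                  function(p) {
                    e <- exp(p[2] * (th - p[3]))
                    cbind(e - 1, p[1] * (th - p[3]) * e, -p[1] * p[2] * e)
                  })
    cf <- stats::setNames(out$par, c("a", "b", "th0"))
    converged <- out$converged
    fitted_fun <- function(x) cf[["a"]] * (exp(cf[["b"]] * (x - cf[["th0"]])) - 1)
  }

  res <- trq - fitted_fun(th)
  rmse <- sqrt(mean(res^2))
  # conditioning: a near-flat exponential makes (a, c) unidentifiable
  ill <- !is.finite(cf[["b"]]) || abs(cf[["b"]]) * diff(range(th)) < 0.05
  obj <- structure(list(coefficients = cf, rmse = rmse, form = form,
                        converged = isTRUE(converged), ill_conditioned = ill,
                        torque_threshold_used = threshold,
                        sub_threshold_used = sub_threshold,
                        angle_cap = angle_cap,
                        data = list(angle = th, torque = trq),
                        fitted_fun = fitted_fun),
                   class = "passive_fit")
  if (form == "offset" && !ill) {
    obj$rom_max <- suppressWarnings(rom_at_torque(obj, threshold, angle_cap))
    obj$rom_sub <- suppressWarnings(rom_submax(obj, sub_threshold, angle_cap))
  } else {
    obj$rom_max <- NA_real_
    obj$rom_sub <- NA_real_
  }
  if (!obj$converged) warning("passive fit did not converge; start values returned")
  if (ill) warning("passive fit is ill-conditioned (near-linear data, b ~ 0)")
  obj
}

#' @export
print.passive_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("<passive_fit> T(theta) = %s\n",
              if (x$form == "offset") "a*exp(b*theta) + c" else "a*(exp(b*(theta-theta0)) - 1)"))
  print(round(cf, 6))
  cat(sprintf("  rmse %0.4f Nm | converged: %s%s\n", x$rmse, x$converged,
              if (x$ill_conditioned) " | ILL-CONDITIONED" else ""))
  if (is.finite(x$rom_max %||% NA))
    cat(sprintf("  ROM @ %g Nm: %0.2f deg | ROM @ %g Nm: %0.2f deg\n",
                x$torque_threshold_used, x$rom_max,
                x$sub_threshold_used, x$rom_sub))
  invisible(x)
}

#' @export
coef.passive_fit <- function(object, ...) object$coefficients

#' @export
predict.passive_fit <- function(object, newdata = NULL, ...) {
  ang <- if (is.null(newdata)) object$data$angle
         else (newdata$angle %||% newdata)
  object$fitted_fun(ang)
}

#' @export
residuals.passive_fit <- function(object, ...) {
  object$data$torque - object$fitted_fun(object$data$angle)
}

#' @export
plot.passive_fit <- function(x, ...) {
  plot(x$data$angle, x$data$torque, xlab = "angle [deg]",
       ylab = "passive torque [Nm]", ...)
  grid_x <- seq(min(x$data$angle), max(x$data$angle), length.out = 200)
  graphics::lines(grid_x, x$fitted_fun(grid_x), col = 2, lwd = 2)
  invisible(x)
}

#' Invert the passive fit at a torque threshold
#'
#' Returns the angle at which the fitted passive torque reaches `threshold`,
#' capped at `angle_cap` -- the maximal passive ROM under a "9 Nm or hard
#' angle limit, whichever first" stopping rule.
#'
#' @param fit a `passive_fit` (offset form) or numeric `c(a, b, c)`.
#' @param threshold torque criterion in Nm (default 9).
#' @param angle_cap hard angle limit in degrees (default `Inf`, i.e. no cap).
#' @return ROM in degrees.
#' @examples
#' rom_at_torque(c(0.5, 0.05, 0), 9, 140)  # log(18)/0.05 = 57.81
#' @export
rom_at_torque <- function(fit, threshold = 9, angle_cap = Inf) {
  cf <- if (inherits(fit, "passive_fit")) fit$coefficients else fit
  a <- cf[[1]]; b <- cf[[2]]; cc <- cf[[3]]
  stop_if_not_scalar_num(threshold, "threshold")
  if (threshold <= cc || a <= 0 || b <= 0) {
    warning("torque asymptote below threshold (or non-increasing fit); returning angle cap")
    return(angle_cap)
  }
  min(log((threshold - cc) / a) / b, angle_cap)
}

#' Submaximal ROM at a configurable torque criterion
#'
#' Same inversion as [rom_at_torque()] at a submaximal threshold (default
#' 4.5 Nm, half the maximal 9 Nm criterion).
#'
#' @inheritParams rom_at_torque
#' @param sub_threshold submaximal torque criterion in Nm.
#' @export
rom_submax <- function(fit, sub_threshold = 4.5, angle_cap = Inf) {
  rom_at_torque(fit, threshold = sub_threshold, angle_cap = angle_cap)
}

#' Active range of motion from an alternating movement trial
#'
#' Detects direction reversals of the angle trace and averages, over cycles,
#' the extreme angle reached in the tested direction.
#'
#' @param trial a `dyn_trial` of an active ROM test with at least two
#'   direction reversals.
#' @param direction `"external"` (angle maxima) or `"internal"` (angle
#'   minima, reported as the unsigned internal-rotation excursion).
#' @return mean extreme angle in degrees.
#' @export
active_rom <- function(trial, direction = c("external", "internal")) {
  direction <- match.arg(direction)
  ang <- trial$angle_deg
  s <- sign(diff(ang))
  nz <- which(s != 0)
  sn <- s[nz]
  ch <- which(diff(sn) != 0)
  if (length(ch) < 2L)
    stop("need at least 2 direction reversals for active ROM", call. = FALSE)
  ext <- ang[nz[ch] + 1L]  # angle at each reversal
  mid <- mean(range(ang))
  vals <- if (direction == "external") ext[ext > mid] else ext[ext < mid]
  if (length(vals) == 0L)
    stop("no extremes found in the tested direction", call. = FALSE)
  mean(vals)
}
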