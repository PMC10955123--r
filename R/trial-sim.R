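#' Specification of a simulated dynamometer trial
#'
#' Bundles the protocol parameters of one isokinetic test: contraction mode,
#' movement direction, commanded speed, range of motion and the acquisition
#' settings of the device (200 Hz sampling by default, matching common
#' isokinetic dynamometers).
#'
#' @param mode one of `"concentric"`, `"eccentric"`, `"passive"`.
#' @param direction tested rotation direction, `"internal"` or `"external"`.
#' @param target_speed commanded isokinetic speed in degrees/s (typically 30
#'   or 60 for strength tests, 10 for passive ROM tests).
#' @param rom_start,rom_end range of motion limits in degrees; angle 0 is the
#'   neutral position with the lever arm perpendicular to the body, positive
#'   angles toward external rotation.
#' @param sampling_rate recording frequency in Hz.
#' @param accel_time time in s to ramp from rest to `target_speed`.
#' @param noise_sd_torque standard deviation of additive Gaussian torque
#'   noise, in Nm.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an object of class `trial_spec`.
#' @export
trial_spec <- function(mode = c("eccentric", "concentric", "passive"),
                       direction = c("external", "internal"),
                       target_speed = 30,
                       rom_start = -60, rom_end = 90,
                       sampling_rate = 200,
                       accel_time = 0.25,
                       noise_sd_torque = 0.5,
                       seed = NULL) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  stop_if_not_scalar_num(target_speed, "target_speed", positive = TRUE)
  stop_if_not_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  stop_if_not_scalar_num(accel_time, "accel_time")
  if (rom_end - rom_start <= 0)
    stop("rom_end must exceed rom_start", call. = FALSE)
  if (noise_sd_torque < 0) stop("noise_sd_torque must be >= 0", call. = FALSE)
  structure(list(mode = mode, direction = direction,
                 target_speed = target_speed,
                 rom_start = rom_start, rom_end = rom_end,
                 sampling_rate = sampling_rate, accel_time = accel_time,
                 noise_sd_torque = noise_sd_torque, seed = seed),
            class = "trial_spec")
}

new_dyn_trial <- function(time, angle, torque, velocity, meta, ground_truth = NULL) {
  stopifnot(length(time) == length(angle),
            length(angle) == length(torque),
            length(torque) == length(velocity))
  structure(list(time_s = time, angle_deg = angle, torque_Nm = torque,
                 velocity_dps = velocity, meta = meta,
                 ground_truth = ground_truth),
            class = "dyn_trial")
}

#' @export
print.dyn_trial <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<dyn_trial> %s %s, %g deg/s, %d samples @ %g Hz\n",
              m$mode %||% "?", m$direction %||% "?",
              m$target_speed %||% NA, length(x$time_s),
              m$sampling_rate %||% NA))
  cat(sprintf("  angle [%0.1f, %0.1f] deg, torque [%0.2f, %0.2f] Nm\n",
              min(x$angle_deg), max(x$angle_deg),
              min(x$torque_Nm), max(x$torque_Nm)))
  invisible(x)
}

# trapezoidal velocity profile of one repetition (unsigned)
trapezoid_velocity <- function(spec) {
  v <- spec$target_speed
  ta <- spec$accel_time
  rom <- spec$rom_end - spec$rom_start
  plateau_time <- (rom - v * ta) / v
  if (plateau_time <= 0)
    stop("no isokinetic plateau: accel_time too long for this ROM and speed",
         call. = FALSE)
  dt <- 1 / spec$sampling_rate
  t_total <- 2 * ta + plateau_time
  tt <- seq(0, t_total, by = dt)
  vel <- ifelse(tt < ta, v * tt / ta,
         ifelse(tt < ta + plateau_time, v,
                pmax(0, v * (t_total - tt) / ta)))
  plateau <- which(tt >= ta & tt <= ta + plateau_time)
  list(t = tt, vel = vel, plateau = range(plateau))
}

#' Simulate an isokinetic strength trial
#'
#' Generates a maximal-contraction dynamometer trial: the lever follows a
#' trapezoidal velocity profile per repetition (ramp up over `accel_time`,
#' constant plateau at the commanded speed, ramp down), repetitions alternate
#' movement direction, and torque is a smooth unimodal (Gaussian-bell)
#' function of joint angle peaking at `optimum_angle`, scaled to
#' `peak_torque`, plus additive Gaussian noise. Ground-truth plateau sample
#' ranges per repetition are attached, so downstream isokinetic-phase
#' extraction can be validated exactly.
#'
#' @param spec a [trial_spec()].
#' @param peak_torque maximal torque of the underlying torque-angle bell, Nm.
#' @param optimum_angle angle of peak torque, degrees.
#' @param n_reps number of repetitions (each an out-and-back pair counts as
#'   two directional movements; `n_reps` counts full out-and-back cycles).
#' @param bell_width standard deviation of the torque-angle bell, degrees.
#' @param body_mass subject body mass in kg, carried in the metadata.
#' @param subject subject identifier carried in the metadata.
#' @return a `dyn_trial`; `$ground_truth$plateau` holds one `c(start, end)`
#'   sample range (1-based, inclusive) per directional movement.
#' @examples
#' tr <- simulate_active_trial(trial_spec(seed = 1), peak_torque = 40,
#'                             optimum_angle = 20, n_reps = 3)
#' @export
simulate_active_trial <- function(spec, peak_torque, optimum_angle,
                                  n_reps = 3L, bell_width = 40,
                                  body_mass = 80, subject = "S01") {
  stopifnot(inherits(spec, "trial_spec"))
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  stop_if_not_scalar_num(peak_torque, "peak_torque", positive = TRUE)
  prof <- trapezoid_velocity(spec)
  n_half <- length(prof$t)
  n_moves <- 2L * n_reps
  dt <- 1 / spec$sampling_rate

  vel <- numeric(0)
  plateaus <- vector("list", n_moves)
  for (k in seq_len(n_moves)) {
    s <- if (k %% 2L == 1L) 1 else -1   # odd moves go rom_start -> rom_end
    offset <- length(vel)
    vel <- c(vel, s * prof$vel)
    plateaus[[k]] <- offset + prof$plateau
  }
  angle <- spec$rom_start + cumsum(vel) * dt
  tt <- seq_along(vel) * dt - dt

  torque <- with_seed(spec$seed, {
    peak_torque * exp(-(angle - optimum_angle)^2 / (2 * bell_width^2)) +
      if (spec$noise_sd_torque > 0) stats::rnorm(length(angle), 0, spec$noise_sd_torque) else 0
  })

  meta <- list(subject = subject, body_mass = body_mass, mode = spec$mode,
               direction = spec$direction, target_speed = spec$target_speed,
               sampling_rate = spec$sampling_rate)
  new_dyn_trial(tt, angle, torque, vel, meta,
                ground_truth = list(plateau = plateaus,
                                    peak_torque = peak_torque,
                                    optimum_angle = optimum_angle,
                                    bell_width = bell_width))
}

#' Simulate a passive range-of-motion trial
#'
#' The device stretches the relaxed joint at constant slow speed (10 deg/s by
#' convention) while passive torque grows exponentially with angle,
#' `T(theta) = a * exp(b * theta) + c`. The motion reverses when the
#' (noise-free) torque reaches `torque_limit` (the 9 Nm comfort criterion) or
#' the angle cap, whichever comes first, then returns to the start angle;
#' `n_cycles` such stretch-return cycles are produced. Ground-truth reversal
#' angles are attached.
#'
#' @param spec a [trial_spec()] with `mode = "passive"`.
#' @param stiffness_params numeric `c(a, b, c)` of the exponential model
#'   (Nm, 1/degree, Nm).
#' @param n_cycles number of stretch cycles (a study protocol typically uses
#'   ten, five per rotation direction).
#' @param torque_limit reversal torque threshold in Nm (default 9).
#' @param angle_cap optional hard angle limit in degrees (e.g. 100 internal /
#'   140 external); `NULL` means no cap.
#' @inheritParams simulate_active_trial
#' @return a `dyn_trial`; `$ground_truth$reversal_angle` is the noise-free
#'   reversal angle, `$ground_truth$cycle_bounds` the sample range of each
#'   stretch-return cycle.
#' @examples
#' sp <- trial_spec(mode = "passive", target_speed = 10, rom_start = 0,
#'                  rom_end = 140, seed = 2)
#' tr <- simulate_passive_trial(sp, c(0.5, 0.05, 0), n_cycles = 10)
#' @export
simulate_passive_trial <- function(spec, stiffness_params, n_cycles = 10L,
                                   torque_limit = 9, angle_cap = NULL,
                                   body_mass = 80, subject = "S01") {
  stopifnot(inherits(spec, "trial_spec"))
  if (spec$mode != "passive")
    stop("simulate_passive_trial requires a spec with mode = 'passive'", call. = FALSE)
  if (length(stiffness_params) != 3L)
    stop("stiffness_params must be c(a, b, c)", call. = FALSE)
  a <- stiffness_params[1]; b <- stiffness_params[2]; cc <- stiffness_params[3]

  # noise-free reversal angle
  reach <- a > 0 && b > 0 && (torque_limit - cc) / a > 0
  theta_torque <- if (reach) log((torque_limit - cc) / a) / b else Inf
  theta_rev <- min(theta_torque, angle_cap %||% Inf)
  if (!is.finite(theta_rev))
    stop("passive torque never reaches the reversal threshold and no angle cap is set",
         call. = FALSE)
  if (theta_rev <= spec$rom_start)
    stop("reversal angle does not exceed rom_start", call. = FALSE)

  v <- spec$target_speed
  dt <- 1 / spec$sampling_rate
  n_up <- max(2L, ceiling((theta_rev - spec$rom_start) / (v * dt)))
  up <- spec$rom_start + seq_len(n_up) * v * dt
  up <- pmin(up, theta_rev)
  down <- rev(up)[-1]
  cyc_angle <- c(up, down)
  cyc_vel <- c(rep(v, length(up)), rep(-v, length(down)))

  angle <- rep(cyc_angle, n_cycles)
  vel <- rep(cyc_vel, n_cycles)
  tt <- seq_along(angle) * dt - dt
  torque <- with_seed(spec$seed, {
    a * exp(b * angle) + cc +
      if (spec$noise_sd_torque > 0) stats::rnorm(length(angle), 0, spec$noise_sd_torque) else 0
  })
  cyc_len <- length(cyc_angle)
  bounds <- lapply(seq_len(n_cycles) - 1L,
                   function(k) c(k * cyc_len + 1L, (k + 1L) * cyc_len))

  meta <- list(subject = subject, body_mass = body_mass, mode = "passive",
               direction = spec$direction, target_speed = v,
               sampling_rate = spec$sampling_rate)
  new_dyn_trial(tt, angle, torque, vel, meta,
                ground_truth = list(reversal_angle = theta_rev,
                                    stiffness_params = c(a = a, b = b, c = cc),
                                    cycle_bounds = bounds))
}

#' Write / read a dynamometer trial as CSV
#'
#' Plain-text interchange format with the header
#' `time_s,angle_deg,torque_Nm,velocity_dps`. Metadata travel in `#`-prefixed
#' key-value comment lines before the header.
#'
#' @param trial a `dyn_trial`.
#' @param path file path.
#' @return `read_trial_csv` returns a `dyn_trial`.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "dyn_trial"))
  meta <- trial$meta
  hdr <- vapply(names(meta), function(k) sprintf("# %s=%s", k, meta[[k]]), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(time_s = trial$time_s, angle_deg = trial$angle_deg,
                              torque_Nm = trial$torque_Nm,
                              velocity_dps = trial$velocity_dps),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) {
      val <- suppressWarnings(as.numeric(kv[2]))
      meta[[kv[1]]] <- if (is.na(val)) kv[2] else val
    }
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  new_dyn_trial(df$time_s, df$angle_deg, df$torque_Nm, df$velocity_dps, meta)
}
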