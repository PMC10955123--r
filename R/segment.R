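#' Cut a dynamometer trial into directional repetition segments
#'
#' Splits a (filtered) trial at zero-crossings of the velocity signal into
#' maximal runs of constant movement direction. Runs shorter than
#' `min_duration` are treated as chatter and dropped. By the angle
#' convention (positive angles toward external rotation) positive velocity
#' labels a segment `"external"`, negative `"internal"`.
#'
#' @param trial a `dyn_trial`.
#' @param min_duration minimum segment duration in seconds (default 0.1).
#' @return list of `rep_segment` objects, each with elements `start`, `end`
#'   (1-based inclusive sample indices), `direction` and `trial`.
#' @export
segment_repetitions <- function(trial, min_duration = 0.1) {
  stopifnot(inherits(trial, "dyn_trial"))
  v <- trial$velocity_dps
  fs <- trial$meta$sampling_rate %||% (1 / stats::median(diff(trial$time_s)))
  sgn <- sign(v)
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0 & r$lengths >= max(1L, round(min_duration * fs))
  if (!any(keep)) {
    warning("no velocity zero-crossings found; returning the whole trial as one segment")
    return(list(new_rep_segment(1L, length(v),
                                if (mean(v) >= 0) "external" else "internal", trial)))
  }
  segs <- lapply(which(keep), function(i) {
    new_rep_segment(starts[i], ends[i],
                    if (r$values[i] > 0) "external" else "internal", trial)
  })
  if (length(segs) == 1L && sum(keep) == 1L && all(sgn[sgn != 0] == sgn[sgn != 0][1]))
    warning("trial contains a single movement direction (no zero-crossings)")
  segs
}

new_rep_segment <- function(start, end, direction, trial) {
  stopifnot(end >= start)
  structure(list(start = as.integer(start), end = as.integer(end),
                 direction = direction, trial = trial),
            class = "rep_segment")
}

#' @export
print.rep_segment <- function(x, ...) {
  cat(sprintf("<rep_segment> %s, samples %d..%d (%d)\n",
              x$direction, x$start, x$end, x$end - x$start + 1L))
  invisible(x)
}

#' Extract the isokinetic phase of a repetition
#'
#' Keeps the longest contiguous run of samples whose absolute velocity lies
#' within a tolerance band around the commanded speed, thereby excluding the
#' acceleration and deceleration phases of the repetition.
#'
#' @param seg a `rep_segment` from [segment_repetitions()].
#' @param target_speed commanded speed in degrees/s; defaults to the parent
#'   trial's metadata.
#' @param tol_fraction half-width of the velocity acceptance band as a
#'   fraction of `target_speed` (default 0.10).
#' @return an `isokin_phase`: sample range within the parent trial, achieved
#'   mean speed, and the angle/torque series of the phase.
#' @export
extract_isokinetic_phase <- function(seg, target_speed = NULL, tol_fraction = 0.10) {
  stopifnot(inherits(seg, "rep_segment"))
  target_speed <- target_speed %||% seg$trial$meta$target_speed
  stop_if_not_scalar_num(target_speed, "target_speed", positive = TRUE)
  idx <- seg$start:seg$end
  v <- abs(seg$trial$velocity_dps[idx])
  inband <- v >= (1 - tol_fraction) * target_speed &
            v <= (1 + tol_fraction) * target_speed
  run <- longest_true_run(inband)
  if (is.null(run))
    stop("no isokinetic phase: no sample within the velocity tolerance band", call. = FALSE)
  start <- idx[run[1]]
  end <- idx[run[2]]
  phase_idx <- start:end
  structure(list(start = start, end = end,
                 achieved_speed = mean(abs(seg$trial$velocity_dps[phase_idx])),
                 direction = seg$direction,
                 angle_deg = seg$trial$angle_deg[phase_idx],
                 torque_Nm = seg$trial$torque_Nm[phase_idx],
                 trial = seg$trial),
            class = "isokin_phase")
}

#' @export
print.isokin_phase <- function(x, ...) {
  cat(sprintf("<isokin_phase> %s, samples %d..%d, mean speed %0.2f deg/s\n",
              x$direction, x$start, x$end, x$achieved_speed))
  invisible(x)
}

#' Normalize torque to body mass
#'
#' @param torque numeric torque in Nm.
#' @param body_mass body mass in kg, must be positive.
#' @return torque in Nm/kg.
#' @examples
#' normalize_to_body_mass(45.63, 89.2)  # 0.5116 Nm/kg
#' @export
normalize_to_body_mass <- function(torque, body_mass) {
  stop_if_not_scalar_num(body_mass, "body_mass")
  if (body_mass <= 0) stop("body_mass must be > 0", call. = FALSE)
  torque / body_mass
}

#' Interpolate an isokinetic phase onto a fixed percent-ROM grid
#'
#' Resamples torque linearly in angle onto `n_nodes` equally spaced angles
#' between the phase's angle extremes (0-100% of the isokinetic ROM), the
#' standard preprocessing for one-dimensional statistical parametric mapping.
#' Duplicate angles are averaged before interpolation; endpoints are
#' preserved exactly.
#'
#' @param phase an `isokin_phase`, or a list with `angle_deg` and `torque_Nm`.
#' @param n_nodes number of grid nodes (default 101).
#' @param body_mass if given, torque is normalized to Nm/kg.
#' @param metadata named list stored on the curve (subject, group, time, ...).
#' @return a `torque_curve`: list with `torque` (length `n_nodes`),
#'   `angle_start`, `angle_end`, `metadata`.
#' @export
to_normalized_curve <- function(phase, n_nodes = 101L, body_mass = NULL,
                                metadata = list()) {
  ang <- phase$angle_deg
  trq <- phase$torque_Nm
  if (length(ang) < 2L) stop("phase must span at least 2 samples", call. = FALSE)
  o <- order(ang)
  ang <- ang[o]; trq <- trq[o]
  if (anyDuplicated(ang)) {
    trq <- tapply(trq, ang, mean)
    ang <- as.numeric(names(trq))
    trq <- as.numeric(trq)
  }
  if (length(ang) < 2L || diff(range(ang)) <= 0)
    stop("degenerate angle span: cannot interpolate", call. = FALSE)
  grid <- seq(ang[1L], ang[length(ang)], length.out = n_nodes)
  out <- stats::approx(ang, trq, xout = grid, ties = "ordered")$y
  out[1L] <- trq[1L]
  out[n_nodes] <- trq[length(trq)]
  if (!is.null(body_mass)) out <- normalize_to_body_mass(out, body_mass)
  structure(list(torque = out, angle_start = ang[1L], angle_end = ang[length(ang)],
                 metadata = metadata),
            class = "torque_curve")
}
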