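#' Peak and mean torque of an isokinetic phase
#'
#' @param phase an `isokin_phase`, or any list with a `torque_Nm` element.
#' @return named numeric `c(peak, mean)` in Nm.
#' @export
torque_summary <- function(phase) {
  trq <- phase$torque_Nm
  if (is.null(trq) || length(trq) == 0L)
    stop("empty isokinetic phase", call. = FALSE)
  c(peak = max(trq), mean = mean(trq))
}

#' Per-subject strength summary over repetitions
#'
#' Aggregates repetition-level torque summaries into the subject-level value:
#' by default the best repetition's peak and the mean of the repetitions'
#' mean torques. Both rules are configurable since testing conventions vary.
#'
#' @param phases list of `isokin_phase` objects (the subject's repetitions).
#' @param peak_rule `"max"` (best repetition) or `"mean"` across repetitions.
#' @param mean_rule `"mean"` across repetitions or `"max"`.
#' @param body_mass if given, also returns Nm/kg values.
#' @return named numeric with `peak_Nm`, `mean_Nm` and, when `body_mass` is
#'   supplied, `peak_Nm_kg`, `mean_Nm_kg`.
#' @export
subject_strength <- function(phases, peak_rule = c("max", "mean"),
                             mean_rule = c("mean", "max"), body_mass = NULL) {
  peak_rule <- match.arg(peak_rule)
  mean_rule <- match.arg(mean_rule)
  if (length(phases) == 0L) stop("no repetitions supplied", call. = FALSE)
  summ <- vapply(phases, torque_summary, numeric(2))
  peak <- if (peak_rule == "max") max(summ["peak", ]) else mean(summ["peak", ])
  mn <- if (mean_rule == "mean") mean(summ["mean", ]) else max(summ["mean", ])
  out <- c(peak_Nm = peak, mean_Nm = mn)
  if (!is.null(body_mass))
    out <- c(out, peak_Nm_kg = normalize_to_body_mass(peak, body_mass),
             mean_Nm_kg = normalize_to_body_mass(mn, body_mass))
  out
}

#' Percent change between pre and post values
#'
#' `100 * (post - pre) / pre`, rounded to two decimals as conventionally
#' reported in pre/post training tables.
#'
#' @param pre,post numeric values (vectors recycle).
#' @return percent change, 2 decimals.
#' @examples
#' percent_change(39.56, 45.63)  # 15.34
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) stop("pre value must be non-zero", call. = FALSE)
  round(100 * (post - pre) / pre, 2)
}
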