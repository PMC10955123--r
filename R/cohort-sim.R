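#' Specification of a simulated two-arm pre/post cohort
#'
#' Describes a randomized-controlled cohort with an intervention and a
#' control arm, each subject measured pre and post on a set of named
#' parameters. Intervention post-test means are shifted by a configurable
#' percent effect; control post-test means are unshifted. Variability is
#' a subject-level random intercept plus occasion noise.
#'
#' @param n_intervention,n_control group sizes (each >= 2).
#' @param baseline named numeric vector of pre-test means, one per parameter.
#' @param effect_pct named numeric vector of percent changes applied to the
#'   intervention group's post-test mean; parameters not named get 0.
#' @param between_subject_sd sd of the subject random intercept (same units
#'   as the parameter; recycled across parameters or named vector).
#' @param within_subject_sd sd of the occasion (measurement) noise.
#' @param body_mass_mean,body_mass_sd body-mass distribution in kg.
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_intervention = 14L, n_control = 12L,
                        baseline = c(ecc_peak_30 = 39.56),
                        effect_pct = c(ecc_peak_30 = 15),
                        between_subject_sd = 8,
                        within_subject_sd = 3,
                        body_mass_mean = 84.8, body_mass_sd = 11.3,
                        seed = NULL) {
  if (n_intervention < 2L || n_control < 2L)
    stop("group sizes must be >= 2", call. = FALSE)
  if (is.null(names(baseline)) || any(!nzchar(names(baseline))))
    stop("baseline must be a named numeric vector", call. = FALSE)
  if (any(between_subject_sd < 0) || any(within_subject_sd < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  eff <- stats::setNames(rep(0, length(baseline)), names(baseline))
  if (length(effect_pct)) eff[names(effect_pct)] <- effect_pct
  structure(list(n_intervention = as.integer(n_intervention),
                 n_control = as.integer(n_control),
                 baseline = baseline, effect_pct = eff,
                 between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 body_mass_mean = body_mass_mean, body_mass_sd = body_mass_sd,
                 seed = seed),
            class = "cohort_spec")
}

#' Simulate a pre/post cohort table
#'
#' Generates one row per subject and parameter with columns `subject`,
#' `group`, `body_mass`, `parameter`, `pre`, `post`. The generative model per
#' subject i and parameter k is
#' `pre = mu_k + u_ik + e`, `post = mu_k * (1 + delta_k/100 * 1[intervention]) + u_ik + e'`,
#' with `u_ik ~ N(0, between_subject_sd^2)` and `e ~ N(0, within_subject_sd^2)`.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` (class `cohort_table`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  params <- names(spec$baseline)
  n_tot <- spec$n_intervention + spec$n_control
  group <- rep(c("intervention", "control"),
               c(spec$n_intervention, spec$n_control))
  sdb <- rep_len(spec$between_subject_sd, length(params))
  sdw <- rep_len(spec$within_subject_sd, length(params))
  with_seed(spec$seed, {
    body_mass <- stats::rnorm(n_tot, spec$body_mass_mean, spec$body_mass_sd)
    rows <- lapply(seq_along(params), function(k) {
      mu <- spec$baseline[[k]]
      delta <- spec$effect_pct[[params[k]]]
      u <- stats::rnorm(n_tot, 0, sdb[k])
      pre <- mu + u + stats::rnorm(n_tot, 0, sdw[k])
      post_mu <- mu * (1 + ifelse(group == "intervention", delta / 100, 0))
      post <- post_mu + u + stats::rnorm(n_tot, 0, sdw[k])
      data.frame(subject = sprintf("S%03d", seq_len(n_tot)),
                 group = group, body_mass = body_mass,
                 parameter = params[k], pre = pre, post = post)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Write / read a cohort table as TSV
#' @param table a `cohort_table` data frame.
#' @param path file path.
#' @export
write_cohort_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
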