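#' Default pipeline configuration
#'
#' All stage parameters with their package-wide defaults: filter settings,
#' velocity tolerance, SPM grid size and alpha, test sidedness policy,
#' tracking criteria and generator settings. The configuration round-trips
#' losslessly through YAML via [write_config()] / [read_config()].
#'
#' @return nested named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    filter = list(cutoff = 6, order = 5L),
    segmentation = list(min_duration = 0.1),
    isokin = list(tol_fraction = 0.10, n_nodes = 101L),
    strength = list(peak_rule = "max", mean_rule = "mean"),
    flex = list(threshold = 9, sub_threshold = 4.5,
                cap_internal = 100, cap_external = 140),
    spm = list(alpha = 0.05),
    stats = list(zscore_cutoff = 2.5,
                 sided_intervention = "one", sided_control = "two"),
    tract = list(step = 1, fa_min = 0.05, fa_max = 0.6, angle_max = 30,
                 length_min = 10, length_max = 200),
    synth = list(n_intervention = 14L, n_control = 11L,
                 effect_pct = 15, optimum_shift_deg = 15,
                 peak_torque_mean = 39.56, peak_torque_sd = 9.32,
                 noise_sd_torque = 0.5, n_reps = 3L,
                 fascicle_length_true = 40, fa_target = 0.3)
  ), class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a `pipeline_config` list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Exercises every stage end to end on generated data: per-subject
#' isokinetic trials are simulated pre and post (with the configured
#' training effect in the intervention arm only), filtered, segmented,
#' reduced to isokinetic phases, normalized 101-node curves and strength
#' summaries; the curve set is analysed by 1D SPM; the strength cohort by
#' mixed ANOVA, paired tests and effect sizes; a DTI phantom is tracked and
#' its fascicle metrics recovered. All artifacts and a manifest (seeds,
#' parameters) are written to `output_dir`.
#'
#' @param config a [default_config()]-style list.
#' @param output_dir directory for outputs (created if missing).
#' @return invisible list with `curves`, `cohort`, `spm`, `stats`, `tract`,
#'   `report` and `manifest`.
#' @export
run_pipeline <- function(config = default_config(), output_dir = tempfile("pipeline")) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  sy <- config$synth
  n_tot <- sy$n_intervention + sy$n_control
  group <- rep(c("intervention", "control"), c(sy$n_intervention, sy$n_control))
  subj <- sprintf("S%03d", seq_len(n_tot))

  subject_params <- with_seed(derive_seed(config$seed, 1L), {
    data.frame(subject = subj, group = group,
               body_mass = stats::rnorm(n_tot, 84.8, 11.3),
               peak_torque = stats::rnorm(n_tot, sy$peak_torque_mean, sy$peak_torque_sd),
               optimum = stats::rnorm(n_tot, 20, 5))
  })

  curves_mat <- NULL
  meta_rows <- list()
  strength_rows <- list()
  for (i in seq_len(n_tot)) {
    for (tm in c("pre", "post")) {
      eff <- tm == "post" && group[i] == "intervention"
      pk <- subject_params$peak_torque[i] * (1 + if (eff) sy$effect_pct / 100 else 0)
      opt <- subject_params$optimum[i] + if (eff) sy$optimum_shift_deg else 0
      sp <- trial_spec(mode = "eccentric", direction = "external",
                       target_speed = 30, rom_start = -60, rom_end = 90,
                       noise_sd_torque = sy$noise_sd_torque,
                       seed = derive_seed(config$seed, 100L + 2L * i + (tm == "post")))
      tr <- simulate_active_trial(sp, pk, opt, n_reps = sy$n_reps,
                                  body_mass = subject_params$body_mass[i],
                                  subject = subj[i])
      tr$torque_Nm <- filter_zero_lag(tr$torque_Nm, sp$sampling_rate,
                                      config$filter$cutoff, config$filter$order)
      segs <- segment_repetitions(tr, config$segmentation$min_duration)
      segs <- Filter(function(s) s$direction == "external", segs)
      phases <- lapply(segs, extract_isokinetic_phase,
                       tol_fraction = config$isokin$tol_fraction)
      strength_rows[[length(strength_rows) + 1L]] <- data.frame(
        subject = subj[i], group = group[i], time = tm,
        t(subject_strength(phases, config$strength$peak_rule,
                           config$strength$mean_rule,
                           body_mass = subject_params$body_mass[i])))
      crv <- to_normalized_curve(phases[[1L]], config$isokin$n_nodes,
                                 body_mass = subject_params$body_mass[i])
      curves_mat <- rbind(curves_mat, crv$torque)
      meta_rows[[length(meta_rows) + 1L]] <-
        data.frame(subject = subj[i], group = group[i], time = tm)
    }
  }
  meta <- do.call(rbind, meta_rows)
  cs <- curve_set(curves_mat, meta$subject, meta$time, meta$group)
  strength_df <- do.call(rbind, strength_rows)

  spm_res <- anova_field(cs, "group_by_time", alpha = config$spm$alpha)

  wide <- stats::reshape(strength_df[, c("subject", "group", "time", "peak_Nm")],
                         idvar = c("subject", "group"), timevar = "time",
                         direction = "wide")
  cohort <- data.frame(subject = wide$subject, group = wide$group,
                       parameter = "ecc_peak_30",
                       pre = wide$peak_Nm.pre, post = wide$peak_Nm.post)
  class(cohort) <- c("cohort_table", "data.frame")
  aov_res <- mixed_anova_2x2(cohort, "ecc_peak_30")
  iv <- cohort[cohort$group == "intervention", ]
  ct <- cohort[cohort$group == "control", ]
  stats_res <- list(
    anova = aov_res,
    t_intervention = paired_t(iv$pre, iv$post,
                              sided = if (config$stats$sided_intervention == "one")
                                "one" else "two"),
    t_control = paired_t(ct$pre, ct$post, sided = "two"))

  ph <- simulate_phantom(phantom_spec(
    fascicle_length_true = sy$fascicle_length_true, fa_target = sy$fa_target,
    seed = derive_seed(config$seed, 3L)))
  sls <- track_volume(ph$volume, step = config$tract$step,
                      fa_min = config$tract$fa_min, fa_max = config$tract$fa_max,
                      angle_max = config$tract$angle_max,
                      length_range = c(config$tract$length_min,
                                       config$tract$length_max),
                      max_seeds = 60L)
  tract_res <- tract_statistics(sls, ph$volume)

  report <- make_report(cohort, stats_res, spm_res)

  write_curves_tsv(cs, file.path(output_dir, "curves.tsv"))
  write_cohort_tsv(cohort, file.path(output_dir, "cohort.tsv"))
  utils::write.table(report, file.path(output_dir, "report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("eccshoulder")),
    seed = config$seed, config = unclass(config),
    n_subjects = n_tot, n_curves = nrow(curves_mat),
    tract = tract_res,
    spm_fwhm = spm_res$fwhm,
    interaction_F_max = max(spm_res$effects$interaction$F))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10)

  invisible(list(curves = cs, cohort = cohort, spm = spm_res,
                 stats = stats_res, tract = tract_res, report = report,
                 manifest = manifest, output_dir = output_dir))
}

#' Render a pre/post comparison table
#'
#' Formats per-group rows in the conventional layout of pre/post training
#' tables: mean +- sd at both occasions, percent change, within-group p,
#' Cohen's d, and the between-group interaction ("Dif") p value. Torque and
#' ROM values print with two decimals, p and d with three.
#'
#' @param cohort a cohort table.
#' @param stats_res list with `anova` and per-group paired-test entries as
#'   produced by [run_pipeline()]; may be `NULL` to format descriptives only.
#' @param spm_res optional `spm_anova` whose cluster summary is attached as
#'   an attribute `"spm"`.
#' @return data frame, one row per parameter and group.
#' @export
make_report <- function(cohort, stats_res = NULL, spm_res = NULL) {
  if (nrow(cohort) == 0L) {
    return(data.frame(parameter = character(), group = character(),
                      pre = character(), post = character(),
                      delta_pct = numeric(), p = numeric(), d = numeric(),
                      dif_p = numeric()))
  }
  fmt2 <- function(m, s) sprintf("%0.2f ± %0.2f", m, s)
  rows <- list()
  for (par in unique(cohort$parameter)) {
    d <- cohort[cohort$parameter == par, ]
    for (g in unique(d$group)) {
      dg <- d[d$group == g, ]
      tt <- if (!is.null(stats_res)) {
        key <- paste0("t_", g)
        if (!is.null(stats_res[[key]])) stats_res[[key]]
        else list(p = NA_real_, d = NA_real_)
      } else list(p = NA_real_, d = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, group = g,
        pre = fmt2(mean(dg$pre), stats::sd(dg$pre)),
        post = fmt2(mean(dg$post), stats::sd(dg$post)),
        delta_pct = percent_change(mean(dg$pre), mean(dg$post)),
        p = round(tt$p, 3), d = round(tt$d, 3),
        dif_p = if (!is.null(stats_res))
          round(stats_res$anova$interaction$p, 3) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(spm_res)) {
    cl <- spm_res$effects$interaction$clusters
    attr(out, "spm") <- sprintf(
      "interaction: %d suprathreshold cluster(s)%s", length(cl),
      if (length(cl)) paste0(" at nodes ", paste(vapply(
        cl, function(x) sprintf("%d-%d", x$start, x$end), ""), collapse = ", "))
      else "")
  }
  out
}
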