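#' Assemble torque curves into a design-labelled curve set
#'
#' Container for one-dimensional SPM: an `n x Q` matrix of curves on a
#' common grid with per-row design labels. The design must be balanced
#' within subject (every subject observed pre and post).
#'
#' @param curves numeric matrix, one row per observation, `Q` columns
#'   (typically 101 percent-ROM nodes).
#' @param subject subject identifier per row.
#' @param time `"pre"`/`"post"` per row.
#' @param group group label per row (constant within subject); may be
#'   omitted for single-group designs.
#' @return an object of class `curve_set`.
#' @export
curve_set <- function(curves, subject, time, group = NULL) {
  curves <- as.matrix(curves)
  n <- nrow(curves)
  stopifnot(length(subject) == n, length(time) == n)
  time <- as.character(time)
  if (!all(time %in% c("pre", "post")))
    stop("time labels must be 'pre' or 'post'", call. = FALSE)
  subject <- as.character(subject)
  tab <- table(subject, time)
  bad <- rownames(tab)[tab[, "pre"] != 1L | tab[, "post"] != 1L]
  if (length(bad))
    stop("unbalanced design: subjects without exactly one pre and one post curve: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(group)) {
    stopifnot(length(group) == n)
    group <- as.character(group)
    gs <- tapply(group, subject, function(g) length(unique(g)))
    if (any(gs != 1L))
      stop("group must be constant within subject", call. = FALSE)
  }
  structure(list(curves = curves, subject = subject, time = time,
                 group = group, Q = ncol(curves)),
            class = "curve_set")
}

# reshape a curve_set to pre/post matrices [subject x Q] + subject-level group
curveset_wide <- function(cs) {
  subj <- unique(cs$subject)
  pre <- cs$curves[match(paste(subj, "pre"), paste(cs$subject, cs$time)), , drop = FALSE]
  post <- cs$curves[match(paste(subj, "post"), paste(cs$subject, cs$time)), , drop = FALSE]
  g <- if (is.null(cs$group)) NULL else cs$group[match(subj, cs$subject)]
  list(subject = subj, pre = pre, post = post, group = g)
}

# Vectorized node-wise 2x2 mixed (split-plot) ANOVA sums of squares.
# pre/post: [N x Q]; group: length-N labels (NULL -> time_only design).
# Returns per-effect F fields and dfs, plus the within-cell residual field.
mixed_anova_fields <- function(pre, post, group = NULL) {
  N <- nrow(pre)
  Q <- ncol(pre)
  if (is.null(group)) {
    # one-group repeated measures on difference scores; F_time equals the
    # paired t^2 field by construction
    D <- post - pre
    dbar <- colMeans(D)
    ss_time <- N * dbar^2 / 2
    ss_err <- colSums(sweep(D, 2, dbar)^2) / 2
    df_err <- N - 1L
    F_time <- (ss_time / 1) / (ss_err / df_err)
    scale <- colSums(pre^2) + colSums(post^2)
    F_time[is.nan(F_time) |
           ss_time <= 1e-24 * pmax(scale, .Machine$double.xmin)] <- 0
    resid_field <- sweep(D, 2, dbar) / sqrt(2)
    return(list(effects = list(time = list(F = F_time, df = c(1, df_err))),
                residuals = resid_field))
  }
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("exactly two groups required", call. = FALSE)
  ng <- tabulate(g)
  if (any(ng < 2L)) stop("need at least 2 subjects per group", call. = FALSE)
  Gm <- rowsum(pre + post, g) / (2 * ng)      # group means [2 x Q]
  M <- colMeans(rbind(pre, post))             # grand mean  [Q]
  S <- (pre + post) / 2                       # subject means [N x Q]
  Tpre <- colMeans(pre)
  Tpost <- colMeans(post)
  Cg_pre <- rowsum(pre, g) / ng               # cell means [2 x Q]
  Cg_post <- rowsum(post, g) / ng

  ss_group <- 2 * colSums(ng * (Gm - rep(M, each = 2))^2)
  ss_subj <- 2 * colSums((S - Gm[as.integer(g), , drop = FALSE])^2)
  ss_time <- N * ((Tpre - M)^2 + (Tpost - M)^2)
  int_pre <- Cg_pre - Gm - rep(Tpre, each = 2) + rep(M, each = 2)
  int_post <- Cg_post - Gm - rep(Tpost, each = 2) + rep(M, each = 2)
  ss_int <- colSums(ng * int_pre^2) + colSums(ng * int_post^2)
  res_pre <- pre - Cg_pre[as.integer(g), , drop = FALSE] - S +
    Gm[as.integer(g), , drop = FALSE]
  res_post <- post - Cg_post[as.integer(g), , drop = FALSE] - S +
    Gm[as.integer(g), , drop = FALSE]
  ss_err <- colSums(res_pre^2) + colSums(res_post^2)

  df_subj <- N - 2L
  df_err <- N - 2L
  ms_subj <- ss_subj / df_subj
  ms_err <- ss_err / df_err
  # roundoff guard: an effect SS that is negligible against the data scale
  # (e.g. identical curves) is an exact zero, not 0/0 junk
  scale <- colSums(pre^2) + colSums(post^2)
  safe_F <- function(ss_num, ms_den) {
    F <- ss_num / ms_den
    F[is.nan(F) | ss_num <= 1e-24 * pmax(scale, .Machine$double.xmin)] <- 0
    F
  }
  list(effects = list(
         group = list(F = safe_F(ss_group, ms_subj), df = c(1, df_subj)),
         time = list(F = safe_F(ss_time, ms_err), df = c(1, df_err)),
         interaction = list(F = safe_F(ss_int, ms_err), df = c(1, df_err))),
       residuals = rbind(res_pre, res_post))
}

#' Node-wise mixed repeated-measures ANOVA over curves (1D SPM)
#'
#' Computes, at every node of the common grid, the 2 (group) x 2 (time)
#' mixed-model ANOVA F statistic for the effects group (tested against the
#' between-subject stratum), time and group-by-time interaction (tested
#' against the within-subject residual), yielding one F field per effect.
#' Field-wise inference uses the random-field-theory critical threshold at
#' level `alpha` computed from the residual smoothness; suprathreshold
#' clusters are reported per effect.
#'
#' With two within-subject levels sphericity holds automatically, so no
#' correction is involved.
#'
#' @param curves a [curve_set()].
#' @param design `"group_by_time"` (default, requires group labels) or
#'   `"time_only"` (single-group repeated measures).
#' @param alpha familywise significance level (default 0.05).
#' @param inference `"rft"` (default) attaches RFT thresholds and clusters;
#'   `"none"` returns raw fields only.
#' @return an object of class `spm_anova`: a list of per-effect
#'   `spm_field` results (`F`, `df`, `fwhm`, `resels`, `F_critical`,
#'   `clusters`) plus the residual matrix and estimated smoothness.
#' @export
anova_field <- function(curves, design = c("group_by_time", "time_only"),
                        alpha = 0.05, inference = c("rft", "none")) {
  design <- match.arg(design)
  inference <- match.arg(inference)
  stopifnot(inherits(curves, "curve_set"))
  w <- curveset_wide(curves)
  if (design == "group_by_time" && is.null(w$group))
    stop("group_by_time design requires group labels", call. = FALSE)
  res <- mixed_anova_fields(w$pre, w$post,
                            if (design == "group_by_time") w$group else NULL)
  Q <- curves$Q
  fwhm <- NA_real_
  effects <- res$effects
  if (inference == "rft" && Q > 1L) {
    fwhm <- estimate_fwhm(res$residuals)
    for (nm in names(effects)) {
      eff <- effects[[nm]]
      Fc <- rft_critical_threshold(eff$df, fwhm, Q, alpha)
      effects[[nm]]$fwhm <- fwhm
      effects[[nm]]$resels <- (Q - 1) / fwhm
      effects[[nm]]$F_critical <- Fc
      effects[[nm]]$clusters <- suprathreshold_clusters(eff$F, Fc)
      class(effects[[nm]]) <- "spm_field"
    }
  } else {
    for (nm in names(effects)) class(effects[[nm]]) <- "spm_field"
  }
  structure(list(effects = effects, residuals = res$residuals,
                 fwhm = fwhm, Q = Q, alpha = alpha, design = design),
            class = "spm_anova")
}

#' @export
print.spm_anova <- function(x, ...) {
  cat(sprintf("<spm_anova> %s design, Q = %d nodes, alpha = %g, FWHM = %s\n",
              x$design, x$Q, x$alpha,
              if (is.na(x$fwhm)) "-" else sprintf("%0.2f nodes", x$fwhm)))
  for (nm in names(x$effects)) {
    e <- x$effects[[nm]]
    cat(sprintf("  %-12s F(%d,%d) max %0.3f", nm, e$df[1], e$df[2], max(e$F)))
    if (!is.null(e$F_critical)) {
      cat(sprintf(" | F* = %0.3f | %d cluster(s)", e$F_critical,
                  length(e$clusters)))
      for (cl in e$clusters)
        cat(sprintf(" [%d-%d]", cl$start, cl$end))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
plot.spm_anova <- function(x, effect = names(x$effects)[length(x$effects)], ...) {
  e <- x$effects[[effect]]
  plot(seq_len(x$Q) - 1, e$F, type = "l", xlab = "% ROM node",
       ylab = sprintf("F (%s)", effect), ...)
  if (!is.null(e$F_critical)) {
    graphics::abline(h = e$F_critical, lty = 2)
    for (cl in e$clusters) {
      sel <- cl$start:cl$end
      graphics::polygon(c(sel - 1, rev(sel - 1)),
                        c(e$F[sel], rep(e$F_critical, length(sel))),
                        col = grDevices::adjustcolor(2, 0.4), border = NA)
    }
  }
  invisible(x)
}

#' Maximal suprathreshold runs of an F field
#'
#' @param F numeric field.
#' @param F_critical threshold.
#' @return list of clusters, each `list(start, end, extent, max_F)` with
#'   1-based inclusive node indices.
#' @export
suprathreshold_clusters <- function(F, F_critical) {
  above <- F > F_critical
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i) {
    sel <- starts[i]:ends[i]
    list(start = starts[i], end = ends[i], extent = length(sel),
         max_F = max(F[sel]))
  })
}
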