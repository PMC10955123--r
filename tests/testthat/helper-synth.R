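# shared fixture builders (all generated in code, no stored data)

# Gaussian smoothing matrix for making smooth 1D noise of known FWHM
smoothing_matrix <- function(Q, fwhm) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  K <- outer(seq_len(Q), seq_len(Q), function(i, j) exp(-(i - j)^2 / (2 * s^2)))
  sweep(K, 2, sqrt(colSums(K^2)), "/")   # unit output variance per node
}

# smooth Gaussian null curves, one row per observation
smooth_noise <- function(n, Q, fwhm) {
  matrix(stats::rnorm(n * Q), n) %*% smoothing_matrix(Q, fwhm)
}

# balanced two-group pre/post curve set of pure smooth noise
null_curve_set <- function(n1, n2, Q = 101, fwhm = 15) {
  N <- n1 + n2
  g <- rep(c("intervention", "control"), c(n1, n2))
  curve_set(rbind(smooth_noise(N, Q, fwhm), smooth_noise(N, Q, fwhm)),
            subject = rep(seq_len(N), 2),
            time = rep(c("pre", "post"), each = N),
            group = rep(g, 2))
}

# small long-format cohort table
make_cohort_table <- function(n1, n2, params = "p1", mu = 10, effect = 0,
                              sd_b = 2, sd_w = 1) {
  N <- n1 + n2
  g <- rep(c("intervention", "control"), c(n1, n2))
  do.call(rbind, lapply(params, function(p) {
    u <- stats::rnorm(N, 0, sd_b)
    pre <- mu + u + stats::rnorm(N, 0, sd_w)
    post <- mu * (1 + ifelse(g == "intervention", effect / 100, 0)) + u +
      stats::rnorm(N, 0, sd_w)
    data.frame(subject = sprintf("S%03d", seq_len(N)), group = g,
               parameter = p, pre = pre, post = post)
  }))
}

# independent brute-force mixed-ANOVA oracle via stats::aov (Error stratum)
aov_oracle_2x2 <- function(pre, post, group) {
  N <- length(pre)
  y <- c(pre, post)
  subj <- factor(rep(seq_len(N), 2))
  tm <- factor(rep(c("pre", "post"), each = N), levels = c("pre", "post"))
  gg <- factor(rep(group, 2))
  sm <- summary(stats::aov(y ~ gg * tm + Error(subj)))
  between <- sm[[1]][[1]]
  within <- sm[[2]][[1]]
  list(group = between[["F value"]][1],
       time = within[["F value"]][1],
       interaction = within[["F value"]][2])
}

# analytic circular direction field in the x-y plane (unit tangents)
circle_field <- function(p, prev = NULL) {
  v <- c(-p[2], p[1], 0)
  v <- v / sqrt(sum(v^2))
  if (!is.null(prev) && sum(v * prev) < 0) v <- -v
  v
}
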