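test_that("identical curves give zero F fields for every effect", {
  base <- matrix(rep(sin(seq(0, pi, length.out = 51)), 12), 12, byrow = TRUE)
  cs <- curve_set(base, rep(1:6, 2), rep(c("pre", "post"), each = 6),
                  rep(rep(c("a", "b"), each = 3), 2))
  res <- anova_field(cs, inference = "none")
  for (e in res$effects) expect_true(all(e$F == 0 | is.nan(e$F)))
})

test_that("scalar (Q = 1) fields equal the brute-force mixed ANOVA oracle", {
  set.seed(41)
  for (rep in 1:5) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    N <- n1 + n2
    pre <- rnorm(N); post <- rnorm(N)
    g <- rep(c("a", "b"), c(n1, n2))
    cs <- curve_set(cbind(c(pre, post)), rep(1:N, 2),
                    rep(c("pre", "post"), each = N), rep(g, 2))
    ours <- anova_field(cs, inference = "none")$effects
    oracle <- aov_oracle_2x2(pre, post, g)
    expect_equal(as.numeric(ours$group$F), oracle$group, tolerance = 1e-10)
    expect_equal(as.numeric(ours$time$F), oracle$time, tolerance = 1e-10)
    expect_equal(as.numeric(ours$interaction$F), oracle$interaction,
                 tolerance = 1e-10)
  }
})

test_that("a pure time effect drives the time field, not the interaction", {
  set.seed(42)
  Q <- 101
  shift <- matrix(rep(2 * exp(-(1:Q - 50)^2 / 200), 10), 10, byrow = TRUE)
  pre <- smooth_noise(10, Q, 12)
  post <- smooth_noise(10, Q, 12) + shift   # both groups shifted post
  cs <- curve_set(rbind(pre, post), rep(1:10, 2),
                  rep(c("pre", "post"), each = 10),
                  rep(rep(c("a", "b"), each = 5), 2))
  res <- anova_field(cs)
  expect_gt(max(res$effects$time$F), res$effects$time$F_critical)
  expect_lt(max(res$effects$interaction$F), res$effects$time$F_critical)
})

test_that("F fields are invariant to constant shifts and subject relabeling", {
  set.seed(43)
  cs <- null_curve_set(5, 4, Q = 31, fwhm = 8)
  res1 <- anova_field(cs, inference = "none")$effects
  cs2 <- curve_set(cs$curves + 7, cs$subject, cs$time, cs$group)
  res2 <- anova_field(cs2, inference = "none")$effects
  for (nm in names(res1)) expect_equal(res1[[nm]]$F, res2[[nm]]$F,
                                       tolerance = 1e-9)
  perm <- sample(unique(cs$subject))
  relab <- setNames(seq_along(perm), perm)
  cs3 <- curve_set(cs$curves, relab[as.character(cs$subject)], cs$time, cs$group)
  res3 <- anova_field(cs3, inference = "none")$effects
  for (nm in names(res1)) expect_equal(res1[[nm]]$F, res3[[nm]]$F,
                                       tolerance = 1e-9)
})

test_that("unbalanced subjects are rejected with the offenders listed", {
  expect_error(curve_set(matrix(rnorm(3 * 5), 3), c("s1", "s1", "s2"),
                         c("pre", "post", "pre")),
               "unbalanced.*s2")
})

test_that("smoothness estimate recovers the kernel FWHM within 15%", {
  set.seed(44)
  for (w in c(5, 10, 20)) {
    est <- replicate(200, estimate_fwhm(smooth_noise(20, 101, w)))
    expect_equal(mean(est), w, tolerance = 0.15)
  }
})

test_that("white-noise smoothness is near its theoretical value and stable", {
  set.seed(45)
  est <- replicate(100, estimate_fwhm(matrix(rnorm(20 * 101), 20)))
  expect_equal(mean(est), sqrt(8 * log(2)), tolerance = 0.10)
  expect_lt(stats::sd(est) / mean(est), 0.05)
  # constant (zero-gradient) residual rows are flagged as infinitely smooth
  expect_warning(estimate_fwhm(matrix(c(1, 2, -1, -2), 4, 11)),
                 "infinitely smooth")
  expect_error(estimate_fwhm(matrix(0, 4, 11)), "zero-variance")
})

test_that("RFT threshold has the scalar-quantile limit and is monotone in resels", {
  df <- c(1, 23)
  expect_equal(rft_critical_threshold(df, fwhm = 1e9, Q = 101),
               stats::qf(0.95, 1, 23), tolerance = 1e-5)
  fw <- c(30, 15, 8, 4)
  thr <- vapply(fw, function(w) rft_critical_threshold(df, w, 101), numeric(1))
  expect_true(all(diff(thr) > 0))   # smaller FWHM -> more resels -> higher bar
  expect_error(rft_critical_threshold(df, 10, 101, alpha = 1.5), "alpha")
})

test_that("permutation with 3+3 subjects enumerates all 20 group splits", {
  set.seed(46)
  cs <- null_curve_set(3, 3, Q = 21, fwhm = 8)
  pt <- permutation_threshold(cs, "interaction", n_perm = 1000)
  expect_true(pt$exact)
  expect_identical(pt$n_perm_used, 20L)
  # Monte-Carlo sampling draws from the same distribution of split statistics
  ptmc <- permutation_threshold(cs, "interaction", n_perm = 10, seed = 1)
  expect_false(ptmc$exact)
  expect_true(all(ptmc$max_distribution %in% 0 |
                  vapply(ptmc$max_distribution, function(v)
                    min(abs(v - pt$max_distribution)) < 1e-9, logical(1))))
})

test_that("permutation threshold is seed-reproducible", {
  set.seed(47)
  cs <- null_curve_set(8, 8, Q = 31, fwhm = 10)
  p1 <- permutation_threshold(cs, "interaction", n_perm = 200, seed = 5)
  p2 <- permutation_threshold(cs, "interaction", n_perm = 200, seed = 5)
  expect_identical(p1$F_critical_perm, p2$F_critical_perm)
})

test_that("suprathreshold clusters are the maximal runs above threshold", {
  F <- c(rep(1, 29), rep(5, 31), rep(1, 41))
  cl <- suprathreshold_clusters(F, 4)
  expect_length(cl, 1)
  expect_identical(c(cl[[1]]$start, cl[[1]]$end), c(30L, 60L))
  expect_equal(cl[[1]]$max_F, 5)
  expect_length(suprathreshold_clusters(F, 10), 0)
  cl0 <- suprathreshold_clusters(F, 0)
  expect_length(cl0, 1)
  expect_identical(cl0[[1]]$extent, length(F))
})

test_that("an injected localized interaction is detected where it was put", {
  # rightward-shift style effect concentrated on nodes 20..40 (the lower
  # third of the grid, i.e. inner internal-rotation angles)
  set.seed(48)
  Q <- 101
  bump <- 3 * exp(-(1:Q - 30)^2 / (2 * 5^2))
  hit <- replicate(10, {
    pre <- smooth_noise(14 + 11, Q, 12)
    post <- smooth_noise(14 + 11, Q, 12)
    post[1:14, ] <- post[1:14, ] + matrix(rep(bump, 14), 14, byrow = TRUE)
    cs <- curve_set(rbind(pre, post), rep(1:25, 2),
                    rep(c("pre", "post"), each = 25),
                    rep(rep(c("i", "c"), c(14, 11)), 2))
    res <- anova_field(cs)
    cls <- res$effects$interaction$clusters
    any(vapply(cls, function(cl) cl$start <= 40 && cl$end >= 20, logical(1)))
  })
  expect_gte(mean(hit), 0.9)
})
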