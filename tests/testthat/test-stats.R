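test_that("z-score screening excludes only genuine outliers", {
  v <- c(rep(0, 9), 100)
  res <- zscore_exclude(v)
  expect_identical(res$excluded, 10L)
  expect_equal(max(abs(res$z)), 2.846, tolerance = 1e-3)
  res2 <- zscore_exclude(1:10)
  expect_length(res2$excluded, 0)
  expect_equal(max(abs(res2$z)), 1.486, tolerance = 1e-3)
  expect_warning(res3 <- zscore_exclude(rep(5, 6)), "zero standard deviation")
  expect_true(all(res3$keep))
  expect_error(zscore_exclude(c(1, 2)), "at least 3")
})

test_that("mixed 2x2 ANOVA equals the aov oracle on random small tables", {
  set.seed(51)
  for (rep in 1:5) {
    tab <- make_cohort_table(4, 4)
    ours <- mixed_anova_2x2(tab, "p1")
    oracle <- aov_oracle_2x2(tab$pre, tab$post, tab$group)
    for (nm in c("group", "time", "interaction"))
      expect_equal(ours[[nm]]$F, oracle[[nm]], tolerance = 1e-10)
    expect_equal(ours$interaction$eta_sq,
                 partial_eta_sq(oracle$interaction, 1, 6), tolerance = 1e-10)
  }
})

test_that("zero effect and zero noise give all-zero F", {
  tab <- make_cohort_table(4, 4, sd_b = 0, sd_w = 0)
  ours <- mixed_anova_2x2(tab, "p1")
  for (nm in c("group", "time", "interaction"))
    expect_true(ours[[nm]]$F == 0 || is.nan(ours[[nm]]$F))
})

test_that("a strong intervention-only effect is detected with high power", {
  set.seed(52)
  p <- replicate(40, {
    tab <- make_cohort_table(50, 50, effect = 15, sd_b = 2, sd_w = 1)
    mixed_anova_2x2(tab, "p1")$interaction$p
  })
  expect_gte(mean(p < 0.001), 0.95)
})

test_that("MANOVA matches the multivariate regression oracle to 1e-10", {
  set.seed(53)
  tab <- make_cohort_table(6, 5, params = c("p1", "p2", "p3"))
  mv <- manova_mixed(tab, c("p1", "p2"))
  getm <- function(col, p) tab[[col]][tab$parameter == p]
  D <- cbind(getm("post", "p1") - getm("pre", "p1"),
             getm("post", "p2") - getm("pre", "p2"))
  g <- factor(tab$group[tab$parameter == "p1"])
  oracle <- stats::anova(stats::lm(D ~ g), test = "Wilks")
  expect_equal(mv$interaction$lambda, oracle$Wilks[2], tolerance = 1e-10)
  expect_equal(mv$interaction$F, oracle[["approx F"]][2], tolerance = 1e-8)
  # balanced case: the intercept row is the (weighted = unweighted) time test
  tabb <- make_cohort_table(6, 6, params = c("p1", "p2"))
  mvb <- manova_mixed(tabb, c("p1", "p2"))
  getb <- function(col, p) tabb[[col]][tabb$parameter == p]
  Db <- cbind(getb("post", "p1") - getb("pre", "p1"),
              getb("post", "p2") - getb("pre", "p2"))
  gb <- factor(tabb$group[tabb$parameter == "p1"])
  orb <- stats::anova(stats::lm(Db ~ gb), test = "Wilks")
  expect_equal(mvb$time$lambda, orb$Wilks[1], tolerance = 1e-10)
})

test_that("single-DV MANOVA reduces exactly to the univariate ANOVA", {
  set.seed(54)
  tab <- make_cohort_table(5, 5, params = c("p1", "p2"))
  mv <- manova_mixed(tab, "p1")
  av <- mixed_anova_2x2(tab[tab$parameter == "p1", ], "p1")
  for (nm in c("group", "time", "interaction")) {
    expect_equal(mv[[nm]]$F, av[[nm]]$F, tolerance = 1e-10)
    expect_equal(mv[[nm]]$eta_sq, av[[nm]]$eta_sq, tolerance = 1e-10)
    expect_equal(1 - mv[[nm]]$lambda, av[[nm]]$eta_sq, tolerance = 1e-10)
  }
})

test_that("multivariate eta squared follows 1 - Lambda for single-df effects", {
  expect_equal(1 - 0.691, 0.309)
  set.seed(55)
  tab <- make_cohort_table(7, 6, params = c("p1", "p2"))
  mv <- manova_mixed(tab, c("p1", "p2"))
  for (nm in names(mv))
    expect_equal(mv[[nm]]$eta_sq, 1 - mv[[nm]]$lambda, tolerance = 1e-12)
})

test_that("paired t matches the closed form and stats::t.test", {
  set.seed(56)
  pre <- rnorm(12, 30, 5); post <- pre + rnorm(12, 2, 3)
  ours <- paired_t(pre, post, sided = "two")
  oracle <- stats::t.test(post, pre, paired = TRUE)
  expect_equal(ours$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(ours$p, oracle$p.value, tolerance = 1e-12)
  ours1 <- paired_t(pre, post, sided = "one")
  oracle1 <- stats::t.test(post, pre, paired = TRUE, alternative = "greater")
  expect_equal(ours1$p, oracle1$p.value, tolerance = 1e-12)
  same <- paired_t(pre, pre)
  expect_identical(c(same$t, same$p), c(0, 1))
  expect_error(paired_t(pre, pre + 1), "zero-variance")
})

test_that("Cohen's d identity d * sqrt(n) = t holds", {
  set.seed(57)
  pre <- rnorm(14, 30, 5); post <- pre + rnorm(14, 2, 3)
  d <- cohens_d_paired(pre, post)
  tt <- paired_t(pre, post)
  expect_equal(d * sqrt(14), tt$t, tolerance = 1e-12)
  expect_equal(cohens_d_paired(c(0, 0, 0), c(2, 6, -2)), 0.5)
  expect_error(cohens_d_paired(1:3, 1:3), "zero-variance")
})

test_that("printed (d, p) pairs are internally consistent at the stated n", {
  # intervention rows, n = 14, one-sided
  cases14 <- list(c(d = 0.692, p = 0.011), c(d = 0.593, p = 0.022),
                  c(d = 0.539, p = 0.032))
  for (cs in cases14) {
    t <- cs[["d"]] * sqrt(14)
    p <- stats::pt(t, 13, lower.tail = FALSE)
    expect_equal(round(p, 3), cs[["p"]])
  }
  # control row, n = 11, two-sided
  t <- 0.632 * sqrt(11)
  expect_equal(round(2 * stats::pt(-t, 10), 3), 0.062)
})

test_that("partial eta squared reproduces the reported effect sizes", {
  expect_equal(round(partial_eta_sq(3.628, 1, 23), 3), 0.136)
  expect_equal(round(partial_eta_sq(4.82, 1, 23), 3), 0.173)
  expect_equal(partial_eta_sq(0, 1, 10), 0)
  F <- seq(0, 50, by = 0.5)
  eta <- partial_eta_sq(F, 1, 23)
  expect_true(all(diff(eta) > 0))
  expect_true(all(eta >= 0 & eta < 1))
})

test_that("one-sided p is uniform under the null", {
  set.seed(58)
  p <- replicate(1000, {
    x <- rnorm(14)
    paired_t(rep(0, 14), x, sided = "one")$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
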