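#' z-score outlier screening
#'
#' Flags values whose absolute z score (sample mean and sd) reaches the
#' cutoff, in a single pass without iterative re-exclusion.
#'
#' @param values numeric vector, length >= 3.
#' @param cutoff absolute z threshold (default 2.5).
#' @return list with logical `keep` mask, `excluded` indices and the `z`
#'   scores.
#' @export
zscore_exclude <- function(values, cutoff = 2.5) {
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero standard deviation: no exclusions possible")
    return(list(keep = rep(TRUE, length(values)), excluded = integer(0),
                z = rep(0, length(values))))
  }
  z <- (values - mean(values)) / s
  keep <- abs(z) < cutoff
  list(keep = keep, excluded = which(!keep), z = z)
}

# shared sums-of-squares core at Q = 1 (delegates to the field engine)
.anova_2x2_scalar <- function(pre, post, group) {
  res <- mixed_anova_fields(matrix(pre, ncol = 1), matrix(post, ncol = 1), group)
  lapply(res$effects, function(e) {
    F <- as.numeric(e$F)
    list(F = F, df = e$df,
         p = stats::pf(F, e$df[1], e$df[2], lower.tail = FALSE),
         eta_sq = partial_eta_sq(F, e$df[1], e$df[2]))
  })
}

#' 2x2 mixed repeated-measures ANOVA on a cohort parameter
#'
#' Group (between) by time (within) ANOVA with subject as random blocking
#' factor, on the pre/post values of one parameter of a cohort table. The
#' interaction p value is the between-group difference-in-change test
#' conventionally reported as "Dif" in pre/post training tables.
#'
#' @param table a cohort table (`subject`, `group`, `parameter`, `pre`,
#'   `post`).
#' @param parameter name of the parameter to analyse.
#' @return named list of effects `group`, `time`, `interaction`, each with
#'   `F`, `df`, `p`, `eta_sq`.
#' @export
mixed_anova_2x2 <- function(table, parameter) {
  d <- table[table$parameter == parameter, , drop = FALSE]
  if (nrow(d) == 0L) stop("parameter not found: ", parameter, call. = FALSE)
  if (anyNA(d$pre) || anyNA(d$post))
    stop("missing pre or post cell for parameter ", parameter, call. = FALSE)
  .anova_2x2_scalar(d$pre, d$post, d$group)
}

#' Mixed MANOVA (Wilks' lambda) over a bundle of parameters
#'
#' Multivariate group-by-time analysis on a set of dependent variables
#' measured pre and post. The within-subject part is carried by the
#' per-subject difference scores `D = post - pre` (one column per
#' parameter): the `time` effect tests the grand mean of `D`, the
#' `interaction` tests the group difference of `D`; the between-subject
#' `group` effect tests the subject means `(pre + post) / 2`. Wilks'
#' lambda is `det(E) / det(E + H)` from the error and hypothesis
#' cross-product matrices, converted with Rao's F approximation; the
#' multivariate partial eta squared is `1 - Lambda^(1/s)` (equal to
#' `1 - Lambda` for single-df effects).
#'
#' @param table a cohort table.
#' @param parameters character vector of >= 2 parameter names (a single name
#'   reduces exactly to the univariate ANOVA).
#' @return named list of effects, each with `lambda`, `F`, `df`, `p`,
#'   `eta_sq`.
#' @export
manova_mixed <- function(table, parameters) {
  subj_sets <- lapply(parameters, function(p)
    sort(table$subject[table$parameter == p]))
  if (length(unique(subj_sets)) != 1L)
    stop("all parameters must be observed on the same subjects", call. = FALSE)
  wide_pre <- sapply(parameters, function(p) {
    d <- table[table$parameter == p, ]
    d$pre[order(d$subject)]
  })
  wide_post <- sapply(parameters, function(p) {
    d <- table[table$parameter == p, ]
    d$post[order(d$subject)]
  })
  d0 <- table[table$parameter == parameters[1], ]
  group <- d0$group[order(d0$subject)]
  N <- length(group)
  p <- length(parameters)
  if (N <= p + 1L)
    stop("need n > number of DVs + 1 per analysis", call. = FALSE)
  D <- as.matrix(wide_post) - as.matrix(wide_pre)
  A <- (as.matrix(wide_post) + as.matrix(wide_pre)) / 2
  g <- as.factor(group)
  # sum-to-zero coding: the intercept is the unweighted grand mean, so the
  # within-subject (time) test is the marginal test of the mean difference
  X <- cbind(1, ifelse(g == levels(g)[1], 1, -1))

  wilks_test <- function(Y, which_coef) {
    XtX <- crossprod(X)
    B <- solve(XtX, crossprod(X, Y))
    E <- crossprod(Y - X %*% B)
    if (p > 1L) {
      cn <- kappa(E, exact = TRUE)
      if (!is.finite(cn) || cn > 1e12)
        stop(sprintf("singular error matrix (condition number %.3g)", cn),
             call. = FALSE)
    } else if (E[1, 1] <= 0) stop("singular error matrix (zero residual variance)",
                                  call. = FALSE)
    Cmat <- matrix(0, 1, ncol(X))
    Cmat[1, which_coef] <- 1
    cb <- Cmat %*% B
    H <- crossprod(cb, solve(Cmat %*% solve(XtX, t(Cmat)), cb))
    lambda <- det(E) / det(E + H)
    df_h <- 1L
    df_e <- N - ncol(X)
    s <- min(p, df_h)
    # Rao's F approximation (exact for df_h = 1)
    tpar <- if (p^2 + df_h^2 - 5 > 0)
      sqrt((p^2 * df_h^2 - 4) / (p^2 + df_h^2 - 5)) else 1
    w <- df_e + df_h - (p + df_h + 1) / 2
    df1 <- p * df_h
    df2 <- w * tpar - (p * df_h - 2) / 2
    Fval <- (1 - lambda^(1 / tpar)) / lambda^(1 / tpar) * df2 / df1
    list(lambda = lambda, F = Fval, df = c(df1, df2),
         p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
         eta_sq = 1 - lambda^(1 / s))
  }

  list(group = wilks_test(A, 2L),
       time = wilks_test(D, 1L),
       interaction = wilks_test(D, 2L))
}

#' Paired t test with hypothesis-dependent sidedness
#'
#' t test on the pre-to-post differences. One-sided testing in the
#' hypothesized improvement direction is conventional for pre-registered
#' intervention effects; two-sided otherwise.
#'
#' @param pre,post paired numeric vectors.
#' @param sided `"two"` or `"one"`.
#' @param direction for one-sided tests, the hypothesized direction of
#'   `post - pre` (`"greater"` = improvement increases the value).
#' @return list with `t`, `df`, `p`, `d` (paired Cohen's d), `sided`.
#' @export
paired_t <- function(pre, post, sided = c("two", "one"),
                     direction = c("greater", "less")) {
  sided <- match.arg(sided)
  direction <- match.arg(direction)
  stopifnot(length(pre) == length(post))
  n <- length(pre)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- post - pre
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (all(d == 0))
      return(list(t = 0, df = n - 1L, p = 1, d = 0, sided = "two"))
    stop("zero-variance differences", call. = FALSE)
  }
  tval <- mean(d) / (sdd / sqrt(n))
  pval <- if (sided == "two") 2 * stats::pt(-abs(tval), n - 1L)
          else if (direction == "greater") stats::pt(tval, n - 1L, lower.tail = FALSE)
          else stats::pt(tval, n - 1L)
  list(t = tval, df = n - 1L, p = pval, d = mean(d) / sdd, sided = sided)
}

#' Paired Cohen's d
#'
#' `mean(post - pre) / sd(post - pre)`; the identity `d * sqrt(n) = t` links
#' it to the paired t statistic.
#'
#' @param pre,post paired numeric vectors.
#' @return Cohen's d.
#' @export
cohens_d_paired <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  if (length(pre) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- post - pre
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero-variance differences: d undefined", call. = FALSE)
  mean(d) / sdd
}

#' Partial eta squared from an F statistic
#'
#' `F * df1 / (F * df1 + df2)`, the proportion of effect-plus-error variance
#' attributable to the effect.
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return partial eta squared in `[0, 1)`.
#' @examples
#' partial_eta_sq(3.628, 1, 23)  # 0.136
#' @export
partial_eta_sq <- function(F, df1, df2) {
  if (any(F < 0) || any(df1 <= 0) || any(df2 <= 0))
    stop("F must be >= 0 and dfs > 0", call. = FALSE)
  F * df1 / (F * df1 + df2)
}
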