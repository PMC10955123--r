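#' Permutation (max-statistic) critical threshold for SPM fields
#'
#' Nonparametric familywise threshold: the `(1 - alpha)` quantile of the
#' distribution of the field maximum of the effect's F statistic under
#' permutation. Exchangeability is respected per effect: for `group` and
#' `interaction` the group labels are permuted between subjects; for `time`
#' the pre/post labels are flipped within subjects. When the number of
#' distinct permutations does not exceed `n_perm`, all of them are
#' enumerated exactly instead of sampled.
#'
#' @param curves a [curve_set()] with group labels (except `effect = "time"`
#'   in a single-group design).
#' @param effect `"interaction"`, `"group"` or `"time"`.
#' @param n_perm number of Monte-Carlo permutations (default 10000).
#' @param alpha familywise error level.
#' @param seed integer seed for the permutation draw.
#' @return list with `F_critical_perm`, the permutation `max_distribution`,
#'   `n_perm_used` and whether enumeration was `exact`.
#' @export
permutation_threshold <- function(curves, effect = c("interaction", "group", "time"),
                                  n_perm = 10000L, alpha = 0.05, seed = NULL) {
  effect <- match.arg(effect)
  stopifnot(inherits(curves, "curve_set"))
  w <- curveset_wide(curves)
  N <- length(w$subject)
  has_group <- !is.null(w$group)
  if (effect %in% c("interaction", "group") && !has_group)
    stop("group permutations require group labels", call. = FALSE)

  field_max <- function(pre, post, group) {
    eff <- mixed_anova_fields(pre, post, group)$effects
    max(eff[[if (has_group) effect else "time"]]$F)
  }

  maxs <- with_seed(seed, {
    if (effect == "time") {
      # flip pre/post within subjects
      if (2^N <= n_perm) {
        flips <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), N)))
        exact <- TRUE
      } else {
        flips <- matrix(stats::runif(n_perm * N) < 0.5, nrow = n_perm)
        flips[1, ] <- FALSE    # include the identity
        exact <- FALSE
      }
      vals <- apply(flips, 1L, function(fl) {
        pre <- w$pre; post <- w$post
        pre[fl, ] <- w$post[fl, , drop = FALSE]
        post[fl, ] <- w$pre[fl, , drop = FALSE]
        field_max(pre, post, w$group)
      })
      attr(vals, "exact") <- exact
      vals
    } else {
      g <- as.factor(w$group)
      n1 <- sum(g == levels(g)[1])
      n_splits <- choose(N, n1)
      if (n_splits <= n_perm) {
        combs <- utils::combn(N, n1)
        exact <- TRUE
        vals <- apply(combs, 2L, function(ix) {
          gg <- rep(levels(g)[2], N)
          gg[ix] <- levels(g)[1]
          field_max(w$pre, w$post, gg)
        })
      } else {
        exact <- FALSE
        vals <- vapply(seq_len(n_perm), function(i) {
          gg <- if (i == 1L) as.character(g) else sample(as.character(g))
          field_max(w$pre, w$post, gg)
        }, numeric(1))
      }
      attr(vals, "exact") <- exact
      vals
    }
  })
  list(F_critical_perm = as.numeric(stats::quantile(maxs, 1 - alpha, type = 7)),
       max_distribution = as.numeric(maxs),
       n_perm_used = length(maxs),
       exact = isTRUE(attr(maxs, "exact")))
}
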