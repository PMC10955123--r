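# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# Deterministic sub-seed derivation: every stochastic operation consumes its
# own stream offset, so adding a draw to one operation never reorders draws in
# another.  Result always a valid 32-bit integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 2017 + offset * 7919) %% 2147483587L) + 1L
}

# Evaluate expr with a local RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  env <- parent.frame()
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  eval(substitute(expr), env)
}

# longest run of TRUE; returns c(start, end) 1-based inclusive, or NULL
longest_true_run <- function(x) {
  if (!any(x)) return(NULL)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  best <- idx[which.max(r$lengths[idx])]
  c(starts[best], ends[best])
}
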