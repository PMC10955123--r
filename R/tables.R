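#' Published group-mean tables bundled with the package
#'
#' Returns the printed pre/post group means, percent changes, p values and
#' effect sizes of the study tables shipped in `extdata` (strength,
#' flexibility and muscle-architecture outcomes for the intervention and
#' control arms).
#'
#' @return data frame with columns `table`, `section`, `parameter`, `speed`,
#'   `group`, `pre`, `post`, `delta_pct`, `p`, `d`, `dif_p` and the printed
#'   decimal precision of the means (`digits`).
#' @export
printed_tables <- function() {
  path <- system.file("extdata", "printed_tables.tsv", package = "eccshoulder",
                      mustWork = TRUE)
  df <- utils::read.delim(path, colClasses = "character")
  dec <- function(s) {
    has <- grepl("\\.", s)
    ifelse(has, nchar(sub("^[^.]*\\.", "", s)), 0L)
  }
  df$digits <- dec(df$pre)
  num_cols <- c("pre", "post", "delta_pct", "p", "d", "dif_p")
  for (cl in num_cols) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  df
}

#' Recompute percent changes from the printed group means
#'
#' For every table row, recomputes `100 * (post - pre) / pre` from the
#' printed group means and compares with the printed percent change. Because
#' the means are printed rounded, a row is only expected to match when the
#' printed change is attainable from means within half a printed unit of the
#' published values; the `consistent` flag records that rounding-feasibility
#' check, and `match_2dp` whether the point recomputation agrees to two
#' decimals.
#'
#' @return data frame: the printed rows plus `delta_computed`, `consistent`
#'   and `match_2dp`.
#' @export
reproduce_tables <- function() {
  df <- printed_tables()
  tol_mean <- 0.5 * 10^(-df$digits)
  df$delta_computed <- percent_change(df$pre, df$post)
  lo <- 100 * ((df$post - tol_mean) / (df$pre + tol_mean) - 1)
  hi <- 100 * ((df$post + tol_mean) / (df$pre - tol_mean) - 1)
  df$consistent <- (df$delta_pct + 0.005 >= lo) & (df$delta_pct - 0.005 <= hi)
  df$match_2dp <- abs(df$delta_computed - df$delta_pct) < 0.005 + 1e-9
  df
}
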