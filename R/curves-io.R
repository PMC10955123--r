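#' Write / read normalized torque curves as TSV
#'
#' One row per curve: metadata columns (`subject`, `group`, `time`) followed
#' by the node values `t000 ... t<Q-1>`.
#'
#' @param curves a [curve_set()].
#' @param path file path.
#' @return `read_curves_tsv` returns a `curve_set`.
#' @export
write_curves_tsv <- function(curves, path) {
  stopifnot(inherits(curves, "curve_set"))
  Q <- curves$Q
  mat <- curves$curves
  colnames(mat) <- sprintf("t%03d", seq_len(Q) - 1L)
  df <- data.frame(subject = curves$subject,
                   group = curves$group %||% NA,
                   time = curves$time, mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curves_tsv
#' @export
read_curves_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  node_cols <- grep("^t[0-9]+$", names(df))
  grp <- if (all(is.na(df$group))) NULL else df$group
  curve_set(as.matrix(df[, node_cols]), df$subject, df$time, grp)
}
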