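#' Truncate to a fixed number of decimal places
#'
#' Truncation (toward zero) rather than rounding, as used when matching
#' printed tables whose entries were cut, not rounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` truncated to `digits` decimals.
#' @examples
#' trunc_dec(17.4950, 2)  # 17.49
#' @export
trunc_dec <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL uses (and advances) the
# current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

check_number <- function(x, name, positive = TRUE, finite = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("'%s' must be numeric and non-missing", name), call. = FALSE)
  }
  if (finite && any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  }
  if (positive && any(x <= 0)) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Headered CSV writer used by the pipeline functions: a comment block records
# package version and seed so outputs are re-runnable and self-describing.
write_output_csv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# roadcross %s", as.character(packageVersion("roadcross"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", format(seed)), con)
  writeLines(sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
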