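# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so generator calls do not disturb, and
#' are not disturbed by, the caller's random stream. All stochastic operations
#' in the package route their `seed` argument through this helper.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# TSV writer with '#'-prefixed metadata header lines (parameter provenance).
write_tsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(params)) {
    vals <- vapply(params, function(x) paste(format(x), collapse = ","), "")
    writeLines(sprintf("# %s=%s", names(params), vals), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

# Derive a bounded child seed from a run seed; keeps values in 32-bit range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483629)
}
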