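#' Two-sided p-value of a Pearson correlation
#'
#' Uses the t-distribution form `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom (the base correlation-test convention), which
#' reproduces the magnitude regime of correlation p-values over
#' transcriptome-sized gene overlaps. `|r| = 1` is degenerate and reported
#' as p = 0.
#'
#' @param r Pearson correlation(s) in [-1, 1].
#' @param n_overlap number(s) of paired observations; must be >= 3.
#' @return two-sided p-value(s), vectorized over `r`/`n_overlap`.
#' @examples
#' correlation_pvalue(0.5, 10)   # ~0.141
#' correlation_pvalue(0, 100)    # 1
#' @export
correlation_pvalue <- function(r, n_overlap) {
  if (any(n_overlap < 3, na.rm = TRUE))
    stop2("n_overlap must be >= 3 for a correlation test")
  if (any(abs(r) > 1, na.rm = TRUE)) stop2("|r| must be <= 1")
  p <- ifelse(abs(r) == 1, 0, {
    t <- r * sqrt((n_overlap - 2) / pmax(1 - r^2, .Machine$double.xmin))
    2 * stats::pt(-abs(t), df = n_overlap - 2)
  })
  p
}

#' Contrast-by-contrast Pearson correlation of signatures
#'
#' Correlates every pair of contrast signatures over their pairwise-complete
#' genes (both non-missing). Pairs sharing fewer than `min_overlap` genes,
#' or where either contrast has zero variance on the overlap, are reported
#' as missing. The diagonal is r = 1 (degenerate, p = 0 by convention).
#'
#' @param m a `signature_matrix` (see [build_signature_matrix()]).
#' @param min_overlap minimum number of shared genes for a reported
#'   correlation (default 100; below this, estimates are suppressed rather
#'   than reported).
#' @return a `correlation_matrix`: list of square matrices `r`, `n_overlap`,
#'   `p` and logical `degenerate`, plus the contrast `metadata`.
#' @export
pairwise_correlation <- function(m, min_overlap = 100) {
  scores <- m$scores
  nc <- ncol(scores)
  if (nc < 2) stop2("need >= 2 contrasts to correlate")
  ids <- colnames(scores)
  r <- n <- p <- matrix(NA_real_, nc, nc, dimnames = list(ids, ids))
  degen <- matrix(FALSE, nc, nc, dimnames = list(ids, ids))
  zero_var_warned <- FALSE
  for (i in seq_len(nc)) {
    r[i, i] <- 1; p[i, i] <- 0; degen[i, i] <- TRUE
    n[i, i] <- sum(!is.na(scores[, i]))
    for (j in seq_len(nc)[-seq_len(i)]) {
      ok <- !is.na(scores[, i]) & !is.na(scores[, j])
      nij <- sum(ok)
      n[i, j] <- n[j, i] <- nij
      if (nij < min_overlap) next
      xi <- scores[ok, i]; xj <- scores[ok, j]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
        zero_var_warned <- TRUE
        next
      }
      rij <- stats::cor(xi, xj)
      r[i, j] <- r[j, i] <- rij
      p[i, j] <- p[j, i] <- correlation_pvalue(rij, nij)
      if (abs(rij) == 1) degen[i, j] <- degen[j, i] <- TRUE
    }
  }
  if (zero_var_warned)
    warning("zero-variance contrast(s) on some overlaps: entries left missing",
            call. = FALSE)
  structure(list(r = r, n_overlap = n, p = p, degenerate = degen,
                 metadata = m$metadata),
            class = "correlation_matrix")
}

#' Long-format view of a correlation matrix
#' @param x a `correlation_matrix`.
#' @param ... unused.
#' @return data frame with columns contrast_a, contrast_b, r, n, p (upper
#'   triangle, diagonal excluded).
#' @export
as.data.frame.correlation_matrix <- function(x, ...) {
  ids <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  data.frame(contrast_a = ids[idx[, 1]], contrast_b = ids[idx[, 2]],
             r = x$r[idx], n = x$n_overlap[idx], p = x$p[idx],
             stringsAsFactors = FALSE)
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d contrasts; %d reported pairs\n",
              ncol(x$r), sum(!is.na(x$r[upper.tri(x$r)]))))
  invisible(x)
}
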