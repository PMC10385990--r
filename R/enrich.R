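#' Parse a GMT gene set file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then genes. Within-set duplicate genes are removed.
#'
#' @param path GMT file path.
#' @return a `gene_set_collection` (named list of character vectors; the
#'   first description field is kept as the `source` attribute).
#' @export
parse_gmt <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop2("GMT line ", lineno[which(short)[1]],
          " has fewer than 3 fields (name, description, genes)")
  nms <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nms))
    stop2("duplicate set name in GMT, line ",
          lineno[which(duplicated(nms))[1]], ": ",
          nms[which(duplicated(nms))[1]])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  structure(sets, source = fields[[1]][2], class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n", length(x),
              min(lengths(x)), max(lengths(x))))
  invisible(x)
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score (weight exponent
# 1). `n` = ranked-list length, `pos` = sorted positions of the set's genes,
# `w` = |score| at those positions. The extremum is evaluated only at hit
# boundaries: between hits the walk is linear, so tops/bots bracket it.
.es_stat <- function(n, pos, w) {
  k <- length(pos)
  nr <- sum(w)
  if (nr <= 0) { w <- rep(1, k); nr <- k }   # all-zero scores: flat weights
  dec <- 1 / (n - k)
  tops <- cumsum(w) / nr - (pos - seq_len(k)) * dec
  bots <- tops - w / nr
  mx <- max(tops)
  mn <- min(bots)
  if (mx > -mn) mx else mn
}

# Null ES values for set size k on a ranked weight vector `rw` (|score| in
# rank order). Uses exhaustive enumeration of all C(n, k) placements when
# that is no larger than n_perm; otherwise samples antithetic (mirror-image)
# pairs of position sets, which makes the null multiset exactly symmetric
# under reversal of the ranking, and hence NES/p exactly antisymmetric under
# signature negation. Consumes RNG only in the sampled branch.
.null_es <- function(n, k, rw, n_perm) {
  n_comb <- suppressWarnings(choose(n, k))
  if (is.finite(n_comb) && n_comb <= n_perm) {
    combs <- utils::combn(n, k)
    apply(combs, 2, function(pp) .es_stat(n, pp, rw[pp]))
  } else {
    half <- ceiling(n_perm / 2)
    out <- numeric(2 * half)
    for (b in seq_len(half)) {
      pp <- sort.int(sample.int(n, k))
      qq <- (n + 1L) - rev(pp)
      out[2 * b - 1] <- .es_stat(n, pp, rw[pp])
      out[2 * b] <- .es_stat(n, qq, rw[qq])
    }
    out
  }
}

# NES and permutation p for one observed ES against a null sample: the ES is
# normalized by the mean |null ES| of its own sign class, and the p-value is
# the one-sided permutation tail within that sign class.
.nes_p <- function(es, nul) {
  if (is.na(es)) return(c(NA_real_, NA_real_))
  if (es > 0) {
    posn <- nul[nul > 0]
    if (!length(posn)) return(c(NA_real_, NA_real_))
    c(es / mean(posn), (1 + sum(posn >= es)) / (1 + length(posn)))
  } else if (es < 0) {
    negn <- nul[nul < 0]
    if (!length(negn)) return(c(NA_real_, NA_real_))
    c(es / mean(-negn), (1 + sum(negn <= es)) / (1 + length(negn)))
  } else c(0, 1)
}

#' Gene set enrichment of one contrast signature
#'
#' Ranks genes by signature descending (ties broken by gene id for
#' determinism) and computes, per set, the weighted Kolmogorov-Smirnov
#' running-sum enrichment score with weight exponent 1 (|s| weights). The
#' null distribution comes from gene-label permutations: random placements
#' of `n_present` labels on the ranked list (antithetic mirror pairs; exact
#' enumeration of all placements when there are no more than `n_perm` of
#' them). `NES = ES / mean(|null ES| of matching sign)` and
#' `p = (1 + #{null at least as extreme, same sign}) / (1 + #{null of that
#' sign})`. Sets with fewer than `min_size` genes present in the signature
#' ("insufficient pathway genes") or more than `max_size` are reported as
#' missing rows.
#'
#' @param sig a [contrast_signature()] in the same gene space as the sets.
#' @param sets a `gene_set_collection`.
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param min_size,max_size set-size admission bounds (defaults 5 and 500).
#' @param seed integer seed for the permutation stream.
#' @return an `enrichment_table` data frame: set, ES, NES, p, n_present;
#'   the contrast id is carried in the `contrast_id` attribute.
#' @export
gsea_contrast <- function(sig, sets, n_perm = 10000, min_size = 5,
                          max_size = 500, seed = 1) {
  s <- as.numeric(sig)
  names(s) <- names(sig)
  if (!length(s)) stop2("signature is empty")
  if (n_perm < 100) stop2("n_perm must be >= 100")
  ord <- order(-s, names(s))
  ranked <- s[ord]
  rw <- abs(ranked)
  n <- length(ranked)
  idx_of <- stats::setNames(seq_len(n), names(ranked))

  pos_list <- lapply(sets, function(g) {
    g <- g[g %in% names(idx_of)]
    sort.int(unname(idx_of[g]))
  })
  n_present <- lengths(pos_list)
  valid <- n_present >= min_size & n_present <= max_size & n_present < n
  out <- data.frame(set = names(sets), ES = NA_real_, NES = NA_real_,
                    p = NA_real_, n_present = n_present,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!any(valid)) {
    warning("no gene set within size bounds [", min_size, ", ", max_size,
            "]", call. = FALSE)
  } else {
    es <- vapply(pos_list[valid], function(pp) .es_stat(n, pp, rw[pp]),
                 numeric(1))
    sizes <- sort(unique(n_present[valid]))
    nulls <- with_rng(seed, {
      stats::setNames(lapply(sizes, function(k) .null_es(n, k, rw, n_perm)),
                      as.character(sizes))
    })
    np <- t(vapply(seq_along(es), function(i) {
      k <- n_present[valid][i]
      .nes_p(es[i], nulls[[as.character(k)]])
    }, numeric(2)))
    out$ES[valid] <- es
    out$NES[valid] <- np[, 1]
    out$p[valid] <- np[, 2]
  }
  structure(out, contrast_id = attr(sig, "contrast_id"),
            class = c("enrichment_table", "data.frame"))
}

#' Stouffer integration of per-contrast NES across a study
#'
#' Combines each set's normalized enrichment scores across contrasts with
#' weighted Stouffer integration (NES values are treated as approximately
#' standard-normal under the null; see the package vignette for the caveat),
#' converts to two-tailed p-values and BH-adjusts in one family over all
#' retained sets. Sets missing from every contrast are dropped with a
#' warning.
#'
#' @param tables list of `enrichment_table`s, one per contrast (named by
#'   contrast id, or carrying `contrast_id` attributes).
#' @param w contrast weights, named by contrast id (e.g.
#'   [species_balanced_weights()]); default equal weights.
#' @return an `integrated_pathway_results` data frame: set, Z, p, q,
#'   n_contrasts.
#' @export
integrate_pathways <- function(tables, w = NULL) {
  if (!length(tables)) stop2("no enrichment tables supplied")
  ids <- names(tables) %||% vapply(tables, function(t)
    as.character(attr(t, "contrast_id") %||% NA_character_), "")
  if (anyNA(ids) || any(!nzchar(ids)))
    ids <- sprintf("contrast_%d", seq_along(tables))
  sets <- tables[[1]]$set
  nes <- vapply(tables, function(t) t$NES[match(sets, t$set)],
                numeric(length(sets)))
  nes <- matrix(nes, nrow = length(sets),
                dimnames = list(sets, ids))
  if (is.null(w)) w <- stats::setNames(rep(1, length(ids)), ids)
  w <- w[ids]
  if (anyNA(w)) stop2("weights must cover every contrast")
  all_missing <- rowSums(!is.na(nes)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " set(s) missing from every contrast dropped",
            call. = FALSE)
    nes <- nes[!all_missing, , drop = FALSE]
  }
  if (!nrow(nes)) stop2("no set has a non-missing NES in any contrast")
  Z <- apply(nes, 1, stouffer_integrate, w = unname(w))
  p <- z_to_p(Z)
  structure(data.frame(set = rownames(nes), Z = Z, p = p, q = bh_adjust(p),
                       n_contrasts = rowSums(!is.na(nes)),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("integrated_pathway_results", "data.frame"))
}
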