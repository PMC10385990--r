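#' Variance-stabilizing-style normalization of a count matrix
#'
#' Size factors by median-of-ratios: per-sample median of count ratios to
#' the per-gene geometric mean, computed over genes with all-positive
#' counts, then rescaled so the median size factor is 1 (the rescaling only
#' shifts the output by a global constant and makes the factors directly
#' interpretable: a sample with all counts doubled gets factor 2). If no
#' gene has all-positive counts, library-size factors are used with a
#' warning. Output is `log2(count / size_factor + 1)`; all-zero genes are
#' excluded from size-factor estimation but retained (as zeros) in the
#' output.
#'
#' @param counts nonnegative integer gene x sample matrix, >= 2 samples.
#' @return normalized expression matrix with a `size_factors` attribute.
#' @export
vst_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop2("need >= 2 samples")
  if (any(counts < 0)) stop2("counts must be nonnegative")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    warning("no gene with all-positive counts: falling back to library-size ",
            "factors", call. = FALSE)
    sf <- colSums(counts) / mean(colSums(counts))
  } else {
    loggeo <- rowMeans(log(counts[allpos, , drop = FALSE]))
    sf <- apply(counts[allpos, , drop = FALSE], 2, function(col)
      exp(stats::median(log(col) - loggeo)))
  }
  sf <- sf / stats::median(sf)
  out <- log2(sweep(counts, 2, sf, "/") + 1)
  attr(out, "size_factors") <- sf
  out
}

#' Learn a metabolite-gene correlation model from a paired reference
#'
#' For every metabolite, computes the Spearman correlation of its abundance
#' with every gene's expression across the shared samples, and extracts the
#' top-`k` (positively correlated) and bottom-`k` (negatively correlated)
#' gene sets (ties broken by gene id). Constant metabolites are skipped
#' with a warning. Spearman makes the model invariant to monotone
#' transforms of the metabolite values.
#'
#' @param ref a `paired_reference` (expression and metabolite matrices over
#'   identical, identically ordered samples; >= 10 samples).
#' @param k genes per correlation set (>= 5); `2 * k` must not exceed the
#'   gene count so the positive and negative sets are disjoint.
#' @return a `metabolite_gene_model`: list with `rho` (genes x metabolites
#'   Spearman matrix), `positive` and `negative` (named lists of gene sets)
#'   and `k`.
#' @export
fit_metabolite_model <- function(ref, k = 100) {
  expr <- ref$expression
  met <- ref$metabolites
  if (!identical(colnames(expr), colnames(met)))
    stop2("expression and metabolite matrices must share identical, ",
          "identically ordered samples")
  if (ncol(expr) < 10) stop2("need >= 10 shared samples")
  if (k < 5) stop2("k must be >= 5")
  if (k > nrow(expr)) stop2("k exceeds the number of reference genes")
  if (2 * k > nrow(expr))
    stop2("2 * k exceeds the gene count: positive and negative sets ",
          "would overlap")
  const <- apply(met, 1, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("skipping constant metabolite(s): ",
            paste(rownames(met)[const], collapse = ", "), call. = FALSE)
    met <- met[!const, , drop = FALSE]
  }
  if (!nrow(met)) stop2("no usable metabolite")
  rho <- stats::cor(t(expr), t(met), method = "spearman")
  genes <- rownames(expr)
  pos <- neg <- vector("list", ncol(rho))
  names(pos) <- names(neg) <- colnames(rho)
  for (m in colnames(rho)) {
    o_desc <- order(-rho[, m], genes)
    o_asc <- order(rho[, m], genes)
    pos[[m]] <- genes[o_desc[seq_len(k)]]
    neg[[m]] <- genes[o_asc[seq_len(k)]]
  }
  structure(list(rho = rho, positive = pos, negative = neg, k = k),
            class = "metabolite_gene_model")
}

#' @export
print.metabolite_gene_model <- function(x, ...) {
  cat(sprintf("metabolite_gene_model: %d metabolites, k = %d (of %d genes)\n",
              ncol(x$rho), x$k, nrow(x$rho)))
  invisible(x)
}

#' Predict metabolite responses from one contrast signature
#'
#' For each metabolite the positive and negative correlation sets are scored
#' against the signature with the package's permutation GSEA machinery
#' ([gsea_contrast()]); the prediction is `NES = NES(positive set) -
#' NES(negative set)`, positive values meaning a predicted metabolite
#' increase. A term whose set has fewer than `min_size` genes in the
#' signature contributes zero; the prediction is missing only when both
#' sets are under-covered.
#'
#' @param sig a [contrast_signature()] in reference gene identifiers.
#' @param model a [fit_metabolite_model()] result.
#' @param n_perm permutations for the enrichment null (default 2000).
#' @param seed integer seed.
#' @param min_size minimum genes of a set present in the signature.
#' @return a `metabolite_prediction` data frame: metabolite, NES,
#'   n_pos_present, n_neg_present; contrast id in the `contrast_id`
#'   attribute.
#' @export
predict_metabolites <- function(sig, model, n_perm = 2000, seed = 1,
                                min_size = 5) {
  if (!inherits(model, "metabolite_gene_model") || !length(model$positive))
    stop2("model is empty or not a metabolite_gene_model")
  mets <- names(model$positive)
  sets <- c(stats::setNames(model$positive, paste0(mets, "..pos")),
            stats::setNames(model$negative, paste0(mets, "..neg")))
  class(sets) <- "gene_set_collection"
  et <- suppressWarnings(
    gsea_contrast(sig, sets, n_perm = n_perm, min_size = min_size,
                  max_size = length(sig), seed = seed))
  nes <- stats::setNames(et$NES, et$set)
  npres <- stats::setNames(et$n_present, et$set)
  pos_nes <- nes[paste0(mets, "..pos")]
  neg_nes <- nes[paste0(mets, "..neg")]
  both_missing <- is.na(pos_nes) & is.na(neg_nes)
  pred <- ifelse(both_missing, NA_real_,
                 ifelse(is.na(pos_nes), 0, pos_nes) -
                   ifelse(is.na(neg_nes), 0, neg_nes))
  structure(data.frame(metabolite = mets, NES = unname(pred),
                       n_pos_present = unname(npres[paste0(mets, "..pos")]),
                       n_neg_present = unname(npres[paste0(mets, "..neg")]),
                       row.names = NULL, stringsAsFactors = FALSE),
            contrast_id = attr(sig, "contrast_id"),
            class = c("metabolite_prediction", "data.frame"))
}

#' Stouffer integration of metabolite predictions across contrasts
#'
#' Per metabolite, the per-contrast NES predictions are combined with
#' weighted Stouffer integration ([stouffer_integrate()]), converted to
#' two-tailed p-values and BH-adjusted over all metabolites in one family.
#'
#' @param predictions list of `metabolite_prediction` tables (named by
#'   contrast id or carrying `contrast_id` attributes).
#' @param w contrast weights named by contrast id; default equal.
#' @return an `integrated_metabolite_results` data frame: metabolite, Z, p,
#'   q, n_contrasts.
#' @export
integrate_metabolites <- function(predictions, w = NULL) {
  if (!length(predictions)) stop2("no predictions supplied")
  ids <- names(predictions) %||% vapply(predictions, function(t)
    as.character(attr(t, "contrast_id") %||% NA_character_), "")
  if (anyNA(ids) || any(!nzchar(ids)))
    ids <- sprintf("contrast_%d", seq_along(predictions))
  mets <- predictions[[1]]$metabolite
  nes <- vapply(predictions, function(t) t$NES[match(mets, t$metabolite)],
                numeric(length(mets)))
  nes <- matrix(nes, nrow = length(mets), dimnames = list(mets, ids))
  if (is.null(w)) w <- stats::setNames(rep(1, length(ids)), ids)
  w <- w[ids]
  if (anyNA(w)) stop2("weights must cover every contrast")
  Z <- apply(nes, 1, stouffer_integrate, w = unname(w))
  p <- z_to_p(Z)
  structure(data.frame(metabolite = mets, Z = Z, p = p, q = bh_adjust(p),
                       n_contrasts = rowSums(!is.na(nes)),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("integrated_metabolite_results", "data.frame"))
}
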