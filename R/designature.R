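#' Differential expression for one two-group contrast
#'
#' A deliberately simple, documented stand-in for a full RNA-seq DE engine:
#' log2 fold changes come from library-size-normalized group means with a
#' pseudocount of 0.5, and p-values from a two-sided moderated t-test on
#' log2-normalized values, with per-gene pooled variances shrunk toward the
#' mean gene variance using a prior of 4 degrees of freedom. Externally
#' produced DE tables (e.g. DESeq2 or limma output, via [read_de_table()])
#' can be used anywhere this function's output is accepted: the method the
#' package implements starts at the signature, not at the DE engine.
#'
#' @param counts nonnegative gene x sample count matrix with row names.
#' @param groups two-level factor or character vector over the columns; the
#'   first level is the control/reference, the second the treated group.
#'   Both groups must have at least three samples (balanced designs with at
#'   least three replicates per group are the admission rule of the method).
#' @return a `de_table` data frame with columns `gene`, `logFC` (log2,
#'   treated vs control) and `pvalue`.
#' @examples
#' counts <- matrix(rnbinom(600, mu = 50, size = 10), nrow = 100,
#'                  dimnames = list(sprintf("g%d", 1:100), NULL))
#' de <- compute_differential_expression(counts,
#'         rep(c("control", "treated"), each = 3))
#' head(de)
#' @export
compute_differential_expression <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop2("counts must have gene row names")
  if (any(counts < 0)) stop2("counts must be nonnegative")
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts))
    stop2("groups must label every sample column")
  if (nlevels(groups) != 2L) stop2("exactly two group levels are required")
  if (any(table(groups) < 3L))
    stop2("at least three replicates per group are required")
  a <- groups == levels(groups)[1]
  b <- !a
  if (sum(counts[, a]) == 0 || sum(counts[, b]) == 0)
    stop2("a group with zero total counts cannot be tested")

  libsize <- colSums(counts)
  sf <- libsize / mean(libsize)
  norm <- sweep(counts, 2, sf, "/")
  mean_a <- rowMeans(norm[, a, drop = FALSE])
  mean_b <- rowMeans(norm[, b, drop = FALSE])
  logfc <- log2((mean_b + 0.5) / (mean_a + 0.5))

  y <- log2(norm + 0.5)
  n1 <- sum(a); n2 <- sum(b)
  m_a <- rowMeans(y[, a, drop = FALSE])
  m_b <- rowMeans(y[, b, drop = FALSE])
  v_a <- apply(y[, a, drop = FALSE], 1, stats::var)
  v_b <- apply(y[, b, drop = FALSE], 1, stats::var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v_a + (n2 - 1) * v_b) / d
  d0 <- 4
  s2_shrunk <- (d0 * mean(s2) + d * s2) / (d0 + d)
  se <- sqrt(s2_shrunk * (1 / n1 + 1 / n2))
  diff <- m_b - m_a
  tstat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- 2 * stats::pt(-abs(tstat), df = d + d0)
  structure(data.frame(gene = rownames(counts), logFC = logfc, pvalue = p,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("de_table", "data.frame"))
}

#' Read an externally produced DE table
#'
#' @param path TSV with a header containing columns `gene`, `logFC` and
#'   `pvalue` (extra columns are ignored).
#' @return a `de_table` data frame.
#' @export
read_de_table <- function(path) {
  df <- read_tsv(path)
  need <- c("gene", "logFC", "pvalue")
  if (!all(need %in% names(df)))
    stop2("DE table must have columns gene, logFC, pvalue")
  structure(df[, need], class = c("de_table", "data.frame"))
}

#' Construct a contrast signature
#'
#' @param s named numeric vector of signed significance scores.
#' @param contrast_id unique contrast identifier.
#' @param species,tissue,compound contrast metadata.
#' @return a `contrast_signature` (named numeric vector with metadata
#'   attributes).
#' @export
contrast_signature <- function(s, contrast_id, species = NA_character_,
                               tissue = NA_character_,
                               compound = NA_character_) {
  if (is.null(names(s)) || anyDuplicated(names(s)))
    stop2("signature scores must carry unique gene names")
  structure(as.numeric(s), names = names(s), contrast_id = contrast_id,
            species = species, tissue = tissue, compound = compound,
            class = "contrast_signature")
}

#' @export
print.contrast_signature <- function(x, ...) {
  cat(sprintf("contrast_signature '%s' (%s): %d genes, range [%.2f, %.2f]\n",
              attr(x, "contrast_id"), attr(x, "species"), length(x),
              min(x), max(x)))
  invisible(x)
}

#' Signed significance signature of a DE table
#'
#' The per-gene transcriptome-wide signature of one exposure-vs-control
#' contrast: `s = -log10(p) * sign(log FC)`, positive for significantly
#' up-regulated and negative for significantly down-regulated genes, with
#' magnitude proportional to significance. p-values are floored at 1e-300
#' before the logarithm, so |s| <= 300; `FC = 0` gives `s = 0`; genes with a
#' missing p-value are dropped rather than imputed.
#'
#' @param de a `de_table` (columns gene, logFC, pvalue).
#' @param contrast_id,species,tissue,compound contrast metadata.
#' @return a [contrast_signature()].
#' @examples
#' de <- data.frame(gene = c("a", "b"), logFC = c(2, -1),
#'                  pvalue = c(0.01, 0.001))
#' signature_from_de(de, "toy")  # s = +2, -3
#' @export
signature_from_de <- function(de, contrast_id = attr(de, "contrast_id"),
                              species = NA_character_,
                              tissue = NA_character_,
                              compound = NA_character_) {
  if (!all(c("gene", "logFC", "pvalue") %in% names(de)))
    stop2("de must have columns gene, logFC, pvalue")
  keep <- !is.na(de$pvalue)
  de <- de[keep, , drop = FALSE]
  if (any(de$pvalue < 0 | de$pvalue > 1))
    stop2("p-values must lie in [0, 1]")
  p <- pmax(de$pvalue, 1e-300)
  s <- -log10(p) * sign(de$logFC)
  names(s) <- de$gene
  contrast_signature(s, contrast_id = contrast_id %||% "contrast",
                     species = species, tissue = tissue, compound = compound)
}

#' Assemble per-contrast signatures into a genes x contrasts matrix
#'
#' Takes the union of genes across contrasts; a gene absent from a contrast
#' (not on its platform, unmapped, or filtered) is missing (`NA`), not zero.
#'
#' @param signatures list of [contrast_signature()] objects with unique
#'   contrast ids, all expressed in reference gene identifiers.
#' @return a `signature_matrix`: list with `scores` (genes x contrasts
#'   numeric matrix) and `metadata` (data frame: contrast_id, species,
#'   tissue, compound).
#' @export
build_signature_matrix <- function(signatures) {
  if (!length(signatures)) stop2("no signatures supplied")
  ids <- vapply(signatures, function(x) as.character(attr(x, "contrast_id")), "")
  if (anyDuplicated(ids))
    stop2("duplicate contrast_id: ", paste(unique(ids[duplicated(ids)]),
                                           collapse = ", "))
  genes <- sort(unique(unlist(lapply(signatures, names))))
  scores <- matrix(NA_real_, length(genes), length(ids),
                   dimnames = list(genes, ids))
  for (i in seq_along(signatures))
    scores[names(signatures[[i]]), i] <- as.numeric(signatures[[i]])
  metadata <- data.frame(
    contrast_id = ids,
    species = vapply(signatures, function(x) as.character(attr(x, "species")), ""),
    tissue = vapply(signatures, function(x) as.character(attr(x, "tissue")), ""),
    compound = vapply(signatures, function(x) as.character(attr(x, "compound")), ""),
    stringsAsFactors = FALSE)
  structure(list(scores = scores, metadata = metadata),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature_matrix: %d genes x %d contrasts (%.1f%% missing)\n",
              nrow(x$scores), ncol(x$scores),
              100 * mean(is.na(x$scores))))
  invisible(x)
}

#' Write a signature matrix as TSV (genes in rows, contrasts in columns)
#' @param m a `signature_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(m, path) {
  write_tsv(data.frame(gene = rownames(m$scores), m$scores,
                       check.names = FALSE),
            path,
            params = list(contrasts = ncol(m$scores),
                          species = paste(unique(m$metadata$species),
                                          collapse = ",")))
}
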