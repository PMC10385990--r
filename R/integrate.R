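#' Species-balanced contrast weights
#'
#' Implements the "equal representation to each species" rule for weighted
#' Stouffer integration: every contrast of a species with `n` contrasts gets
#' weight `1 / n`, so each species contributes the same total weight
#' regardless of how many contrasts it supplies.
#'
#' @param metadata data frame with columns `contrast_id` and `species`.
#' @return named numeric vector of weights (names = contrast ids).
#' @examples
#' md <- data.frame(contrast_id = c("a1", "b1", "b2", "b3"),
#'                  species = c("A", "B", "B", "B"))
#' species_balanced_weights(md)  # 1, 1/3, 1/3, 1/3
#' @export
species_balanced_weights <- function(metadata) {
  if (!all(c("contrast_id", "species") %in% names(metadata)))
    stop2("metadata must have columns contrast_id and species")
  sp <- metadata$species
  if (anyNA(sp) || any(!nzchar(sp)) || any(sp == "NA"))
    stop2("every contrast must carry a species label")
  counts <- table(sp)
  stats::setNames(1 / as.numeric(counts[sp]), metadata$contrast_id)
}

#' Convert a signed significance signature to a normal Z-score
#'
#' Interprets `|s|` as `-log10` of a two-tailed p-value and returns the
#' signed standard-normal quantile: `z = sign(s) * qnorm(1 - 10^(-|s|) / 2)`.
#' `|s|` is capped at 300 (the p-value floor of the signature), so
#' |z| <= ~37. This is the inverse of [z_to_p()] on the -log10 scale and
#' makes signatures directly integrable by Stouffer's method with
#' standard-normal calibration under the null.
#'
#' @param s signature value(s); vectors and matrices are handled
#'   elementwise (missing values propagate).
#' @return Z-score(s) with the shape of `s`.
#' @export
signature_to_z <- function(s) {
  a <- pmin(abs(s), 300)
  z <- sign(s) * stats::qnorm(10^(-a) / 2, lower.tail = FALSE)
  z[which(s == 0)] <- 0
  z
}

#' Weighted Stouffer combination of Z-scores
#'
#' `Z = sum(w_i z_i) / sqrt(sum(w_i^2))` over non-missing entries; missing
#' z's are excluded together with their weights. With all weights 1 this
#' reduces to `sum(z) / sqrt(k)`. The denominator keeps Z standard-normal
#' under the null for independent inputs.
#'
#' @param z numeric vector of Z-scores (may contain `NA`).
#' @param w nonnegative weights aligned with `z`; default all 1.
#' @return the combined Z, or `NA` if every input is missing.
#' @examples
#' stouffer_integrate(c(1, 1, 1, 1))          # 2
#' stouffer_integrate(c(3, -1), c(2, 1))      # 5 / sqrt(5)
#' @export
stouffer_integrate <- function(z, w = NULL) {
  if (is.null(w)) w <- rep(1, length(z))
  if (length(w) != length(z)) stop2("weights must align with z")
  ok <- !is.na(z)
  if (!any(ok)) return(NA_real_)
  sum(w[ok] * z[ok]) / sqrt(sum(w[ok]^2))
}

#' Two-tailed normal p-value of a Z-score
#'
#' `p = 2 * (1 - Phi(|Z|))`, computed through the survival tail of the
#' normal distribution so it does not flush to zero until |Z| beyond ~37
#' (e.g. Z = 10 gives 1.52e-23, not 0).
#'
#' @param z Z-score(s).
#' @return two-tailed p-value(s).
#' @examples
#' z_to_p(10)  # ~1.5e-23
#' z_to_p(5)   # ~5.7e-7
#' @export
z_to_p <- function(z) {
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)` over the ascending order
#' statistics, clipped at 1 and returned in input order. Missing p-values
#' are left missing and excluded from the family size `m`.
#'
#' @param p p-values in [0, 1].
#' @return adjusted p-values (FDR q-values) in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop2("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pp <- p[ok]
  m <- length(pp)
  if (!m) return(q)
  o <- order(pp, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(m / seq(m, 1) * pp[o]))[ro]
  q
}

#' Genes present in at least `min_species` species
#'
#' A gene counts as present in a species when it has a non-missing signature
#' in at least one contrast of that species. The default threshold mirrors
#' the "appearing in at least six of the seven species" admission rule for
#' the integrated gene analysis.
#'
#' @param m a `signature_matrix`.
#' @param min_species minimum number of distinct species (default 6).
#' @return character vector of retained gene identifiers.
#' @export
species_presence_filter <- function(m, min_species = 6) {
  sp <- m$metadata$species
  if (is.null(sp)) stop2("signature matrix metadata lacks species labels")
  present <- !is.na(m$scores)
  n_species <- apply(present, 1, function(row)
    length(unique(sp[row])))
  rownames(m$scores)[n_species >= min_species]
}

#' Classify conserved responder genes
#'
#' Reproduces the prioritization bands of the integrated-signature scatter:
#' genes with an extreme integrated Z (|Z| >= `z_hi`) and high
#' cross-contrast signature standard deviation (>= `sd_cut`) are strong but
#' fluctuating responders (`up_high_sd` / `down_high_sd`); genes with
#' |Z| >= `z_lo` and lower SD (< `sd_cut`) are consistent responders
#' (`up_consistent` / `down_consistent`); everything else is `none`.
#' High-SD bands are evaluated first.
#'
#' @param Z integrated Z-score(s).
#' @param sd_sig cross-contrast signature standard deviation(s).
#' @param z_hi,z_lo,sd_cut thresholds (defaults 10, 5, 10, in Z and
#'   signature units respectively).
#' @return factor of class labels aligned with `Z`.
#' @export
classify_conserved_genes <- function(Z, sd_sig, z_hi = 10, z_lo = 5,
                                     sd_cut = 10) {
  cls <- rep("none", length(Z))
  hi_sd <- !is.na(sd_sig) & sd_sig >= sd_cut
  cls[!is.na(Z) & Z >= z_hi & hi_sd] <- "up_high_sd"
  cls[!is.na(Z) & Z <= -z_hi & hi_sd] <- "down_high_sd"
  lo_sd <- !is.na(sd_sig) & sd_sig < sd_cut
  cls[!is.na(Z) & Z >= z_lo & lo_sd] <- "up_consistent"
  cls[!is.na(Z) & Z <= -z_lo & lo_sd] <- "down_consistent"
  factor(cls, levels = c("up_consistent", "up_high_sd", "down_consistent",
                         "down_high_sd", "none"))
}

#' Species-balanced Stouffer integration of a signature matrix
#'
#' The integration step of the meta-analysis: per-gene signatures are
#' converted to normal Z-scores ([signature_to_z()], the default) or used
#' raw, combined across contrasts by weighted Stouffer integration with
#' species-balanced weights, converted to two-tailed p-values, BH-adjusted
#' in one family over all retained genes, and classified into conserved
#' response bands. The cross-contrast standard deviation is computed on the
#' signature scale (the scale of the classification bands), over contrasts
#' where the gene is present, without imputation.
#'
#' @param m a `signature_matrix`.
#' @param weights contrast weights (named by contrast id); default
#'   [species_balanced_weights()] on the matrix metadata.
#' @param input `"z"` (default; z-convert signatures before integrating) or
#'   `"signature"` (integrate raw signature values).
#' @param min_species species-presence admission threshold (default 6); the
#'   filter is applied before integration.
#' @param z_hi,z_lo,sd_cut classification thresholds, see
#'   [classify_conserved_genes()].
#' @return an `integrated_gene_results` data frame: gene, Z, p, q, sd_sig,
#'   n_species, class.
#' @export
integrate_signature_matrix <- function(m, weights = NULL,
                                       input = c("z", "signature"),
                                       min_species = 6,
                                       z_hi = 10, z_lo = 5, sd_cut = 10) {
  input <- match.arg(input)
  if (is.null(weights)) weights <- species_balanced_weights(m$metadata)
  weights <- weights[colnames(m$scores)]
  if (anyNA(weights)) stop2("weights must cover every contrast")
  genes <- species_presence_filter(m, min_species)
  if (!length(genes)) stop2("no gene passes the species-presence filter")
  scores <- m$scores[genes, , drop = FALSE]
  zmat <- if (input == "z") signature_to_z(scores) else scores
  present <- !is.na(zmat)
  wmat <- matrix(weights, nrow(zmat), ncol(zmat), byrow = TRUE)
  num <- rowSums(wmat * zmat, na.rm = TRUE)
  den <- sqrt(rowSums(wmat^2 * present))
  Z <- num / den
  p <- z_to_p(Z)
  sp <- m$metadata$species
  n_species <- apply(!is.na(scores), 1, function(row)
    length(unique(sp[row])))
  sd_sig <- apply(scores, 1, stats::sd, na.rm = TRUE)
  structure(data.frame(gene = genes, Z = Z, p = p, q = bh_adjust(p),
                       sd_sig = sd_sig, n_species = n_species,
                       class = classify_conserved_genes(Z, sd_sig, z_hi,
                                                        z_lo, sd_cut),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("integrated_gene_results", "data.frame"))
}
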