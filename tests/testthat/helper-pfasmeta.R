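# Shared fixtures and independent oracles. Oracles deliberately use a
# different computational route than the package (direct loops, exhaustive
# enumeration, base-R reference functions).

tiny_config <- function(...) {
  args <- list(species_list = c("AAA", "BBB", "CCC"),
               contrasts_per_species = 2, genes_per_species = 200,
               n_replicates = 3, n_conserved_up = 10, n_conserved_down = 10,
               effect_logfc = 2, dispersion = 0.1, ortholog_coverage = 1,
               seed = 42)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

# Signatures for every contrast of a study, mapped to the reference space.
study_signatures <- function(study) {
  sigs <- lapply(seq_len(nrow(study$metadata)), function(i) {
    md <- study$metadata[i, ]
    ct <- study$contrasts[[md$contrast_id]]
    de <- compute_differential_expression(ct$counts, ct$groups)
    sig <- signature_from_de(de, contrast_id = md$contrast_id,
                             species = md$species, tissue = md$tissue,
                             compound = md$compound)
    map_signature_to_reference(sig, study$orthologs[[md$species]])
  })
  names(sigs) <- study$metadata$contrast_id
  sigs
}

# Brute-force enrichment score: explicit walk over the full ranked list.
naive_es <- function(ranked_scores, in_set) {
  n <- length(ranked_scores)
  k <- sum(in_set)
  nr <- sum(abs(ranked_scores[in_set]))
  if (nr <= 0) nr <- k
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (in_set[i]) {
      if (sum(abs(ranked_scores[in_set])) > 0) abs(ranked_scores[i]) / nr
      else 1 / nr
    } else -1 / (n - k)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Exhaustive permutation oracle: ES of every C(n, k) label placement on a
# ranked score vector, via the naive walk.
enum_null_es <- function(ranked_scores, k) {
  n <- length(ranked_scores)
  apply(utils::combn(n, k), 2, function(pp) {
    in_set <- rep(FALSE, n)
    in_set[pp] <- TRUE
    naive_es(ranked_scores, in_set)
  })
}

# Exact permutation p for an observed ES, same sign-conditional formula.
# Ties are counted with a small tolerance: the oracle computes ES by a
# different arithmetic route, so placements identical to the observed set
# agree only to rounding error, while genuinely distinct placements are
# separated by far more than 1e-9 on continuous scores.
enum_p <- function(es, null_es) {
  if (es > 0) {
    pos <- null_es[null_es > 0]
    (1 + sum(pos >= es - 1e-9)) / (1 + length(pos))
  } else {
    neg <- null_es[null_es < 0]
    (1 + sum(neg <= es + 1e-9)) / (1 + length(neg))
  }
}

random_signature <- function(n, seed, id = "c1", species = "HSA") {
  set.seed(seed)
  s <- rnorm(n)
  names(s) <- sprintf("G%03d", seq_len(n))
  contrast_signature(s, contrast_id = id, species = species)
}
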