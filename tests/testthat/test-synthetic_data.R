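test_that("configuration invariants are enforced", {
  expect_error(tiny_config(n_replicates = 2), "three replicates")
  expect_error(tiny_config(effect_logfc = 0), "effect_logfc")
  expect_error(tiny_config(dispersion = -1), "dispersion")
  expect_error(tiny_config(ortholog_coverage = 0), "ortholog_coverage")
  expect_error(tiny_config(n_conserved_up = 150, n_conserved_down = 100),
               "orthologous")
  expect_error(tiny_config(contrasts_per_species = 0), "contrasts_per_species")
})

test_that("study shape follows the configuration and is deterministic", {
  cfg <- tiny_config()
  study <- generate_multispecies_study(cfg)
  expect_length(study$contrasts, 6L)  # 3 species x 2 contrasts
  expect_identical(nrow(study$metadata), 6L)
  # two groups of >= 3, nonnegative integer counts
  for (ct in study$contrasts) {
    expect_true(all(table(ct$groups) >= 3))
    expect_true(all(ct$counts >= 0) && all(ct$counts == round(ct$counts)))
  }
  study2 <- generate_multispecies_study(tiny_config())
  expect_identical(study, study2)
  # planted genes are reachable from every species' gene space
  planted <- study$truth$gene[study$truth$direction != "null"]
  for (sp in names(study$orthologs))
    expect_true(all(planted %in% study$orthologs[[sp]]$target_gene))
})

test_that("planted up-genes show positive empirical log2 fold changes", {
  cfg <- tiny_config(n_conserved_up = 25, n_conserved_down = 0,
                     n_replicates = 5, seed = 7)
  study <- generate_multispecies_study(cfg)
  up <- study$truth$gene[study$truth$direction == "up"]
  expect_gte(length(up), 20)
  lfc <- sapply(names(study$contrasts), function(cid) {
    ct <- study$contrasts[[cid]]
    sp <- study$metadata$species[study$metadata$contrast_id == cid]
    idx <- match(sub("G", paste0(sp, "_g"), up), rownames(ct$counts))
    a <- rowMeans(ct$counts[idx, ct$groups == "control", drop = FALSE])
    b <- rowMeans(ct$counts[idx, ct$groups == "treated", drop = FALSE])
    log2((b + 0.5) / (a + 0.5))
  })
  expect_gt(mean(lfc), 0)
  expect_gt(mean(rowMeans(lfc) > 0), 0.95)
})

test_that("gene set generator plants enriched sets as promised", {
  study <- generate_multispecies_study(tiny_config())
  expect_error(generate_gene_sets(study, n_sets = 5, n_enriched = 6),
               "n_enriched")
  sets <- generate_gene_sets(study, n_sets = 10, set_size = 5,
                             n_enriched = 2, seed = 1)
  expect_length(sets, 10L)
  expect_true(all(lengths(sets) == 5L))
  tru <- attr(sets, "truth")
  expect_identical(sum(tru$direction != "none"), 2L)
  up <- study$truth$gene[study$truth$direction == "up"]
  dn <- study$truth$gene[study$truth$direction == "down"]
  for (i in seq_len(nrow(tru))) {
    if (tru$direction[i] == "none") next
    pool <- if (tru$direction[i] == "up") up else dn
    expect_gte(length(intersect(sets[[tru$set[i]]], pool)), 0.8 * 5)
  }
})

test_that("paired reference plants the promised correlation structure", {
  expect_error(generate_reference_paired_dataset(n_samples = 5), ">= 10")
  expect_error(generate_reference_paired_dataset(n_genes = 10,
                                                 genes_per_metabolite = 20),
               "genes_per_metabolite")
  ref <- generate_reference_paired_dataset(n_genes = 120, n_metabolites = 3,
                                           n_samples = 200,
                                           genes_per_metabolite = 4,
                                           rho = 0.9, seed = 2)
  expect_length(ref$truth, 3L)
  expect_true(all(vapply(ref$truth, nrow, 1L) == 4L))
  expect_identical(colnames(ref$expression), colnames(ref$metabolites))
  # planted pairs dominate non-planted pairs in |Spearman|
  rho_planted <- rho_null <- c()
  for (m in names(ref$truth)) {
    tr <- ref$truth[[m]]
    rr <- apply(ref$expression, 1, function(x)
      cor(x, ref$metabolites[m, ], method = "spearman"))
    rho_planted <- c(rho_planted, abs(rr[tr$gene]))
    rho_null <- c(rho_null, abs(rr[setdiff(names(rr),
                                           unlist(lapply(ref$truth,
                                                         `[[`, "gene")))]))
  }
  expect_gt(median(rho_planted), median(rho_null))
  expect_gt(median(rho_planted), 0.7)
  ref2 <- generate_reference_paired_dataset(n_genes = 120, n_metabolites = 3,
                                            n_samples = 200,
                                            genes_per_metabolite = 4,
                                            rho = 0.9, seed = 2)
  expect_identical(ref, ref2)
})

test_that("study round-trips through the TSV serialization byte-identically", {
  study <- generate_multispecies_study(tiny_config(genes_per_species = 50,
                                                   n_conserved_up = 5,
                                                   n_conserved_down = 5))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(study, d1)
  write_study(study, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  back <- read_study(d1)
  expect_identical(names(back$contrasts), names(study$contrasts))
  expect_equal(back$contrasts[[1]]$counts, study$contrasts[[1]]$counts)
  expect_identical(back$truth$direction, study$truth$direction)
})
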