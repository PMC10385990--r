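test_that("median-of-ratios size factors behave on worked examples", {
  set.seed(1)
  base <- matrix(rnbinom(400, mu = 100, size = 10) + 1, nrow = 100)
  # identical samples: all size factors 1, output log2(count + 1)
  same <- cbind(base[, 1], base[, 1], base[, 1])
  v <- vst_normalize(same)
  expect_equal(unname(attr(v, "size_factors")), rep(1, 3))
  expect_equal(v[, 1], log2(base[, 1] + 1), ignore_attr = TRUE)
  # one sample with all counts doubled gets size factor 2
  doubled <- cbind(base[, 1], base[, 1], base[, 1], base[, 1] * 2)
  sf <- attr(vst_normalize(doubled), "size_factors")
  expect_equal(unname(sf), c(1, 1, 1, 2))
  # all-zero gene excluded from estimation, retained as zeros
  withzero <- rbind(doubled, 0)
  v2 <- vst_normalize(withzero)
  expect_equal(unname(v2[nrow(v2), ]), rep(0, 4))
  expect_equal(attr(v2, "size_factors"), sf)
  # no all-positive gene: library-size fallback with warning
  sparse <- matrix(c(0, 5, 5, 0), nrow = 2)
  expect_warning(vst_normalize(sparse), "library-size")
})

test_that("model fitting ranks planted and self-identical genes on top", {
  ref <- generate_reference_paired_dataset(n_genes = 150, n_metabolites = 4,
                                           n_samples = 120,
                                           genes_per_metabolite = 6,
                                           rho = 0.9, seed = 3)
  model <- fit_metabolite_model(ref, k = 12)
  for (m in names(ref$truth)) {
    tr <- ref$truth[[m]]
    planted_pos <- tr$gene[tr$sign > 0]
    planted_neg <- tr$gene[tr$sign < 0]
    expect_gte(mean(planted_pos %in% model$positive[[m]]), 0.8)
    expect_gte(mean(planted_neg %in% model$negative[[m]]), 0.8)
    expect_length(intersect(model$positive[[m]], model$negative[[m]]), 0L)
  }
  # metabolite identical to one gene's profile: rho = 1, ranks first
  ref2 <- ref
  ref2$metabolites[1, ] <- ref2$expression[10, ]
  model2 <- fit_metabolite_model(ref2, k = 12)
  m1 <- colnames(model2$rho)[1]
  expect_equal(model2$rho[10, m1], 1)
  expect_identical(model2$positive[[m1]][1], rownames(ref2$expression)[10])
  # constant metabolite skipped; k validation
  ref3 <- ref
  ref3$metabolites[2, ] <- 1
  expect_warning(model3 <- fit_metabolite_model(ref3, k = 12), "constant")
  expect_false(rownames(ref3$metabolites)[2] %in% names(model3$positive))
  expect_error(fit_metabolite_model(ref, k = 200), "exceeds")
  # Spearman model is invariant to monotone transforms of the metabolite
  ref4 <- ref
  ref4$metabolites <- exp(ref4$metabolites / 2)
  model4 <- fit_metabolite_model(ref4, k = 12)
  expect_identical(model4$positive, model$positive)
  expect_identical(model4$negative, model$negative)
})

test_that("prediction is signed correctly and antisymmetric", {
  ref <- generate_reference_paired_dataset(n_genes = 200, n_metabolites = 3,
                                           n_samples = 100,
                                           genes_per_metabolite = 8,
                                           rho = 0.9, seed = 5)
  model <- fit_metabolite_model(ref, k = 10)
  # signature up-regulating exactly MET01's positive set; the background is
  # continuous (tie-free ranking), the regime the antisymmetry contract
  # covers
  set.seed(77)
  s <- setNames(abs(rnorm(200, sd = 0.2)) * sign(rnorm(200)),
                rownames(ref$expression))
  s[model$positive[["MET01"]]] <- 4 + abs(rnorm(10, sd = 0.1))
  sig <- contrast_signature(s, "c1")
  pred <- predict_metabolites(sig, model, n_perm = 300, seed = 2)
  expect_gt(pred$NES[pred$metabolite == "MET01"], 0)
  # negated signature negates the prediction
  nsig <- contrast_signature(-s, "c1")
  npred <- predict_metabolites(nsig, model, n_perm = 300, seed = 2)
  expect_equal(npred$NES, -pred$NES, tolerance = 1e-12)
  expect_error(predict_metabolites(sig, list(), n_perm = 300), "model")
})

test_that("metabolites tied to planted genes get large integrated Z", {
  study <- generate_multispecies_study(tiny_config(n_conserved_up = 20,
                                                   n_conserved_down = 0,
                                                   seed = 29))
  up <- study$truth$gene[study$truth$direction == "up"]
  # paired reference whose first metabolite loads on planted up-genes:
  # build it from the generic generator, then relabel genes so that MET01's
  # planted positive genes are exactly a subset of the planted up set.
  ref <- generate_reference_paired_dataset(n_genes = 200, n_metabolites = 4,
                                           n_samples = 80,
                                           genes_per_metabolite = 10,
                                           rho = 0.9, seed = 30)
  genes <- rownames(ref$expression)
  tr1 <- ref$truth[["MET01"]]
  pos1 <- tr1$gene[tr1$sign > 0]
  take <- up[seq_along(pos1)]
  newnames <- genes
  newnames[match(pos1, genes)] <- take
  newnames[match(setdiff(take, pos1), genes)] <- setdiff(pos1, take)
  rename <- setNames(newnames, genes)  # a permutation of the gene names
  rownames(ref$expression) <- unname(rename[genes])
  for (m in names(ref$truth))
    ref$truth[[m]]$gene <- unname(rename[ref$truth[[m]]$gene])
  model <- fit_metabolite_model(ref, k = 10)
  sigs <- study_signatures(study)
  preds <- lapply(seq_along(sigs), function(i)
    predict_metabolites(sigs[[i]], model, n_perm = 300, seed = i))
  names(preds) <- names(sigs)
  res <- integrate_metabolites(preds,
                               species_balanced_weights(study$metadata))
  z1 <- res$Z[res$metabolite == "MET01"]
  expect_gt(z1, max(res$Z[res$metabolite != "MET01"]))
  expect_gt(z1, 2)
})

test_that("metabolite integration matches closed forms", {
  mk <- function(nes, id) structure(
    data.frame(metabolite = paste0("M", seq_along(nes)), NES = nes,
               n_pos_present = 10L, n_neg_present = 10L),
    contrast_id = id, class = c("metabolite_prediction", "data.frame"))
  res <- integrate_metabolites(list(a = mk(3, "a"), b = mk(3, "b"),
                                    c = mk(3, "c")))
  expect_equal(res$Z, 3 * sqrt(3))
  res1 <- integrate_metabolites(list(a = mk(-2.5, "a")))
  expect_equal(res1$Z, -2.5)
  expect_true(all(res$q >= res$p))
})
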