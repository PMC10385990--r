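test_that("GMT parsing validates lines, names and duplicates", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tsrc\tA\tB\tC", "S2\tsrc\tB\tD"), p)
  sets <- parse_gmt(p)
  expect_length(sets, 2L)
  expect_identical(sets$S1, c("A", "B", "C"))
  writeLines(c("S1\tsrc\tA\tA\tB"), p)
  expect_identical(parse_gmt(p)$S1, c("A", "B"))  # within-set dedup
  writeLines(c("S1\tsrc\tA", "S1\tsrc\tB"), p)
  expect_error(parse_gmt(p), "duplicate set name")
  writeLines(c("S1"), p)
  expect_error(parse_gmt(p), "line 1")
  # round trip through write_gmt
  sets2 <- structure(list(X = c("g1", "g2", "g3"), Y = c("g2", "g4", "g5")),
                     class = "gene_set_collection")
  write_gmt(sets2, p)
  expect_identical(unclass(parse_gmt(p))[1:2], unclass(sets2)[1:2])
})

test_that("a set of top-ranked genes scores positive ES", {
  sig <- random_signature(100, seed = 1)
  top5 <- names(sort(sig, decreasing = TRUE))[1:5]
  sets <- structure(list(top = top5), class = "gene_set_collection")
  et <- gsea_contrast(sig, sets, n_perm = 100, seed = 1)
  expect_gt(et$ES, 0)
  expect_gt(et$NES, 0)
  expect_lt(et$p, 0.2)
})

test_that("ES agrees with the brute-force running-sum oracle", {
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(30:80, 1)
    sig <- random_signature(n, seed = rep + 100)
    k <- sample(5:12, 1)
    genes <- sample(names(sig), k)
    sets <- structure(list(s = genes), class = "gene_set_collection")
    et <- suppressWarnings(gsea_contrast(sig, sets, n_perm = 100, seed = 1))
    ranked <- sig[order(-as.numeric(sig), names(sig))]
    expect_equal(et$ES, naive_es(as.numeric(ranked),
                                 names(ranked) %in% genes),
                 tolerance = 1e-12)
  }
})

test_that("tiny universes reproduce the exhaustive permutation null", {
  # universe of 6 genes, 2-gene set: all C(6,2) = 15 label placements
  sig <- random_signature(6, seed = 3)
  genes <- names(sig)[c(2, 5)]
  sets <- structure(list(s = genes), class = "gene_set_collection")
  et <- gsea_contrast(sig, sets, n_perm = 100, min_size = 2, seed = 1)
  ranked <- sig[order(-as.numeric(sig), names(sig))]
  nul <- enum_null_es(as.numeric(ranked), 2)
  expect_length(nul, 15L)
  expect_equal(et$p, enum_p(et$ES, nul), tolerance = 1 / (1 + 100))
  # and the match is exact, since all placements are enumerated
  expect_equal(et$p, enum_p(et$ES, nul), tolerance = 1e-12)
})

test_that("set-size bounds produce missing rows", {
  sig <- random_signature(50, seed = 4)
  sets <- structure(list(small = names(sig)[1:4],
                         ok = names(sig)[5:12]),
                    class = "gene_set_collection")
  et <- gsea_contrast(sig, sets, n_perm = 100, min_size = 5, seed = 1)
  expect_true(is.na(et$ES[et$set == "small"]))
  expect_identical(et$n_present[et$set == "small"], 4L)
  expect_false(is.na(et$ES[et$set == "ok"]))
  expect_warning(gsea_contrast(sig, sets["small"], n_perm = 100,
                               min_size = 5, seed = 1), "size bounds")
  expect_error(gsea_contrast(sig, sets, n_perm = 50, seed = 1), ">= 100")
})

test_that("negating the signature negates ES and NES, keeps p", {
  sig <- random_signature(120, seed = 6)
  nsig <- contrast_signature(setNames(-as.numeric(sig), names(sig)), "c1",
                             species = attr(sig, "species"))
  set.seed(1)
  sets <- structure(lapply(1:4, function(i) sample(names(sig), 10)),
                    class = "gene_set_collection")
  names(sets) <- paste0("S", 1:4)
  a <- gsea_contrast(sig, sets, n_perm = 400, seed = 11)
  b <- gsea_contrast(nsig, sets, n_perm = 400, seed = 11)
  expect_equal(a$ES, -b$ES, tolerance = 1e-12)
  expect_equal(a$NES, -b$NES, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("null NES distribution is centred near +/-1 per sign class", {
  sig <- random_signature(400, seed = 7)
  set.seed(2)
  sets <- structure(lapply(1:40, function(i) sample(names(sig), 15)),
                    class = "gene_set_collection")
  names(sets) <- sprintf("S%02d", 1:40)
  et <- gsea_contrast(sig, sets, n_perm = 2000, seed = 3)
  expect_lt(abs(mean(et$NES[et$ES > 0]) - 1), 0.15)
  expect_lt(abs(mean(et$NES[et$ES < 0]) + 1), 0.15)
})

test_that("pathway integration matches closed forms and drops empty sets", {
  mk <- function(nes, id) structure(
    data.frame(set = paste0("S", seq_along(nes)), ES = sign(nes),
               NES = nes, p = 0.5, n_present = 10L),
    contrast_id = id, class = c("enrichment_table", "data.frame"))
  tabs <- list(c1 = mk(c(2, NA), "c1"), c2 = mk(c(2, NA), "c2"),
               c3 = mk(c(2, NA), "c3"), c4 = mk(c(2, NA), "c4"))
  expect_warning(res <- integrate_pathways(tabs), "missing from every")
  expect_equal(res$Z[res$set == "S1"], 4)  # 8 / sqrt(4)
  expect_false("S2" %in% res$set)
  res1 <- integrate_pathways(list(c1 = mk(3.3, "c1")))
  expect_equal(res1$Z, 3.3)
  expect_true(all(res$q >= res$p))
})

test_that("planted enriched pathways dominate integrated results", {
  # planted genes are a small fraction of the genome (<1%), so uniform
  # "random" sets are rarely contaminated with real signal
  study <- generate_multispecies_study(tiny_config(genes_per_species = 2000,
                                                   n_conserved_up = 8,
                                                   n_conserved_down = 8,
                                                   seed = 19))
  sets <- generate_gene_sets(study, n_sets = 30, set_size = 10,
                             n_enriched = 2, seed = 20)
  sigs <- study_signatures(study)
  tabs <- lapply(seq_along(sigs), function(i)
    gsea_contrast(sigs[[i]], sets, n_perm = 300, seed = i))
  names(tabs) <- names(sigs)
  w <- species_balanced_weights(study$metadata)
  res <- integrate_pathways(tabs, w)
  tru <- attr(sets, "truth")
  planted <- tru$set[tru$direction != "none"]
  expect_true(all(res$q[match(planted, res$set)] < 0.05))
  random_q <- res$q[!res$set %in% planted]
  expect_gte(mean(random_q > 0.05), 0.9)
})
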