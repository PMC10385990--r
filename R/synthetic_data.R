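#' Simulation configuration for a multi-species exposure corpus
#'
#' Describes the synthetic world the generator emulates: a set of species,
#' each contributing a number of two-group (exposed vs control) contrasts
#' with at least three replicates per group, a shared reference gene space
#' reachable through per-species ortholog tables, and a block of "planted"
#' genes that respond to the exposure with a consistent direction in every
#' contrast of every species.
#'
#' Defaults mirror the scale of the real corpus the package targets: 7
#' species contributing 110 contrasts in total (dominated by human), ~2000
#' genes, and 50 conserved up- plus 50 conserved down-regulated genes with a
#' mean absolute log2 fold change of 2.
#'
#' @param species_list character vector of species labels.
#' @param contrasts_per_species integer vector (recycled if scalar) of
#'   contrasts contributed by each species; all must be >= 1.
#' @param genes_per_species number of genes on each species' platform.
#' @param n_replicates replicates per group in every contrast; must be >= 3.
#' @param n_conserved_up,n_conserved_down numbers of planted conserved genes.
#' @param effect_logfc mean absolute log2 fold change of planted genes (> 0).
#' @param dispersion negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param ortholog_coverage fraction of each species' genes carrying a
#'   reference ortholog, in (0, 1]; planted genes are always covered.
#' @param seed integer seed; the whole study is a deterministic function of
#'   the configuration including the seed.
#' @return an object of class `simulation_config`.
#' @seealso [generate_multispecies_study()]
#' @export
simulation_config <- function(species_list = c("HSA", "MMU", "DRE", "GMO",
                                               "CEL", "PPR", "MSA"),
                              contrasts_per_species = c(55, 20, 10, 9, 6, 6, 4),
                              genes_per_species = 2000,
                              n_replicates = 3,
                              n_conserved_up = 50,
                              n_conserved_down = 50,
                              effect_logfc = 2,
                              dispersion = 0.1,
                              ortholog_coverage = 0.9,
                              seed = 1) {
  if (!is.character(species_list) || !length(species_list) ||
      anyDuplicated(species_list))
    stop2("species_list must be a non-empty vector of unique labels")
  if (length(contrasts_per_species) == 1L)
    contrasts_per_species <- rep(contrasts_per_species, length(species_list))
  if (length(contrasts_per_species) != length(species_list))
    stop2("contrasts_per_species must align with species_list")
  if (any(contrasts_per_species < 1))
    stop2("contrasts_per_species must all be >= 1")
  if (n_replicates < 3)
    stop2("n_replicates must be >= 3: the design requires a balanced ",
          "exposed vs control contrast with at least three replicates per group")
  if (effect_logfc <= 0) stop2("effect_logfc must be > 0")
  if (dispersion <= 0) stop2("dispersion must be > 0")
  if (ortholog_coverage <= 0 || ortholog_coverage > 1)
    stop2("ortholog_coverage must be in (0, 1]")
  n_orth <- round(ortholog_coverage * genes_per_species)
  if (n_conserved_up + n_conserved_down > n_orth)
    stop2("n_conserved_up + n_conserved_down exceeds the number of ",
          "orthologous genes")
  structure(list(species_list = species_list,
                 contrasts_per_species = stats::setNames(
                   as.integer(contrasts_per_species), species_list),
                 genes_per_species = as.integer(genes_per_species),
                 n_replicates = as.integer(n_replicates),
                 n_conserved_up = as.integer(n_conserved_up),
                 n_conserved_down = as.integer(n_conserved_down),
                 effect_logfc = effect_logfc,
                 dispersion = dispersion,
                 ortholog_coverage = ortholog_coverage,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.TISSUES   <- c("liver", "kidney", "blood", "ovary", "testis", "embryo")
.COMPOUNDS <- c("PFOA", "PFOS", "PFNA", "PFHxS", "PFBS", "PFDA")

#' Generate a synthetic multi-species exposure study
#'
#' Draws per-contrast count matrices from a negative-binomial model with
#' gene-specific baselines (log-normal, meanlog 5, sdlog 1.5, drawn once per
#' species and reused across that species' contrasts). Planted conserved
#' genes are shifted by `+effect_logfc` (up) or `-effect_logfc` (down) log2
#' units in the treated group of every contrast; all other genes have zero
#' expected log fold change. Species gene identifiers are `<SPECIES>_g<k>`,
#' reference identifiers `G<k>`, and each species' ortholog table maps gene
#' `k` to reference gene `k` for a covered subset that always includes every
#' planted gene, so planted effects survive ortholog mapping in all species.
#'
#' @param config a [simulation_config()].
#' @return an object of class `synthetic_study`: a list with elements
#'   `contrasts` (named list of `list(counts, groups)`; counts are genes x
#'   samples nonnegative integer matrices, groups is a character vector with
#'   levels control/treated), `metadata` (data frame: contrast_id, species,
#'   tissue, compound), `orthologs` (per-species data frames with columns
#'   source_gene, target_gene, score), `truth` (data frame: gene, direction
#'   in up/down/null over reference genes) and `config`.
#' @examples
#' cfg <- simulation_config(species_list = c("AAA", "BBB"),
#'                          contrasts_per_species = 2,
#'                          genes_per_species = 100, n_conserved_up = 5,
#'                          n_conserved_down = 5, seed = 7)
#' study <- generate_multispecies_study(cfg)
#' length(study$contrasts)  # 4
#' @export
generate_multispecies_study <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop2("config must be a simulation_config")
  if (config$n_replicates < 3)
    stop2("n_replicates must be >= 3 (minimum replicate rule)")
  ngene <- config$genes_per_species
  nrep  <- config$n_replicates
  ref_genes <- sprintf("G%d", seq_len(ngene))
  with_rng(config$seed, {
    planted <- sample(seq_len(ngene), config$n_conserved_up +
                        config$n_conserved_down)
    up_idx <- planted[seq_len(config$n_conserved_up)]
    dn_idx <- setdiff(planted, up_idx)
    direction <- rep("null", ngene)
    direction[up_idx] <- "up"
    direction[dn_idx] <- "down"
    truth <- data.frame(gene = ref_genes, direction = direction,
                        stringsAsFactors = FALSE)
    delta <- numeric(ngene)
    delta[up_idx] <- config$effect_logfc
    delta[dn_idx] <- -config$effect_logfc

    contrasts <- list()
    orthologs <- list()
    meta <- list()
    size <- 1 / config$dispersion
    for (sp in config$species_list) {
      sp_genes <- sprintf("%s_g%d", sp, seq_len(ngene))
      covered <- rep(FALSE, ngene)
      covered[planted] <- TRUE
      n_target <- round(config$ortholog_coverage * ngene)
      extra <- n_target - sum(covered)
      if (extra > 0)
        covered[sample(which(!covered), extra)] <- TRUE
      orthologs[[sp]] <- data.frame(
        source_gene = sp_genes[covered],
        target_gene = ref_genes[covered],
        score = round(stats::runif(sum(covered), 5, 15), 2),
        stringsAsFactors = FALSE)
      mu0 <- stats::rlnorm(ngene, meanlog = 5, sdlog = 1.5)
      mu1 <- mu0 * 2^delta
      for (j in seq_len(config$contrasts_per_species[[sp]])) {
        cid <- sprintf("%s_c%02d", sp, j)
        counts <- cbind(
          matrix(stats::rnbinom(ngene * nrep, mu = mu0, size = size),
                 nrow = ngene),
          matrix(stats::rnbinom(ngene * nrep, mu = mu1, size = size),
                 nrow = ngene))
        groups <- rep(c("control", "treated"), each = nrep)
        dimnames(counts) <- list(sp_genes,
                                 sprintf("%s_%s_%d", cid, groups,
                                         rep(seq_len(nrep), 2)))
        contrasts[[cid]] <- list(counts = counts, groups = groups)
        meta[[cid]] <- data.frame(contrast_id = cid, species = sp,
                                  tissue = sample(.TISSUES, 1),
                                  compound = sample(.COMPOUNDS, 1),
                                  stringsAsFactors = FALSE)
      }
    }
    structure(list(contrasts = contrasts,
                   metadata = do.call(rbind, c(meta, make.row.names = FALSE)),
                   orthologs = orthologs,
                   truth = truth,
                   config = config),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d species, %d contrasts, %d genes/species, %d planted\n",
    length(x$orthologs), length(x$contrasts), x$config$genes_per_species,
    sum(x$truth$direction != "null")))
  invisible(x)
}

#' Generate gene set collections with planted enriched sets
#'
#' Builds `n_sets` gene sets over the study's reference gene space. The first
#' `n_enriched` sets are "enriched": at least 80% of their members are drawn
#' from the planted conserved genes of one direction (alternating up, down,
#' up, ...), the remainder from unplanted genes. All other sets are uniform
#' random draws. The enrichment truth is recorded in the `truth` attribute.
#'
#' @param study a `synthetic_study`.
#' @param n_sets total number of sets.
#' @param set_size genes per set (must not exceed the reference gene count).
#' @param n_enriched number of planted-enriched sets; must be <= `n_sets`.
#' @param seed integer seed.
#' @return a `gene_set_collection`: named list of character vectors with a
#'   `truth` attribute (data frame: set, direction in up/down/none).
#' @export
generate_gene_sets <- function(study, n_sets = 50, set_size = 20,
                               n_enriched = 5, seed = 1) {
  if (!inherits(study, "synthetic_study")) stop2("study must be a synthetic_study")
  ref <- study$truth$gene
  if (set_size > length(ref)) stop2("set_size exceeds the reference gene count")
  if (n_enriched > n_sets) stop2("n_enriched must be <= n_sets")
  up <- study$truth$gene[study$truth$direction == "up"]
  dn <- study$truth$gene[study$truth$direction == "down"]
  unplanted <- study$truth$gene[study$truth$direction == "null"]
  n_core <- ceiling(0.8 * set_size)
  with_rng(seed, {
    sets <- vector("list", n_sets)
    dir <- rep("none", n_sets)
    for (i in seq_len(n_sets)) {
      if (i <= n_enriched) {
        d <- if (i %% 2 == 1) "up" else "down"
        pool <- if (d == "up") up else dn
        if (n_core > length(pool))
          stop2("not enough planted ", d, "-genes for an enriched set of size ",
                set_size)
        sets[[i]] <- c(sample(pool, n_core),
                       sample(unplanted, set_size - n_core))
        dir[i] <- d
      } else {
        sets[[i]] <- sample(ref, set_size)
      }
    }
    names(sets) <- sprintf("SET_%04d", seq_len(n_sets))
    structure(sets,
              truth = data.frame(set = names(sets), direction = dir,
                                 stringsAsFactors = FALSE),
              source = "synthetic",
              class = "gene_set_collection")
  })
}

#' Generate a paired transcriptome/metabolome reference with planted structure
#'
#' Stands in for a large paired expression/metabolite resource (e.g. a cell
#' line encyclopedia) used to learn metabolite-gene correlation structure.
#' Each metabolite is a latent Gaussian factor over samples; its planted
#' genes load on that factor with alternating sign and a Gaussian-copula
#' coefficient chosen so that the expected |Spearman| correlation equals
#' `rho`; all remaining genes are independent noise.
#'
#' @param n_genes,n_metabolites,n_samples dimensions; `n_samples` must be
#'   >= 10 (correlation estimates are unstable below that).
#' @param genes_per_metabolite planted genes per metabolite; planted blocks
#'   are disjoint, so `n_metabolites * genes_per_metabolite <= n_genes`.
#' @param rho target absolute Spearman correlation of planted pairs, in (0,1).
#' @param seed integer seed.
#' @return a `paired_reference`: list with `expression` (genes x samples,
#'   log-scale continuous), `metabolites` (metabolites x samples, arbitrary
#'   units; identical ordered sample columns) and `truth` (named list of data
#'   frames gene/sign per metabolite).
#' @export
generate_reference_paired_dataset <- function(n_genes = 1000,
                                              n_metabolites = 20,
                                              n_samples = 100,
                                              genes_per_metabolite = 20,
                                              rho = 0.7, seed = 1) {
  if (n_samples < 10)
    stop2("n_samples must be >= 10: correlation estimates are unstable below")
  if (genes_per_metabolite > n_genes)
    stop2("genes_per_metabolite must be <= n_genes")
  if (rho <= 0 || rho >= 1) stop2("rho must be in (0, 1)")
  if (n_metabolites * genes_per_metabolite > n_genes)
    stop2("planted gene blocks would overlap: need n_metabolites * ",
          "genes_per_metabolite <= n_genes")
  genes <- sprintf("G%d", seq_len(n_genes))
  samples <- sprintf("S%03d", seq_len(n_samples))
  mets <- sprintf("MET%02d", seq_len(n_metabolites))
  # Pearson loading giving Spearman ~ rho under the Gaussian copula
  a <- 2 * sin(pi * rho / 6)
  with_rng(seed, {
    expr <- matrix(stats::rnorm(n_genes * n_samples), n_genes,
                   dimnames = list(genes, samples))
    metmat <- matrix(stats::rnorm(n_metabolites * n_samples), n_metabolites,
                     dimnames = list(mets, samples))
    blocks <- matrix(sample(n_genes, n_metabolites * genes_per_metabolite),
                     nrow = n_metabolites)
    truth <- vector("list", n_metabolites)
    names(truth) <- mets
    for (m in seq_len(n_metabolites)) {
      gidx <- sort(blocks[m, ])
      signs <- rep(c(1, -1), length.out = genes_per_metabolite)
      z <- metmat[m, ]
      expr[gidx, ] <- signs *
        (a * matrix(z, genes_per_metabolite, n_samples, byrow = TRUE) +
           sqrt(1 - a^2) *
           matrix(stats::rnorm(genes_per_metabolite * n_samples),
                  genes_per_metabolite))
      truth[[m]] <- data.frame(gene = genes[gidx], sign = signs,
                               stringsAsFactors = FALSE)
    }
    structure(list(expression = 8 + 1.5 * expr,
                   metabolites = 10 + metmat,
                   truth = truth),
              class = "paired_reference")
  })
}

# ---------------------------------------------------------------------------
# Serialization: plain TSV/GMT, '#'-prefixed metadata headers.

#' Write a synthetic study to a directory of TSV files
#'
#' Emits one counts TSV per contrast (first column `gene`, remaining columns
#' samples), a per-sample `metadata.tsv` (contrast_id, species, tissue,
#' compound, sample, group), one ortholog TSV per species (source_gene,
#' target_gene, score) and `truth.tsv`.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_rows <- list()
  for (cid in names(study$contrasts)) {
    ct <- study$contrasts[[cid]]
    df <- data.frame(gene = rownames(ct$counts), ct$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, file.path(dir, paste0("counts_", cid, ".tsv")))
    mrow <- study$metadata[study$metadata$contrast_id == cid, , drop = FALSE]
    meta_rows[[cid]] <- data.frame(
      mrow[rep(1, ncol(ct$counts)), , drop = FALSE],
      sample = colnames(ct$counts), group = ct$groups,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, c(meta_rows, make.row.names = FALSE)),
            file.path(dir, "metadata.tsv"))
  for (sp in names(study$orthologs))
    write_tsv(study$orthologs[[sp]],
              file.path(dir, paste0("orthologs_", sp, ".tsv")))
  write_tsv(study$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#' @param dir directory path.
#' @return a `synthetic_study`-shaped list (without a `config` element).
#' @export
read_study <- function(dir) {
  meta_long <- read_tsv(file.path(dir, "metadata.tsv"))
  metadata <- unique(meta_long[, c("contrast_id", "species", "tissue",
                                   "compound")])
  rownames(metadata) <- NULL
  contrasts <- list()
  for (cid in metadata$contrast_id) {
    df <- read_tsv(file.path(dir, paste0("counts_", cid, ".tsv")))
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df$gene
    rows <- meta_long[meta_long$contrast_id == cid, ]
    contrasts[[cid]] <- list(
      counts = counts[, rows$sample, drop = FALSE],
      groups = rows$group)
  }
  orthologs <- list()
  for (sp in unique(metadata$species)) {
    p <- file.path(dir, paste0("orthologs_", sp, ".tsv"))
    if (file.exists(p)) orthologs[[sp]] <- read_tsv(p)
  }
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) read_tsv(truth_path) else NULL
  structure(list(contrasts = contrasts, metadata = metadata,
                 orthologs = orthologs, truth = truth, config = NULL),
            class = "synthetic_study")
}

#' Write a gene set collection as a GMT file
#' @param sets a `gene_set_collection` (or named list of character vectors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  src <- attr(sets, "source") %||% "pfasmeta"
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, src, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a paired reference as two TSVs sharing one sample header
#' @param ref a `paired_reference`.
#' @param expression_path,metabolite_path output paths.
#' @return invisibly, the two paths.
#' @export
write_paired_reference <- function(ref, expression_path, metabolite_path) {
  write_tsv(data.frame(gene = rownames(ref$expression), ref$expression,
                       check.names = FALSE), expression_path)
  write_tsv(data.frame(metabolite = rownames(ref$metabolites),
                       ref$metabolites, check.names = FALSE), metabolite_path)
  invisible(c(expression_path, metabolite_path))
}

#' Read a paired reference from two TSVs
#' @param expression_path,metabolite_path paths written by
#'   [write_paired_reference()] (first column gene / metabolite, remaining
#'   columns identically ordered samples).
#' @return a `paired_reference` (without a truth map).
#' @export
read_paired_reference <- function(expression_path, metabolite_path) {
  e <- read_tsv(expression_path)
  m <- read_tsv(metabolite_path)
  expr <- as.matrix(e[, -1, drop = FALSE]); rownames(expr) <- e[[1]]
  met <- as.matrix(m[, -1, drop = FALSE]); rownames(met) <- m[[1]]
  if (!identical(colnames(expr), colnames(met)))
    stop2("expression and metabolite tables must share an identical, ",
          "identically ordered sample header")
  structure(list(expression = expr, metabolites = met, truth = NULL),
            class = "paired_reference")
}
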