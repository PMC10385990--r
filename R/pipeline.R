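#' Build and validate a pipeline configuration
#'
#' One object drives a full run. Inputs can be in-memory objects (a
#' `synthetic_study`, `gene_set_collection`, `paired_reference`) or paths
#' (study directory, GMT file, paired-reference TSVs); paths are validated
#' here, before any stage runs. Every numeric key mirrors a CLI flag of the
#' command-line driver (`inst/cli/pfasmeta.R`); on conflict the CLI wins.
#' On-disk configurations are JSON documents with the same keys, read with
#' [read_pipeline_config()].
#'
#' @param study a `synthetic_study` (or `NULL`).
#' @param study_dir directory written by [write_study()] (or `NULL`).
#' @param sim a [simulation_config()] to simulate a study from (or `NULL`).
#'   Exactly one of `study`, `study_dir`, `sim` must be given.
#' @param gene_sets a `gene_set_collection`, or `NULL`.
#' @param gmt GMT path (alternative to `gene_sets`).
#' @param paired_reference a `paired_reference`, or `NULL`.
#' @param expression_tsv,metabolite_tsv paired-reference paths (alternative
#'   to `paired_reference`).
#' @param stages character vector of optional stages to run, a subset of
#'   `c("correlate", "integrate", "gsea", "metabolites")`; signatures and QC
#'   always run.
#' @param min_overlap,z_hi,z_lo,sd_cut,min_species,n_perm,k,evalue_cutoff
#'   stage parameters (see the respective stage functions).
#' @param metabolite_species species whose contrasts enter metabolite
#'   prediction (`NULL` = all; the original analysis restricted this stage
#'   to the reference species).
#' @param collapse ortholog many-to-one collapse rule, see
#'   [map_signature_to_reference()].
#' @param seed integer run seed; all stage seeds derive from it.
#' @param output_dir directory for result TSVs and the run manifest
#'   (`NULL` = in-memory only).
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(study = NULL, study_dir = NULL, sim = NULL,
                            gene_sets = NULL, gmt = NULL,
                            paired_reference = NULL, expression_tsv = NULL,
                            metabolite_tsv = NULL,
                            stages = c("correlate", "integrate", "gsea",
                                       "metabolites"),
                            min_overlap = 100, z_hi = 10, z_lo = 5,
                            sd_cut = 10, min_species = 6, n_perm = 1000,
                            k = 100, evalue_cutoff = 1e-5,
                            metabolite_species = NULL,
                            collapse = "max_abs", seed = 1,
                            output_dir = NULL) {
  n_src <- sum(!is.null(study), !is.null(study_dir), !is.null(sim))
  if (n_src != 1)
    stop2("exactly one of study, study_dir or sim must be supplied")
  stages <- if (length(stages))
    match.arg(stages, c("correlate", "integrate", "gsea", "metabolites"),
              several.ok = TRUE)
  else character(0)
  for (p in c(study_dir, gmt, expression_tsv, metabolite_tsv))
    if (!is.null(p) && !file.exists(p)) stop2("path does not exist: ", p)
  if ("gsea" %in% stages && is.null(gene_sets) && is.null(gmt))
    stop2("gsea stage requires gene_sets or a gmt path")
  if ("metabolites" %in% stages && is.null(paired_reference) &&
      (is.null(expression_tsv) || is.null(metabolite_tsv)))
    stop2("metabolites stage requires a paired_reference or both ",
          "expression_tsv and metabolite_tsv")
  stopifnot(min_overlap >= 3, n_perm >= 100, k >= 5, evalue_cutoff > 0,
            z_hi >= z_lo, z_lo > 0, sd_cut > 0, min_species >= 1)
  structure(list(study = study, study_dir = study_dir, sim = sim,
                 gene_sets = gene_sets, gmt = gmt,
                 paired_reference = paired_reference,
                 expression_tsv = expression_tsv,
                 metabolite_tsv = metabolite_tsv, stages = stages,
                 min_overlap = min_overlap, z_hi = z_hi, z_lo = z_lo,
                 sd_cut = sd_cut, min_species = min_species,
                 n_perm = n_perm, k = k, evalue_cutoff = evalue_cutoff,
                 metabolite_species = metabolite_species,
                 collapse = collapse, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON document
#' @param path JSON file whose keys mirror the [pipeline_config()] arguments.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  keys <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipeline_config, keys)
}

#' Per-contrast differential-expression QC
#'
#' The corpus admission check: every contrast should yield more than 10
#' genes differentially expressed at p <= 0.05; contrasts at or below that
#' count are flagged.
#'
#' @param de_tables named list of `de_table`s (one per contrast).
#' @return data frame: contrast_id, n_significant, flagged.
#' @export
qc_report <- function(de_tables) {
  n_sig <- vapply(de_tables, function(de)
    sum(de$pvalue <= 0.05, na.rm = TRUE), integer(1))
  data.frame(contrast_id = names(de_tables), n_significant = unname(n_sig),
             flagged = unname(n_sig) <= 10L,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Run one stage with failure bookkeeping: on error, abort naming the stage
# and leave a FAILED_<stage> marker next to any partial outputs.
.run_stage <- function(name, output_dir, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(output_dir))
      writeLines(conditionMessage(e),
                 file.path(output_dir, paste0("FAILED_", name)))
    stop2("stage '", name, "' failed: ", conditionMessage(e))
  })
}

.log_stage <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run the full cross-species meta-analysis pipeline
#'
#' Executes, in dependency order: study acquisition (simulate or load),
#' per-contrast differential expression and QC, signature computation and
#' ortholog mapping to the reference gene space, signature-matrix assembly,
#' then the enabled optional stages (pairwise correlation, species-balanced
#' Stouffer gene integration, permutation GSEA with NES integration, and
#' metabolite prediction). Identical configuration and seed give identical
#' outputs. If `output_dir` is set, every result table is written as TSV
#' with a '#'-prefixed parameter header, plus a JSON run manifest with the
#' seed and a parameter hash.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list: `signature_matrix`, `qc`,
#'   `mapping_report`, and (as enabled) `correlation`, `integrated_genes`,
#'   `enrichment` (per-contrast long table), `integrated_pathways`,
#'   `metabolite_predictions`, `integrated_metabolites`, plus `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop2("config must be a pipeline_config (see pipeline_config())")
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  result <- list()

  study <- .run_stage("study", out_dir, {
    if (!is.null(config$study)) config$study
    else if (!is.null(config$study_dir)) read_study(config$study_dir)
    else generate_multispecies_study(config$sim)
  })
  .log_stage("study: ", length(study$contrasts), " contrasts, ",
             length(unique(study$metadata$species)), " species")

  sigs <- .run_stage("signature", out_dir, {
    de_tables <- list()
    sig_list <- list()
    reports <- list()
    for (i in seq_len(nrow(study$metadata))) {
      md <- study$metadata[i, ]
      cid <- md$contrast_id
      ct <- study$contrasts[[cid]]
      de <- compute_differential_expression(ct$counts, ct$groups)
      de_tables[[cid]] <- de
      sig <- signature_from_de(de, contrast_id = cid, species = md$species,
                               tissue = md$tissue, compound = md$compound)
      ortho <- study$orthologs[[md$species]]
      if (!is.null(ortho))
        sig <- map_signature_to_reference(sig, as_ortholog_table(ortho),
                                          collapse = config$collapse)
      reports[[cid]] <- data.frame(contrast_id = cid,
                                   attr(sig, "mapping_report") %||%
                                     data.frame(n_in = length(sig),
                                                n_mapped = length(sig),
                                                n_collapsed = 0L))
      sig_list[[cid]] <- sig
    }
    list(de = de_tables, sigs = sig_list,
         report = do.call(rbind, c(reports, make.row.names = FALSE)))
  })
  result$qc <- qc_report(sigs$de)
  result$mapping_report <- sigs$report
  m <- .run_stage("signature_matrix", out_dir,
                  build_signature_matrix(sigs$sigs))
  result$signature_matrix <- m
  .log_stage("signatures: ", nrow(m$scores), " reference genes")

  weights <- species_balanced_weights(m$metadata)

  if ("correlate" %in% config$stages) {
    result$correlation <- .run_stage("correlate", out_dir,
      pairwise_correlation(m, min_overlap = config$min_overlap))
  }
  if ("integrate" %in% config$stages) {
    result$integrated_genes <- .run_stage("integrate", out_dir,
      integrate_signature_matrix(m, weights = weights,
                                 min_species = config$min_species,
                                 z_hi = config$z_hi, z_lo = config$z_lo,
                                 sd_cut = config$sd_cut))
  }
  if ("gsea" %in% config$stages) {
    sets <- config$gene_sets %||% parse_gmt(config$gmt)
    res <- .run_stage("gsea", out_dir, {
      tabs <- lapply(seq_along(sigs$sigs), function(i)
        gsea_contrast(sigs$sigs[[i]], sets, n_perm = config$n_perm,
                      seed = child_seed(config$seed, i)))
      names(tabs) <- names(sigs$sigs)
      list(tables = tabs, integrated = integrate_pathways(tabs, weights))
    })
    result$enrichment <- do.call(rbind, c(lapply(names(res$tables), function(cid)
      data.frame(contrast_id = cid, res$tables[[cid]])),
      make.row.names = FALSE))
    result$integrated_pathways <- res$integrated
  }
  if ("metabolites" %in% config$stages) {
    res <- .run_stage("metabolites", out_dir, {
      ref <- config$paired_reference %||%
        read_paired_reference(config$expression_tsv, config$metabolite_tsv)
      model <- fit_metabolite_model(ref, k = config$k)
      keep <- if (is.null(config$metabolite_species)) m$metadata$contrast_id
        else m$metadata$contrast_id[m$metadata$species %in%
                                      config$metabolite_species]
      if (!length(keep)) stop2("no contrast matches metabolite_species")
      preds <- lapply(keep, function(cid)
        predict_metabolites(sigs$sigs[[cid]], model, n_perm = config$n_perm,
                            seed = child_seed(config$seed,
                                              100000 + match(cid, keep))))
      names(preds) <- keep
      w_sub <- species_balanced_weights(
        m$metadata[m$metadata$contrast_id %in% keep, ])
      list(predictions = preds,
           integrated = integrate_metabolites(preds, w_sub))
    })
    result$metabolite_predictions <- do.call(rbind,
      c(lapply(names(res$predictions), function(cid)
        data.frame(contrast_id = cid, res$predictions[[cid]])),
        make.row.names = FALSE))
    result$integrated_metabolites <- res$integrated
  }

  params <- config[c("min_overlap", "z_hi", "z_lo", "sd_cut", "min_species",
                     "n_perm", "k", "evalue_cutoff", "collapse", "seed",
                     "stages")]
  if (!is.null(out_dir)) {
    write_signature_matrix(m, file.path(out_dir, "signature_matrix.tsv"))
    write_tsv(result$qc, file.path(out_dir, "qc.tsv"), params["seed"])
    write_tsv(result$mapping_report,
              file.path(out_dir, "mapping_report.tsv"))
    if (!is.null(result$correlation))
      write_tsv(as.data.frame(result$correlation),
                file.path(out_dir, "correlation.tsv"),
                params[c("min_overlap", "seed")])
    if (!is.null(result$integrated_genes))
      write_tsv(result$integrated_genes,
                file.path(out_dir, "integrated_genes.tsv"),
                params[c("z_hi", "z_lo", "sd_cut", "min_species", "seed")])
    if (!is.null(result$enrichment))
      write_tsv(result$enrichment, file.path(out_dir, "enrichment.tsv"),
                params[c("n_perm", "seed")])
    if (!is.null(result$integrated_pathways))
      write_tsv(result$integrated_pathways,
                file.path(out_dir, "integrated_pathways.tsv"),
                params[c("n_perm", "seed")])
    if (!is.null(result$metabolite_predictions))
      write_tsv(result$metabolite_predictions,
                file.path(out_dir, "metabolite_predictions.tsv"),
                params[c("n_perm", "k", "seed")])
    if (!is.null(result$integrated_metabolites))
      write_tsv(result$integrated_metabolites,
                file.path(out_dir, "integrated_metabolites.tsv"),
                params[c("n_perm", "k", "seed")])
  }
  manifest <- list(package = "pfasmeta",
                   version = as.character(utils::packageVersion("pfasmeta")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed, parameters = params)
  pj <- tempfile(fileext = ".json")
  jsonlite::write_json(params, pj, auto_unbox = TRUE)
  manifest$parameter_hash <- unname(tools::md5sum(pj))
  unlink(pj)
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  result$manifest <- manifest
  structure(result, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result with tables:",
      paste(setdiff(names(x), "manifest"), collapse = ", "), "\n")
  invisible(x)
}
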