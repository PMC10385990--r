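#' Load an ortholog mapping table
#'
#' @param path TSV with at least three columns: source gene, target
#'   (reference) gene, and a nonnegative numeric confidence score. A header
#'   row is detected automatically. Duplicated (source, target) pairs are
#'   collapsed to one row (keeping the maximum score) with a warning.
#' @return an `ortholog_table` data frame with columns `source_gene`,
#'   `target_gene`, `score`.
#' @export
load_ortholog_table <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (!length(fields)) stop2("empty ortholog table: ", path)
  short <- lengths(fields) < 3L
  if (any(short))
    stop2("ortholog table needs >= 3 columns; line ", lineno[which(short)[1]],
          " of ", path, " has ", lengths(fields)[which(short)[1]])
  first_score <- suppressWarnings(as.numeric(fields[[1]][3]))
  if (is.na(first_score)) {  # header row
    fields <- fields[-1]
    lineno <- lineno[-1]
    if (!length(fields)) stop2("ortholog table has a header but no rows: ", path)
  }
  score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(score))
    stop2("non-numeric score in ortholog table, line ",
          lineno[which(is.na(score))[1]], " of ", path)
  tab <- data.frame(source_gene = vapply(fields, `[`, "", 1L),
                    target_gene = vapply(fields, `[`, "", 2L),
                    score = score, stringsAsFactors = FALSE)
  as_ortholog_table(tab)
}

#' Validate a data frame as an ortholog table
#'
#' Checks columns and score validity, and collapses duplicated
#' (source, target) pairs (keeping the maximum score) with a warning.
#'
#' @param tab data frame with columns `source_gene`, `target_gene`, `score`.
#' @return an `ortholog_table` data frame.
#' @export
as_ortholog_table <- function(tab) {
  if (!all(c("source_gene", "target_gene", "score") %in% names(tab)))
    stop2("ortholog table must have columns source_gene, target_gene, score")
  if (any(!is.finite(tab$score)) || any(tab$score < 0))
    stop2("ortholog scores must be finite and nonnegative")
  key <- paste(tab$source_gene, tab$target_gene, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicated (source, target) pairs collapsed to one entry",
            call. = FALSE)
    o <- order(key, -tab$score)
    tab <- tab[o, ][!duplicated(key[o]), ]
    rownames(tab) <- NULL
  }
  structure(tab[, c("source_gene", "target_gene", "score")],
            class = c("ortholog_table", "data.frame"))
}

#' Read pairwise-similarity hits in BLAST tabular (outfmt 6) layout
#'
#' Uses columns 1, 2, 11 and 12 (query id, subject id, e-value, bit score).
#'
#' @param path BLAST tabular file.
#' @return a `hit_table` data frame with columns `query_id`, `subject_id`,
#'   `evalue`, `bitscore`.
#' @export
read_blast_hits <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop2("expected >= 12 tab-separated columns (outfmt 6)")
  hit_table(df[[1]], df[[2]], evalue = df[[11]], bitscore = df[[12]])
}

#' Construct a hit table
#' @param query_id,subject_id sequence identifiers.
#' @param evalue nonnegative e-values.
#' @param bitscore finite bit scores.
#' @return a `hit_table` data frame.
#' @export
hit_table <- function(query_id, subject_id, evalue, bitscore) {
  if (any(evalue < 0)) stop2("evalue must be >= 0")
  if (any(!is.finite(bitscore))) stop2("bitscore must be finite")
  structure(data.frame(query_id = as.character(query_id),
                       subject_id = as.character(subject_id),
                       evalue = as.numeric(evalue),
                       bitscore = as.numeric(bitscore),
                       stringsAsFactors = FALSE),
            class = c("hit_table", "data.frame"))
}

# Best hit per query: max bitscore, ties by min evalue then lexicographic
# subject id. Returns a named character vector query -> subject, plus scores.
.best_hits <- function(hits) {
  o <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  h <- hits[o, ]
  h <- h[!duplicated(h$query_id), ]
  list(best = stats::setNames(h$subject_id, h$query_id),
       bitscore = stats::setNames(h$bitscore, h$query_id))
}

#' Reciprocal (bidirectional) best hits from forward and reverse searches
#'
#' After discarding hits with e-value above `evalue_cutoff`, a pair (a, b)
#' is an ortholog call iff b is a's best forward hit and a is b's best
#' reverse hit, where "best" means maximum bit score, ties broken by minimum
#' e-value and then lexicographically smallest subject id. The emitted
#' confidence score is the mean of the two bit scores. The result is 1:1 by
#' construction.
#'
#' @param forward,reverse `hit_table`s of the two search directions.
#' @param evalue_cutoff e-value filter (default 1e-5).
#' @return an `ortholog_table` (source = forward query space).
#' @export
bbh_from_hits <- function(forward, reverse, evalue_cutoff = 1e-5) {
  f <- forward[forward$evalue <= evalue_cutoff, ]
  r <- reverse[reverse$evalue <= evalue_cutoff, ]
  if (!nrow(f) || !nrow(r))
    stop2("no hits remain after e-value filtering at ", evalue_cutoff)
  bf <- .best_hits(f)
  br <- .best_hits(r)
  q <- names(bf$best)
  s <- unname(bf$best)
  mutual <- !is.na(br$best[s]) & br$best[s] == q
  if (!any(mutual))
    return(as_ortholog_table(data.frame(source_gene = character(),
                                        target_gene = character(),
                                        score = numeric())))
  as_ortholog_table(data.frame(
    source_gene = q[mutual],
    target_gene = s[mutual],
    score = (bf$bitscore[q[mutual]] + br$bitscore[s[mutual]]) / 2,
    stringsAsFactors = FALSE))
}

#' Compose two ortholog tables into a two-hop mapping
#'
#' For species with no direct mapping to the reference (mapped first to an
#' intermediate species), composition joins `ab` (source -> intermediate)
#' with `bc` (intermediate -> reference); the composed confidence is the
#' minimum of the two hop scores (conservative). Multiple composed routes to
#' the same (source, target) pair keep the best composed score.
#'
#' @param ab,bc `ortholog_table`s to compose.
#' @return an `ortholog_table` from `ab`'s source space to `bc`'s target
#'   space.
#' @export
compose_ortholog_tables <- function(ab, bc) {
  m <- merge(ab, bc, by.x = "target_gene", by.y = "source_gene",
             suffixes = c("_ab", "_bc"))
  if (!nrow(m)) stop2("composition is empty: no shared intermediate genes")
  as_ortholog_table(data.frame(source_gene = m$source_gene,
                               target_gene = m$target_gene_bc,
                               score = pmin(m$score_ab, m$score_bc),
                               stringsAsFactors = FALSE))
}

#' Map a species-level signature into the reference gene space
#'
#' Each source gene is converted to its most likely reference ortholog: the
#' highest-scoring target in the table (ties broken by lexicographically
#' smallest target id). When several source genes land on one target, the
#' retained score is, by default, the one with maximum |s| (ties resolved
#' toward the more positive value), preserving the strongest evidence;
#' `collapse = "mean"` averages instead. Unmapped genes are dropped and
#' counted in the `mapping_report` attribute of the result.
#'
#' @param sig a [contrast_signature()] in source-species identifiers.
#' @param table an `ortholog_table`.
#' @param collapse many-to-one collapse rule, `"max_abs"` (default) or
#'   `"mean"`.
#' @return a [contrast_signature()] over reference gene identifiers, with a
#'   `mapping_report` attribute (data frame: n_in, n_mapped, n_collapsed).
#' @export
map_signature_to_reference <- function(sig, table,
                                       collapse = c("max_abs", "mean")) {
  collapse <- match.arg(collapse)
  if (!nrow(table)) stop2("ortholog table is empty")
  # most likely target per source: max score, ties -> smallest target id
  o <- order(table$source_gene, -table$score, table$target_gene)
  t1 <- table[o, ]
  t1 <- t1[!duplicated(t1$source_gene), ]
  target_of <- stats::setNames(t1$target_gene, t1$source_gene)

  src <- names(sig)
  mapped <- !is.na(target_of[src])
  if (!any(mapped)) stop2("no signature gene could be mapped to the reference")
  tgt <- unname(target_of[src[mapped]])
  s <- as.numeric(sig)[mapped]
  if (collapse == "max_abs") {
    o2 <- order(tgt, -abs(s), -s)
    keep <- !duplicated(tgt[o2])
    out <- stats::setNames(s[o2][keep], tgt[o2][keep])
  } else {
    out0 <- tapply(s, tgt, mean)
    out <- stats::setNames(as.numeric(out0), names(out0))
  }
  res <- contrast_signature(out, contrast_id = attr(sig, "contrast_id"),
                            species = attr(sig, "species"),
                            tissue = attr(sig, "tissue"),
                            compound = attr(sig, "compound"))
  attr(res, "mapping_report") <- data.frame(
    n_in = length(sig), n_mapped = sum(mapped),
    n_collapsed = sum(mapped) - length(out))
  res
}
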