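# Expression screening: presence/absence filtering of abundance tables and
# transcript-to-gene aggregation. Counts are RSEM-style expected counts and
# may be fractional; all comparisons are numeric.

#' Expression filter parameters
#'
#' The screen retains a row when strictly more than `min_samples` samples
#' have abundance strictly greater than `min_count` ("higher than 10 in
#' more than two samples" under the defaults: >10 in at least 3 samples).
#' Both thresholds are configurable because the inclusive reading is also
#' defensible.
#'
#' @param min_count abundance threshold (strict `>`), default 10.
#' @param min_samples sample-count threshold (strict `>`), default 2.
#' @return a `filter_params` list.
#' @export
filter_params <- function(min_count = 10, min_samples = 2L) {
  if (min_count < 0) stop("min_count must be >= 0")
  if (min_samples < 0) stop("min_samples must be >= 0")
  structure(list(min_count = min_count, min_samples = as.integer(min_samples)),
            class = "filter_params")
}

check_count_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("count matrix must be a numeric matrix")
  if (nrow(m) > 0L && is.null(rownames(m)))
    stop("count matrix must have row identifiers")
  if (anyDuplicated(rownames(m))) stop("count matrix row ids must be unique")
  if (any(m < 0)) stop("count matrix must be non-negative")
  invisible(m)
}

#' Filter a count matrix to expressed rows
#'
#' Retains rows where the number of samples with abundance
#' `> min_count` exceeds `min_samples`. Row order is preserved. The caller
#' slices the matrix to one population-by-condition group first (see
#' [run_pipeline()] for the per-group orchestration).
#'
#' @param m numeric count matrix, rows = transcripts or genes, cols = samples.
#' @param params a [filter_params].
#' @return the retained row subset of `m` (possibly 0 rows).
#' @export
filter_expressed <- function(m, params = filter_params()) {
  check_count_matrix(m)
  if (params$min_samples >= ncol(m))
    stop(sprintf("min_samples (%d) must be < number of samples (%d)",
                 params$min_samples, ncol(m)))
  keep <- rowSums(m > params$min_count) > params$min_samples
  m[keep, , drop = FALSE]
}

#' Aggregate transcript abundances to genes
#'
#' Sums member-transcript abundances per gene and sample ("abundances of
#' transcripts assigned to the same gene were combined together"). Column
#' mass is conserved.
#'
#' @param m transcript-level count matrix (rownames = transcript ids).
#' @param gene_models data.frame with columns `transcript_id`, `gene_id`
#'   covering every row of `m`.
#' @return gene-level count matrix (rownames = unique gene ids, in first-
#'   appearance order of the transcripts).
#' @export
aggregate_genes <- function(m, gene_models) {
  check_count_matrix(m)
  idx <- match(rownames(m), gene_models$transcript_id)
  orphans <- rownames(m)[is.na(idx)]
  if (length(orphans) > 0L)
    stop("transcript(s) missing from gene models: ",
         paste(utils::head(orphans, 10), collapse = ", "),
         if (length(orphans) > 10) sprintf(" (and %d more)", length(orphans) - 10) else "")
  gene <- gene_models$gene_id[idx]
  out <- rowsum(m, group = gene, reorder = FALSE)
  out[unique(gene), , drop = FALSE]
}

#' Expressed gene set for one population-by-condition group
#'
#' @param m gene-level count matrix for the labeled group.
#' @param params a [filter_params].
#' @param population,condition labels carried on the result.
#' @return a [candidate_set] labeled `"<population>:<condition>"`.
#' @export
expressed_set <- function(m, params = filter_params(), population, condition) {
  kept <- filter_expressed(m, params)
  candidate_set(rownames(kept), label = paste(population, condition, sep = ":"))
}

#' Read a transcript count table from TSV
#'
#' Layout: first column `transcript_id`, second `gene_id`, remaining columns
#' one per sample.
#'
#' @param path TSV path with header.
#' @return list with `counts` (matrix, rownames = transcript ids) and
#'   `gene_models` (data.frame transcript_id, gene_id).
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3L || names(df)[1L] != "transcript_id" || names(df)[2L] != "gene_id")
    stop("count table must start with columns transcript_id, gene_id")
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$transcript_id
  list(counts = m, gene_models = df[, 1:2])
}

#' Write a transcript count table to TSV
#'
#' @param counts transcript-level matrix.
#' @param gene_models transcript-to-gene data.frame.
#' @param path output path.
#' @export
write_count_table <- function(counts, gene_models, path) {
  idx <- match(rownames(counts), gene_models$transcript_id)
  df <- data.frame(transcript_id = rownames(counts),
                   gene_id = gene_models$gene_id[idx],
                   counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
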