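# Proteomic cross-validation: reduce an MS-identified protein list to
# plasma-membrane genes and intersect with the transcriptomic candidates.

#' Read an MS protein list from TSV
#'
#' Columns: `protein_id` (unique), `gene_symbol` (raw, may be unmapped),
#' `membrane_flag` (0/1: identified in the membrane fraction).
#'
#' @param path TSV path with header.
#' @return data.frame with those three columns.
#' @export
read_ms_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "gene_symbol", "membrane_flag")
  if (!all(need %in% names(df)))
    stop("MS list TSV needs columns protein_id, gene_symbol, membrane_flag")
  if (anyDuplicated(df$protein_id)) stop("MS protein ids must be unique")
  df$membrane_flag <- as.logical(df$membrane_flag)
  df[, need]
}

#' Reduce an MS protein list to plasma-membrane genes
#'
#' Keeps entries flagged as membrane-fraction identifications, maps their
#' gene symbols to canonical form, and retains those whose annotation
#' includes the plasma membrane. Unmapped and unannotated identifiers are
#' reported in attributes, never silently dropped.
#'
#' @param ms MS list data.frame (see [read_ms_list()]).
#' @param ann an [annotation_table].
#' @param map an [id_map].
#' @return a [candidate_set] of canonical gene symbols with attributes
#'   `unmapped` (raw symbols without a canonical match) and `unannotated`
#'   (mapped genes missing from `ann` or lacking plasma-membrane
#'   annotation).
#' @export
filter_membrane_proteins <- function(ms, ann, map) {
  flagged <- ms[ms$membrane_flag, , drop = FALSE]
  canon <- normalize_id(flagged$gene_symbol, map)
  unmapped <- unique(names(canon)[is.na(canon)])
  genes <- unique(canon[!is.na(canon)])
  idx <- match(genes, ann$gene_id)
  has_pm <- !is.na(idx) & vapply(seq_along(genes), function(i) {
    if (is.na(idx[i])) FALSE else "plasma_membrane" %in% ann$compartments[[idx[i]]]
  }, logical(1))
  out <- candidate_set(genes[has_pm], label = "proteomic plasma membrane")
  attr(out, "unmapped") <- unmapped
  attr(out, "unannotated") <- genes[!has_pm]
  out
}

#' Cross-validate transcriptomic and proteomic candidate sets
#'
#' The final candidates are the intersection of the two arms (symmetric up
#' to labels); the molecular-function histogram is computed over the final
#' set; provenance records the input and intersection sizes.
#'
#' @param transcriptomic,proteomic canonicalized [candidate_set]s.
#' @param ann an [annotation_table] for the function histogram.
#' @return a `cross_validation_result`: list with `final_candidates`,
#'   `function_histogram`, `provenance` (named sizes).
#' @export
cross_validate <- function(transcriptomic, proteomic, ann) {
  final <- candidate_set(intersect(transcriptomic$gene_ids, proteomic$gene_ids),
                         label = "cross-validated")
  structure(list(
    final_candidates = final,
    function_histogram = categorize_functions(final, ann),
    provenance = c(n_transcriptomic = length(transcriptomic$gene_ids),
                   n_proteomic = length(proteomic$gene_ids),
                   n_final = length(final$gene_ids))),
    class = "cross_validation_result")
}

#' @export
print.cross_validation_result <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("cross-validation: %d transcriptomic x %d proteomic -> %d final\n",
              p["n_transcriptomic"], p["n_proteomic"], p["n_final"]))
  h <- x$function_histogram
  h <- h[h$count > 0, , drop = FALSE]
  if (nrow(h) > 0L)
    cat("  functions:", paste(sprintf("%s=%d", h$class, h$count), collapse = ", "), "\n")
  invisible(x)
}
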