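# The composite membranome screen: per-protein candidate decision, set
# algebra over labeled gene sets, plasma-membrane annotation screen,
# population-specificity screen, and molecular-function categorization.

#' Labeled candidate set
#'
#' The set-algebra currency of the pipeline: a label plus a set of gene
#' identifiers (duplicates removed, order normalized).
#'
#' @param gene_ids character vector of gene identifiers.
#' @param label set label.
#' @return a `candidate_set`.
#' @export
candidate_set <- function(gene_ids, label = "") {
  structure(list(label = label,
                 gene_ids = sort(unique(as.character(gene_ids)))),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set '%s': %d gene(s)\n", x$label, length(x$gene_ids)))
  if (length(x$gene_ids) > 0L)
    cat("  ", paste(utils::head(x$gene_ids, 10), collapse = ", "),
        if (length(x$gene_ids) > 10) "..." else "", "\n")
  invisible(x)
}

#' @export
length.candidate_set <- function(x) length(x$gene_ids)

MEMBRANOME_FILTERS <- c("no_signal_peptide", "no_tm", "has_nls", "has_nes",
                        "has_er_retention", "has_mtp")

#' Membranome decision rule configuration
#'
#' The screen keeps proteins with a signal peptide and at least one TM
#' segment and none of the enabled exclusion signals. All four exclusions
#' (NLS, NES, ER retention, MTP) are enabled by default and individually
#' toggleable.
#'
#' @param exclude_nls,exclude_nes,exclude_er_retention,exclude_mtp logical
#'   toggles.
#' @return a `membranome_rules` list.
#' @export
membranome_rules <- function(exclude_nls = TRUE, exclude_nes = TRUE,
                             exclude_er_retention = TRUE, exclude_mtp = TRUE) {
  as.list(environment())
}

#' Per-protein membranome decision
#'
#' Candidate iff the topology report shows a signal peptide AND at least
#' one transmembrane segment AND none of the enabled exclusion signals.
#' `failed_filters` lists every violated clause, not just the first.
#'
#' @param report a `topology_report`.
#' @param rules a [membranome_rules] list.
#' @return list with `protein_id`, `is_candidate`, `failed_filters`.
#' @export
decide_membranome <- function(report, rules = membranome_rules()) {
  failed <- character(0)
  if (!report$signal_peptide$present) failed <- c(failed, "no_signal_peptide")
  if (nrow(report$tm_segments) == 0L) failed <- c(failed, "no_tm")
  if (rules$exclude_nls && report_has(report, NLS_KINDS))
    failed <- c(failed, "has_nls")
  if (rules$exclude_nes && report_has(report, "NES"))
    failed <- c(failed, "has_nes")
  if (rules$exclude_er_retention && report_has(report, ER_KINDS))
    failed <- c(failed, "has_er_retention")
  if (rules$exclude_mtp && report_has(report, "MTP"))
    failed <- c(failed, "has_mtp")
  list(protein_id = report$protein_id,
       is_candidate = length(failed) == 0L,
       failed_filters = failed)
}

#' Intersect candidate sets across conditions
#'
#' @param sets list of at least two [candidate_set]s.
#' @return a [candidate_set] holding the intersection, labeled by
#'   concatenating the input labels.
#' @export
condition_intersection <- function(sets) {
  if (length(sets) < 2L) stop("need at least two sets to intersect")
  ids <- Reduce(intersect, lapply(sets, function(s) s$gene_ids))
  candidate_set(ids, label = paste(vapply(sets, function(s) s$label,
                                          character(1)), collapse = " & "))
}

#' Annotation table constructor / reader
#'
#' Maps each gene to a set of subcellular compartments
#' (plasma_membrane, ER, nucleus, mitochondrion, cytosol, secreted, other)
#' and a molecular-function class (receptor, transporter, enzyme,
#' ion_channel, undefined). Stands in for the screening databases.
#'
#' @param gene_id character vector.
#' @param compartments list of character vectors (one per gene, each
#'   non-empty) or a semicolon-separated character vector.
#' @param molecular_function character vector (default "undefined").
#' @return an `annotation_table` data.frame with columns gene_id,
#'   compartments (list column), molecular_function.
#' @export
annotation_table <- function(gene_id, compartments,
                             molecular_function = "undefined") {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("annotation gene ids must be unique")
  if (is.character(compartments))
    compartments <- strsplit(compartments, ";", fixed = TRUE)
  if (any(lengths(compartments) == 0L))
    stop("every annotated gene needs at least one compartment")
  df <- data.frame(gene_id = gene_id, stringsAsFactors = FALSE)
  df$compartments <- compartments
  df$molecular_function <- rep_len(as.character(molecular_function),
                                   length(gene_id))
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' @rdname annotation_table
#' @param path TSV with header columns gene_id, compartments
#'   (semicolon-separated), molecular_function.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  annotation_table(df$gene_id, df$compartments, df$molecular_function)
}

#' @rdname annotation_table
#' @param ann an `annotation_table` to serialize.
#' @export
write_annotation_table <- function(ann, path) {
  df <- data.frame(gene_id = ann$gene_id,
                   compartments = vapply(ann$compartments, paste,
                                         character(1), collapse = ";"),
                   molecular_function = ann$molecular_function,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Screen candidates for plasma-membrane annotation
#'
#' Retains genes whose annotated compartments include `plasma_membrane`.
#' Genes absent from the annotation table are excluded and reported in the
#' `unannotated` attribute — never silently dropped.
#'
#' @param cands a [candidate_set].
#' @param ann an [annotation_table].
#' @return a [candidate_set] (subset of `cands`) with attributes
#'   `unannotated` (ids missing from `ann`) and `not_pm` (annotated but
#'   not plasma-membrane).
#' @export
plasma_membrane_screen <- function(cands, ann) {
  idx <- match(cands$gene_ids, ann$gene_id)
  unann <- cands$gene_ids[is.na(idx)]
  present <- cands$gene_ids[!is.na(idx)]
  has_pm <- vapply(ann$compartments[idx[!is.na(idx)]],
                   function(cp) "plasma_membrane" %in% cp, logical(1))
  out <- candidate_set(present[has_pm],
                       label = paste0(cands$label, " [plasma membrane]"))
  attr(out, "unannotated") <- unann
  attr(out, "not_pm") <- present[!has_pm]
  out
}

#' Population-specificity screen
#'
#' `mode = "specific"` (default): genes of `target` absent from every
#' other set (set difference against the union) — the reading under which
#' the retained candidates are population-specific. `mode = "shared"`:
#' genes of `target` also present in the union of the others. The mode is
#' recorded on the result.
#'
#' @param target a [candidate_set].
#' @param others non-empty list of [candidate_set]s.
#' @param mode `"specific"` or `"shared"`.
#' @return a [candidate_set] with attribute `mode`.
#' @export
specificity_screen <- function(target, others, mode = c("specific", "shared")) {
  mode <- match.arg(mode)
  if (length(others) == 0L) stop("specificity screen needs at least one comparison set")
  u <- unique(unlist(lapply(others, function(s) s$gene_ids)))
  ids <- if (mode == "specific") setdiff(target$gene_ids, u)
         else intersect(target$gene_ids, u)
  out <- candidate_set(ids, label = sprintf("%s [%s]", target$label, mode))
  attr(out, "mode") <- mode
  out
}

FUNCTION_CLASSES <- c("receptor", "transporter", "enzyme", "ion_channel",
                      "undefined")

#' Molecular-function histogram of a candidate set
#'
#' Counts and proportions per molecular-function class. Genes missing from
#' the annotation table, or annotated without a function, count as
#' `undefined`.
#'
#' @param cands a [candidate_set].
#' @param ann an [annotation_table].
#' @return data.frame with columns class, count, proportion (all five
#'   classes always present; zero rows sum handled as proportion 0).
#' @export
categorize_functions <- function(cands, ann) {
  fn <- ann$molecular_function[match(cands$gene_ids, ann$gene_id)]
  fn[is.na(fn) | !(fn %in% FUNCTION_CLASSES)] <- "undefined"
  counts <- table(factor(fn, levels = FUNCTION_CLASSES))
  total <- sum(counts)
  data.frame(class = FUNCTION_CLASSES,
             count = as.integer(counts),
             proportion = if (total > 0) as.numeric(counts) / total else
               rep(0, length(FUNCTION_CLASSES)),
             stringsAsFactors = FALSE)
}

#' Write / read a candidate set as one-column TSV
#'
#' The label travels in a `# label:` comment header.
#'
#' @param x a [candidate_set].
#' @param path file path.
#' @export
write_candidate_set <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label: %s", x$label), con)
  writeLines("gene_id", con)
  writeLines(x$gene_ids, con)
  invisible(path)
}

#' @rdname write_candidate_set
#' @export
read_candidate_set <- function(path) {
  lines <- readLines(path)
  lab <- sub("^# label:\\s*", "", lines[grepl("^# label:", lines)][1])
  body <- lines[!grepl("^#", lines)]
  body <- body[body != "gene_id" & nzchar(body)]
  candidate_set(body, label = if (is.na(lab)) "" else lab)
}
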