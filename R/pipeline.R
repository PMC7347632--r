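# End-to-end orchestration of the candidate funnel: per-group expression
# screens, per-condition membranome decisions, condition intersection,
# plasma-membrane annotation screen, population-specificity screen, and
# proteomic cross-validation, with a per-gene provenance ledger.

#' Run the membranome discovery pipeline
#'
#' Executes the full candidate funnel on a simulated study object, a
#' YAML config file, or an input directory written by
#' [write_simulation()]. Stage sizes along the funnel are asserted to be
#' non-increasing; a violation aborts with a diagnostic. Every input gene
#' is accounted for in the provenance ledger: either its elimination
#' stage and reason or final-candidate status.
#'
#' @param x a `membranome_sim` from [simulate_study()], a path to a YAML
#'   config (fields: `seed`, `simulate` + `sim:` options, or `input_dir`;
#'   optional `filter:`, `specificity_mode`, `outdir`), or a path to an
#'   input directory.
#' @param filter a [filter_params]; per-group the sample threshold is
#'   capped at (group size - 1) so small reference groups remain
#'   filterable.
#' @param topo a [topology_params].
#' @param rules a [membranome_rules].
#' @param target_population population whose membranome is screened
#'   (default `"PW1"`).
#' @param specificity_mode `"specific"` (set difference, default) or
#'   `"shared"`.
#' @param filter_mode `"group"` (default: filter each population-by-
#'   condition group on its own samples) or `"joint"` (additionally
#'   require the joint filter over all samples, the whole-study reading).
#' @param ... passed through between methods.
#' @return a `pipeline_report`: list with `funnel` (stage sizes, in
#'   funnel order), `sets` (the candidate sets of every stage),
#'   `decisions`, `provenance` (per-gene ledger), `function_histogram`,
#'   `config`, `seed`, `timestamp`, `elapsed`.
#' @export
run_pipeline <- function(x, ...) UseMethod("run_pipeline")

#' @rdname run_pipeline
#' @export
run_pipeline.membranome_sim <- function(x, filter = filter_params(),
                                        topo = topology_params(),
                                        rules = membranome_rules(),
                                        target_population = "PW1",
                                        specificity_mode = "specific",
                                        filter_mode = "group", ...) {
  run_pipeline_core(counts = x$expression$counts,
                    gene_models = x$expression$gene_models,
                    sample_info = x$expression$sample_info,
                    proteins = x$proteins, ann = x$annotation, ms = x$ms,
                    idmap = x$idmap, filter = filter, topo = topo,
                    rules = rules, target_population = target_population,
                    specificity_mode = specificity_mode,
                    filter_mode = filter_mode, seed = x$config$seed)
}

#' @rdname run_pipeline
#' @export
run_pipeline.character <- function(x, ...) {
  if (dir.exists(x)) return(run_pipeline_dir(x, ...))
  if (!file.exists(x)) stop("no such config file or directory: ", x)
  cfg <- yaml::read_yaml(x)
  extra <- list(...)
  filter <- do.call(filter_params, cfg$filter %||% list())
  args <- list(filter = filter,
               target_population = cfg$target_population %||% "PW1",
               specificity_mode = cfg$specificity_mode %||% "specific",
               filter_mode = cfg$filter_mode %||% "group")
  if (isTRUE(cfg$simulate)) {
    if (is.null(cfg$seed)) stop("config field missing: seed")
    sim_args <- cfg$sim %||% list()
    sim_args$seed <- cfg$seed
    sim <- simulate_study(do.call(sim_config, sim_args))
    if (!is.null(cfg$outdir)) write_simulation(sim, cfg$outdir)
    report <- do.call(run_pipeline, c(list(sim), args, extra))
  } else {
    if (is.null(cfg$input_dir)) stop("config field missing: input_dir")
    report <- do.call(run_pipeline_dir, c(list(cfg$input_dir), args, extra))
  }
  if (!is.null(cfg$outdir)) write_pipeline_report(report, cfg$outdir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_pipeline_dir <- function(dir, ...) {
  si_path <- file.path(dir, "sample_info.tsv")
  if (!file.exists(si_path)) stop("missing input: ", si_path)
  sample_info <- utils::read.delim(si_path, stringsAsFactors = FALSE)
  groups <- unique(sample_info[, c("population", "condition")])
  counts <- list(); gene_models <- NULL
  for (i in seq_len(nrow(groups))) {
    key <- paste(groups$population[i], groups$condition[i], sep = ":")
    path <- file.path(dir, sprintf("counts_%s.tsv", gsub(":", "_", key)))
    if (!file.exists(path)) stop("missing input: ", path)
    ct <- read_count_table(path)
    counts[[key]] <- ct$counts
    gene_models <- ct$gene_models
  }
  for (f in c("proteins.fasta", "annotation.tsv", "ms_list.tsv", "id_map.tsv"))
    if (!file.exists(file.path(dir, f))) stop("missing input: ", file.path(dir, f))
  run_pipeline_core(counts = counts, gene_models = gene_models,
                    sample_info = sample_info,
                    proteins = read_fasta(file.path(dir, "proteins.fasta"), "aa"),
                    ann = read_annotation_table(file.path(dir, "annotation.tsv")),
                    ms = read_ms_list(file.path(dir, "ms_list.tsv")),
                    idmap = read_id_map(file.path(dir, "id_map.tsv")), ...)
}

run_pipeline_core <- function(counts, gene_models, sample_info, proteins,
                              ann, ms, idmap, filter = filter_params(),
                              topo = topology_params(),
                              rules = membranome_rules(),
                              target_population = "PW1",
                              specificity_mode = "specific",
                              filter_mode = "group", seed = NA_integer_) {
  t0 <- Sys.time()
  n_total_samples <- sum(vapply(counts, ncol, integer(1)))
  if (filter$min_samples >= n_total_samples)
    stop(sprintf("min_samples (%d) must be < total number of samples (%d)",
                 filter$min_samples, n_total_samples))
  keys <- names(counts)
  pops <- sub(":.*$", "", keys)
  if (!any(pops == target_population))
    stop("target population not present in count tables: ", target_population)

  # stage 1: per-group gene aggregation + expression filter
  gene_mats <- lapply(counts, aggregate_genes, gene_models = gene_models)
  joint_pass <- NULL
  if (filter_mode == "joint") {
    jm <- do.call(cbind, gene_mats)
    joint_pass <- rownames(filter_expressed(jm, filter))
  }
  expressed <- list()
  for (key in keys) {
    grp_filter <- filter_params(filter$min_count,
                                min(filter$min_samples,
                                    ncol(gene_mats[[key]]) - 1L))
    es <- expressed_set(gene_mats[[key]], grp_filter,
                        population = sub(":.*$", "", key),
                        condition = sub("^.*:", "", key))
    if (!is.null(joint_pass))
      es <- candidate_set(intersect(es$gene_ids, joint_pass), label = es$label)
    expressed[[key]] <- es
  }
  all_genes <- sort(unique(gene_models$gene_id))

  # stage 2: topology on every gene expressed anywhere
  union_expressed <- sort(unique(unlist(lapply(expressed, `[[`, "gene_ids"))))
  seq_avail <- union_expressed[union_expressed %in% names(proteins)]
  reports <- build_topology_reports(
    seq_set(unclass(proteins)[seq_avail], seq_avail, "aa"), topo)
  decisions <- lapply(reports, decide_membranome, rules = rules)
  candidate_genes <- names(decisions)[vapply(decisions, `[[`, logical(1),
                                             "is_candidate")]

  # stage 3: per-condition membranome of the target population
  target_keys <- keys[pops == target_population]
  if (length(target_keys) < 1L) stop("no target-population groups")
  membranomes <- lapply(target_keys, function(key)
    candidate_set(intersect(expressed[[key]]$gene_ids, candidate_genes),
                  label = paste0(key, " membranome")))
  names(membranomes) <- target_keys

  # stage 4: condition intersection (condition-insensitive candidates)
  cond_insensitive <- if (length(membranomes) >= 2L)
    condition_intersection(membranomes) else membranomes[[1L]]

  # stage 5: plasma-membrane annotation screen
  pm_screened <- plasma_membrane_screen(cond_insensitive, ann)

  # stage 6: reference-population membranomes + specificity screen
  ref_pops <- unique(pops[pops != target_population])
  others <- lapply(ref_pops, function(p) {
    ids <- unique(unlist(lapply(keys[pops == p],
                                function(k) expressed[[k]]$gene_ids)))
    candidate_set(intersect(ids, candidate_genes),
                  label = paste0(p, " membranome"))
  })
  specific <- if (length(others) > 0L)
    specificity_screen(pm_screened, others, specificity_mode)
  else pm_screened

  # stage 7: proteomic arm + cross-validation
  proteomic_pm <- filter_membrane_proteins(ms, ann, idmap)
  xval <- cross_validate(specific, proteomic_pm, ann)
  final <- xval$final_candidates

  funnel <- c(setNames(vapply(expressed, length, integer(1)),
                       paste0("expressed ", keys)),
              setNames(vapply(membranomes, length, integer(1)),
                       paste0("membranome ", target_keys)),
              "condition-insensitive" = length(cond_insensitive),
              "plasma-membrane annotated" = length(pm_screened),
              "population-specific" = length(specific),
              "proteomic membrane proteins" = sum(ms$membrane_flag),
              "proteomic plasma-membrane" = length(proteomic_pm),
              "cross-validated final" = length(final))
  check_funnel(funnel)

  provenance <- build_provenance(all_genes, expressed, target_keys,
                                 decisions, cond_insensitive, pm_screened,
                                 specific, final)

  structure(list(funnel = funnel,
                 sets = list(expressed = expressed,
                             membranomes = membranomes,
                             condition_insensitive = cond_insensitive,
                             plasma_membrane = pm_screened,
                             population_specific = specific,
                             proteomic_pm = proteomic_pm,
                             final = final),
                 decisions = decisions,
                 provenance = provenance,
                 function_histogram = xval$function_histogram,
                 config = list(filter = filter, rules = rules,
                               target_population = target_population,
                               specificity_mode = specificity_mode,
                               filter_mode = filter_mode),
                 seed = seed,
                 timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            class = "pipeline_report")
}

# transcriptomic funnel must narrow monotonically
check_funnel <- function(funnel) {
  chain <- funnel[c("condition-insensitive", "plasma-membrane annotated",
                    "population-specific", "cross-validated final")]
  if (any(diff(chain) > 0))
    stop("funnel monotonicity violated: ",
         paste(sprintf("%s=%d", names(chain), chain), collapse = " -> "))
  invisible(funnel)
}

build_provenance <- function(all_genes, expressed, target_keys, decisions,
                             cond_insensitive, pm_screened, specific, final) {
  in_target <- lapply(target_keys, function(k) expressed[[k]]$gene_ids)
  state <- vapply(all_genes, function(g) {
    hit <- vapply(in_target, function(ids) g %in% ids, logical(1))
    if (!any(hit)) return("not_expressed_in_target")
    if (!all(hit)) return("condition_specific")
    d <- decisions[[g]]
    if (is.null(d)) return("no_protein_sequence")
    if (!d$is_candidate)
      return(paste0("failed_topology:", paste(d$failed_filters, collapse = "+")))
    if (!(g %in% pm_screened$gene_ids)) {
      if (g %in% attr(pm_screened, "unannotated")) return("unannotated")
      return("not_plasma_membrane")
    }
    if (!(g %in% specific$gene_ids)) return("not_population_specific")
    if (!(g %in% final$gene_ids)) return("not_in_proteome")
    "final_candidate"
  }, character(1))
  data.frame(gene_id = all_genes, state = unname(state),
             stringsAsFactors = FALSE)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("membranome pipeline report\n")
  for (i in seq_along(x$funnel))
    cat(sprintf("  %-32s %d\n", names(x$funnel)[i], x$funnel[i]))
  h <- x$function_histogram
  h <- h[h$count > 0, , drop = FALSE]
  if (nrow(h) > 0L)
    cat("  final-set functions:",
        paste(sprintf("%s=%d", h$class, h$count), collapse = ", "), "\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (funnel, provenance, histogram, config snapshot,
#' seed, timestamp) plus one candidate-set TSV per stage.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(funnel = as.list(report$funnel),
         function_histogram = report$function_histogram,
         provenance = report$provenance,
         config = list(filter = unclass(report$config$filter),
                       rules = report$config$rules,
                       target_population = report$config$target_population,
                       specificity_mode = report$config$specificity_mode,
                       filter_mode = report$config$filter_mode),
         seed = report$seed,
         timestamp = report$timestamp),
    file.path(dir, "report.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  write_candidate_set(report$sets$condition_insensitive,
                      file.path(dir, "candidates_condition_insensitive.tsv"))
  write_candidate_set(report$sets$plasma_membrane,
                      file.path(dir, "candidates_plasma_membrane.tsv"))
  write_candidate_set(report$sets$population_specific,
                      file.path(dir, "candidates_population_specific.tsv"))
  write_candidate_set(report$sets$final, file.path(dir, "candidates_final.tsv"))
  invisible(dir)
}
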