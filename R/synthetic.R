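# Seeded generators for every input the pipeline consumes, with planted
# ground truth. The statistical structure mirrors the study design the
# analysis assumes: five cell populations profiled in 12 bulk samples
# (target stromal population under sham and infarct conditions, plus
# cardiomyocyte, non-myocyte and embryonic stem cell references),
# negative-binomial transcript counts with population-specific expressed
# sets, proteins carrying planted sorting signals, an annotation table
# consistent with the plants up to a configurable error rate, an MS
# detection process with configurable sensitivity, and a clustered
# single-cell matrix with one planted co-expression cluster.

AA20 <- setdiff(AA_ALPHABET, "X")

PROTEIN_CLASSES <- c("plasma_membrane", "secreted", "nuclear", "ER_resident",
                     "mitochondrial", "cytosolic")

CLASS_COMPARTMENT <- c(plasma_membrane = "plasma_membrane",
                       secreted = "secreted",
                       nuclear = "nucleus",
                       ER_resident = "ER",
                       mitochondrial = "mitochondrion",
                       cytosolic = "cytosol")

#' Simulation configuration
#'
#' The defaults define the emulated study: a target stromal population
#' profiled under two conditions (sham and infarct, 3 samples each) plus
#' three reference populations (cardiomyocytes, non-myocytes, embryonic
#' stem cells, 2 samples each — 12 samples in total); expressed genes at
#' negative-binomial mean 200 with dispersion 0.3 (variance =
#' mu + mu^2 * dispersion), silent genes at mean 0.5; a protein-class mix
#' dominated by membrane and cytosolic classes; 5% annotation corruption
#' and 80% MS detection sensitivity. `noise = "zero"` is the closure
#' preset: silent genes at exactly 0, Poisson counts for expressed genes,
#' no annotation error, full MS detection.
#'
#' @param seed mandatory integer seed; all generators derive their streams
#'   from it.
#' @param n_genes number of genes.
#' @param membership_mix named fractions over membership categories
#'   (housekeeping, target_both, target_sham_only, target_mi_only, cm,
#'   non_myocyte, esc, silent); must sum to 1.
#' @param class_mix named fractions over protein classes; must sum to 1.
#' @param mu_hi,dispersion,mu_lo negative-binomial parameters for
#'   expressed/silent genes (`dispersion = 0` means Poisson).
#' @param annotation_error_rate per-gene compartment corruption
#'   probability.
#' @param ms_detection_prob detection probability for target-population
#'   plasma-membrane proteins in the MS list.
#' @param ms_background_prob detection probability for all other proteins.
#' @param nes_fraction fraction of cytosolic proteins carrying a planted
#'   nuclear export signal.
#' @param sc single-cell block: named list with `clusters`,
#'   `cells_per_cluster`, `coexpr_cluster`, `markers`, `base_rate`,
#'   `coexpr_rate`, `n_filler_genes`, `mu`, `size`.
#' @param noise `"default"` or `"zero"` (the zero-noise closure preset).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_genes = 500L,
                       membership_mix = c(housekeeping = 0.20,
                                          target_both = 0.15,
                                          target_sham_only = 0.05,
                                          target_mi_only = 0.05,
                                          cm = 0.15, non_myocyte = 0.15,
                                          esc = 0.15, silent = 0.10),
                       class_mix = c(plasma_membrane = 0.25, secreted = 0.15,
                                     nuclear = 0.15, ER_resident = 0.10,
                                     mitochondrial = 0.10, cytosolic = 0.25),
                       mu_hi = 200, dispersion = 0.3, mu_lo = 0.5,
                       annotation_error_rate = 0.05,
                       ms_detection_prob = 0.8,
                       ms_background_prob = 0.3,
                       nes_fraction = 0.5,
                       sc = list(clusters = c("endothelial", "fibroblast",
                                              "myeloid", "pericyte",
                                              "schwann", "smooth_muscle"),
                                 cells_per_cluster = 60L,
                                 coexpr_cluster = "fibroblast",
                                 markers = c("Peg3", "Itgav"),
                                 base_rate = 0.25, coexpr_rate = 0.8,
                                 n_filler_genes = 40L, mu = 2, size = 1),
                       noise = c("default", "zero")) {
  if (missing(seed)) stop("seed is mandatory")
  noise <- match.arg(noise)
  if (abs(sum(membership_mix) - 1) > 1e-9) stop("membership_mix must sum to 1")
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (n_genes < 1L) stop("n_genes must be positive")
  if (noise == "zero") {
    mu_lo <- 0; dispersion <- 0
    annotation_error_rate <- 0; ms_detection_prob <- 1
  }
  groups <- data.frame(
    population = c("PW1", "PW1", "CM", "nonCM", "ESC"),
    condition = c("sham", "MI", "normal", "normal", "normal"),
    n_samples = c(3L, 3L, 2L, 2L, 2L),
    stringsAsFactors = FALSE)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 groups = groups, membership_mix = membership_mix,
                 class_mix = class_mix, mu_hi = mu_hi,
                 dispersion = dispersion, mu_lo = mu_lo,
                 annotation_error_rate = annotation_error_rate,
                 ms_detection_prob = ms_detection_prob,
                 ms_background_prob = ms_background_prob,
                 nes_fraction = nes_fraction, sc = sc, noise = noise),
            class = "sim_config")
}

# Independent reproducible seed per generator stream.
stream_seed <- function(cfg, k) (cfg$seed %% 200000000L) * 10L + k

# membership -> which (population, condition) groups express the gene
membership_groups <- function(membership, groups) {
  key <- paste(groups$population, groups$condition, sep = ":")
  switch(membership,
         housekeeping = key,
         target_both = c("PW1:sham", "PW1:MI"),
         target_sham_only = "PW1:sham",
         target_mi_only = "PW1:MI",
         cm = "CM:normal",
         non_myocyte = "nonCM:normal",
         esc = "ESC:normal",
         silent = character(0))
}

# --- background sequence sampling ------------------------------------------
# Backgrounds are drawn uniformly over the 20 residues, then rejection-
# scrubbed so they contain no incidental sorting-signal matches (NLS and NES
# regexes, hydrophobic windows strong enough to seed an h-region or TM
# segment). This keeps planting labels exact: a "negative" background that
# happened to contain a real motif would be a labeling error, not a
# detector error.

NLS_MONO_RE <- "K[KR].[KR]"
NLS_BIP_RE <- "[KR]{2}.{9,12}[KR]{3,5}"
NES_RE <- "[LIVFM].{2,3}[LIVFM].{2,3}[LIVFM].[LIVFM]"
BASIC_CLUSTER_RE <- "[KR]([^KR]?[KR]){2}"  # 3 basics, gaps <= 1: HMM bait

bg_violations <- function(ch, kd) {
  s <- paste(ch, collapse = "")
  iv <- list()
  for (re in c(NLS_MONO_RE, NLS_BIP_RE, NES_RE, BASIC_CLUSTER_RE)) {
    m <- gregexpr(re, s, perl = TRUE)[[1L]]
    if (m[1L] != -1L)
      iv <- c(iv, lapply(seq_along(m), function(i)
        c(m[i], m[i] + attr(m, "match.length")[i] - 1L)))
  }
  # hydrophobic 6-windows with mean >= 2.0 (would seed an h-region / TM)
  v <- unname(kd[ch])
  n <- length(v)
  if (n >= 6L) {
    cs <- c(0, cumsum(v))
    w <- (cs[7:(n + 1L)] - cs[1:(n - 5L)]) / 6
    bad <- which(w >= 2.0)
    iv <- c(iv, lapply(bad, function(i) c(i, i + 5L)))
    # 19-window smoothed hydropathy above the TM threshold
    if (n >= 19L) {
      w19 <- (cs[20:(n + 1L)] - cs[1:(n - 18L)]) / 19
      bad19 <- which(w19 > 1.6)
      iv <- c(iv, lapply(bad19, function(i) c(i, i + 18L)))
    }
  }
  iv
}

clean_background <- function(n, kd = hydropathy_scale("kd"), max_iter = 200L) {
  if (n == 0L) return("")
  ch <- sample(AA20, n, replace = TRUE)
  for (it in seq_len(max_iter)) {
    iv <- bg_violations(ch, kd)
    if (length(iv) == 0L) return(paste(ch, collapse = ""))
    for (b in iv) {
      idx <- b[1L]:min(b[2L], n)
      ch[idx] <- sample(AA20, length(idx), replace = TRUE)
    }
  }
  # extremely unlikely; fall back to an inert polar filler
  paste(sample(c("S", "T", "N", "Q", "G", "A", "P", "H"), n, replace = TRUE),
        collapse = "")
}

# residues safe against every screened motif class (no K/R, D/E, or Phi)
POLAR_SAFE <- c("A", "G", "S", "T", "N", "Q", "H", "P", "Y", "C")

SP_BLOCK <- paste0("MK", strrep("L", 10), "ASA")   # n / h / c regions, 15 aa
NLS_BLOCK <- "PKKKRKV"                              # SV40-type monopartite
NES_BLOCK <- "LAQLAELSL"                            # Phi-x2-Phi-x2-Phi-x-Phi

tm_block <- function(len = 21L) paste(sample(c("L", "I", "V", "F"), len,
                                             replace = TRUE), collapse = "")

# N-terminal amphipathic, arginine-rich presequence: residues assigned by
# helical-wheel side (100 degrees/residue), hydrophobic face A, basic face R
# (alanine keeps the moment high without feeding the leucine-rich NES
# pattern — natural presequences are R/A/S/L-rich).
mtp_block <- function() {
  k <- 0:17
  res <- ifelse(cos(k * 100 * pi / 180) > 0, "A", "R")
  res[1L] <- "M"
  paste0(paste(res, collapse = ""),
         paste(sample(POLAR_SAFE, 12L, replace = TRUE), collapse = ""))
}

# A protein is assembled from parts; background parts stay resampleable so
# a post-assembly verification pass can remove any false signal arising at
# part boundaries (the per-part scrub cannot see across joins).
assemble <- function(...) {
  parts <- list(...)
  ch <- unlist(lapply(parts, function(p) strsplit(p$text, "", TRUE)[[1L]]))
  bg <- unlist(lapply(parts, function(p) rep(p$bg, nchar(p$text))))
  list(ch = ch, bg = bg)
}
bg_part <- function(n) list(text = clean_background(n), bg = TRUE)
fixed <- function(text) list(text = text, bg = FALSE)

# False-signal intervals (0-based half-open) given the planting record.
false_signal_intervals <- function(seq, plant) {
  iv <- list()
  add <- function(s, e) iv[[length(iv) + 1L]] <<- c(s, e)
  sp <- if (nchar(seq) >= 25L) predict_signal_peptide(seq)
        else list(present = FALSE, cleavage_pos = NA_integer_)
  if (!plant$sp && sp$present) add(3L, 31L)    # kill the h/c-region support
  tm <- suppressWarnings(predict_tm_segments(seq))
  if (sp$present && nrow(tm) > 0L)
    tm <- tm[!(tm$end <= sp$cleavage_pos), , drop = FALSE]
  if (plant$tm == 0L && nrow(tm) > 0L)
    for (i in seq_len(nrow(tm))) add(tm$start[i], tm$end[i])
  if (!plant$nls) {
    h <- detect_nls(seq)
    if (nrow(h) > 0L) for (i in seq_len(nrow(h))) add(h$start[i], h$end[i])
  }
  if (!plant$nes) {
    h <- detect_nes(seq)
    if (nrow(h) > 0L) for (i in seq_len(nrow(h))) {
      # hits inside the SP or a TM helix are masked downstream; only
      # background-exposed matches are labeling hazards
      in_sp <- sp$present && h$start[i] < sp$cleavage_pos
      in_tm <- nrow(tm) > 0L && any(h$start[i] < tm$end & h$end[i] > tm$start)
      if (!in_sp && !in_tm) add(h$start[i], h$end[i])
    }
  }
  if (!plant$er && nchar(seq) >= 4L) {
    h <- detect_er_retention(seq)
    if (nrow(h) > 0L) for (i in seq_len(nrow(h))) add(h$start[i], h$end[i])
  }
  if (!plant$mtp && !sp$present && nchar(seq) >= 30L &&
      nrow(detect_mtp(seq, sp = sp)) > 0L) add(0L, 30L)
  iv
}

# Resample background residues inside false-signal intervals until the
# sequence carries exactly its planted signals (labels exact by
# construction). Gives up after max_iter; callers treat that as a failed
# draw and rebuild.
fixup_protein <- function(asm, plant, max_iter = 40L) {
  for (it in seq_len(max_iter)) {
    seq <- paste(asm$ch, collapse = "")
    iv <- false_signal_intervals(seq, plant)
    if (length(iv) == 0L) return(seq)
    touched <- FALSE
    for (b in iv) {
      idx <- which(asm$bg & seq_along(asm$ch) > b[1L] &
                     seq_along(asm$ch) <= b[2L])
      if (length(idx) > 0L) {
        asm$ch[idx] <- sample(AA20, length(idx), replace = TRUE)
        touched <- TRUE
      }
    }
    if (!touched) return(NULL)   # false signal with no background support
  }
  NULL
}

# Build one protein of the given class; returns residues plus the planted-
# signal record.
build_protein <- function(class, nes_fraction) {
  plant <- list(sp = FALSE, tm = 0L, nls = FALSE, nes = FALSE,
                er = FALSE, mtp = FALSE)
  for (attempt in 1:10) {
    asm <- switch(class,
      plasma_membrane = {
        n_tm <- if (stats::runif(1) < 0.3) 2L else 1L
        plant$sp <- TRUE; plant$tm <- n_tm
        if (n_tm == 2L)
          assemble(fixed(SP_BLOCK), bg_part(25L), fixed(tm_block()),
                   bg_part(25L), fixed(tm_block()), bg_part(50L))
        else
          assemble(fixed(SP_BLOCK), bg_part(25L), fixed(tm_block()),
                   bg_part(50L))
      },
      secreted = {
        plant$sp <- TRUE
        assemble(fixed(SP_BLOCK), bg_part(100L))
      },
      nuclear = {
        plant$nls <- TRUE
        assemble(fixed("M"), bg_part(25L), fixed(NLS_BLOCK), bg_part(70L))
      },
      ER_resident = {
        plant$sp <- TRUE; plant$tm <- 1L; plant$er <- TRUE
        tail <- if (stats::runif(1) < 0.7) "KDEL" else "GKKAA"
        assemble(fixed(SP_BLOCK), bg_part(25L), fixed(tm_block()),
                 bg_part(40L), fixed(tail))
      },
      mitochondrial = {
        plant$mtp <- TRUE
        assemble(fixed(mtp_block()), bg_part(90L))
      },
      cytosolic = {
        if (attempt == 1L) plant$nes <- stats::runif(1) < nes_fraction
        if (plant$nes)
          assemble(fixed("M"), bg_part(35L), fixed(NES_BLOCK), bg_part(60L))
        else
          assemble(fixed("M"), bg_part(100L))
      },
      stop("unknown protein class: ", class))
    seq <- fixup_protein(asm, plant)
    if (!is.null(seq)) { plant$residues <- seq; return(plant) }
  }
  stop("could not realize a clean '", class, "' protein")
}

#' Simulate protein sequences with planted sorting signals
#'
#' Assigns each gene a protein class from `class_mix` and builds a protein
#' carrying exactly the sorting signals of its class (signal peptide,
#' transmembrane blocks, SV40-type NLS, NES, C-terminal ER-retention
#' motif, amphipathic arginine-rich presequence), concatenated with
#' motif-free background (see the package vignette for the rejection-
#' sampling construction). Deterministic under the config seed.
#'
#' @param cfg a [sim_config].
#' @param classes optional precomputed class assignment (character vector
#'   of length `n_genes`); drawn from `class_mix` when `NULL`.
#' @return list with `proteins` (a [seq_set]) and `truth` (data.frame:
#'   gene_id, class, sp, n_tm, nls, nes, er, mtp).
#' @export
simulate_proteins <- function(cfg, classes = NULL) {
  set.seed(stream_seed(cfg, 1L))
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  if (is.null(classes))
    classes <- sample(names(cfg$class_mix), cfg$n_genes, replace = TRUE,
                      prob = cfg$class_mix)
  plants <- lapply(classes, build_protein, nes_fraction = cfg$nes_fraction)
  res <- vapply(plants, function(p) p$residues, character(1))
  truth <- data.frame(gene_id = gene_ids, class = classes,
                      sp = vapply(plants, `[[`, logical(1), "sp"),
                      n_tm = vapply(plants, `[[`, integer(1), "tm"),
                      nls = vapply(plants, `[[`, logical(1), "nls"),
                      nes = vapply(plants, `[[`, logical(1), "nes"),
                      er = vapply(plants, `[[`, logical(1), "er"),
                      mtp = vapply(plants, `[[`, logical(1), "mtp"),
                      stringsAsFactors = FALSE)
  list(proteins = seq_set(res, gene_ids, "aa"), truth = truth)
}

nb_draw <- function(n, mu, dispersion) {
  if (mu <= 0) return(numeric(n))
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate per-group transcript abundance tables
#'
#' Draws gene-level counts (negative binomial, mean `mu_hi` for genes
#' expressed in the group, `mu_lo` otherwise), splits each gene over 1-3
#' transcripts by Dirichlet weights (fixed per gene, so aggregation is
#' exercised), and emits one transcript-level matrix per
#' population-by-condition group.
#'
#' @param cfg a [sim_config].
#' @param membership optional precomputed membership assignment; drawn
#'   from `membership_mix` when `NULL`.
#' @return list with `counts` (named list of transcript matrices, one per
#'   group `"<population>:<condition>"`), `gene_models`, `sample_info`
#'   (data.frame: sample, population, condition), and `membership`
#'   (data.frame: gene_id, membership).
#' @export
simulate_expression <- function(cfg, membership = NULL) {
  set.seed(stream_seed(cfg, 2L))
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  if (is.null(membership))
    membership <- sample(names(cfg$membership_mix), cfg$n_genes,
                         replace = TRUE, prob = cfg$membership_mix)
  n_tx <- sample(1:3, cfg$n_genes, replace = TRUE)
  tx_w <- lapply(n_tx, function(k) { w <- stats::rgamma(k, 1); w / sum(w) })
  tx_ids <- unlist(lapply(seq_len(cfg$n_genes), function(i)
    sprintf("%s.t%d", gene_ids[i], seq_len(n_tx[i]))))
  gene_models <- data.frame(
    transcript_id = tx_ids,
    gene_id = rep(gene_ids, n_tx), stringsAsFactors = FALSE)
  expr_groups <- lapply(membership, membership_groups, groups = cfg$groups)
  counts <- list()
  sample_info <- data.frame(sample = character(0), population = character(0),
                            condition = character(0), stringsAsFactors = FALSE)
  for (g in seq_len(nrow(cfg$groups))) {
    pop <- cfg$groups$population[g]; cond <- cfg$groups$condition[g]
    key <- paste(pop, cond, sep = ":")
    ns <- cfg$groups$n_samples[g]
    smp <- sprintf("%s_%s_s%d", pop, cond, seq_len(ns))
    expressed <- vapply(expr_groups, function(e) key %in% e, logical(1))
    gm <- matrix(0, cfg$n_genes, ns)
    gm[expressed, ] <- nb_draw(sum(expressed) * ns, cfg$mu_hi, cfg$dispersion)
    if (cfg$mu_lo > 0)
      gm[!expressed, ] <- nb_draw(sum(!expressed) * ns, cfg$mu_lo,
                                  cfg$dispersion)
    tx <- matrix(0, length(tx_ids), ns,
                 dimnames = list(tx_ids, smp))
    row0 <- 0L
    for (i in seq_len(cfg$n_genes)) {
      k <- n_tx[i]
      tx[row0 + seq_len(k), ] <- outer(tx_w[[i]], gm[i, ])
      row0 <- row0 + k
    }
    counts[[key]] <- tx
    sample_info <- rbind(sample_info,
                         data.frame(sample = smp, population = pop,
                                    condition = cond, stringsAsFactors = FALSE))
  }
  list(counts = counts, gene_models = gene_models, sample_info = sample_info,
       membership = data.frame(gene_id = gene_ids, membership = membership,
                               stringsAsFactors = FALSE))
}

#' Simulate the MS protein list and the annotation table
#'
#' The annotation table reports each gene's planted compartment, corrupted
#' independently with probability `annotation_error_rate` (a corrupted
#' gene gets a different random compartment); plasma-membrane genes get a
#' molecular-function class (receptor/transporter/enzyme/ion_channel or
#' undefined). The MS list detects each target-population plasma-membrane
#' protein with probability `ms_detection_prob` and every other protein
#' with probability `ms_background_prob`; the membrane-fraction flag is
#' true for membrane-class proteins. A fraction of gene symbols are
#' emitted as case variants or aliases to exercise identifier
#' normalization.
#'
#' @param cfg a [sim_config].
#' @param truth protein truth data.frame from [simulate_proteins()].
#' @param membership membership data.frame from [simulate_expression()].
#' @return list with `ms` (data.frame protein_id, gene_symbol,
#'   membrane_flag), `annotation` (an [annotation_table]), `idmap` (an
#'   [id_map]), and `ms_detected` (character vector of genes planted as
#'   MS-detected target plasma-membrane proteins).
#' @export
simulate_ms_and_annotation <- function(cfg, truth, membership) {
  set.seed(stream_seed(cfg, 3L))
  genes <- truth$gene_id
  n <- length(genes)
  # annotation: planted compartment, corrupted at the configured rate
  comp <- unname(CLASS_COMPARTMENT[truth$class])
  corrupt <- stats::runif(n) < cfg$annotation_error_rate
  all_comp <- unique(unname(CLASS_COMPARTMENT))
  comp[corrupt] <- vapply(comp[corrupt], function(cp)
    sample(setdiff(all_comp, cp), 1L), character(1))
  fn <- rep("undefined", n)
  is_pm_ann <- comp == "plasma_membrane"
  fn[is_pm_ann] <- sample(FUNCTION_CLASSES, sum(is_pm_ann), replace = TRUE,
                          prob = c(0.20, 0.15, 0.075, 0.075, 0.50))
  ann <- annotation_table(genes, as.list(comp), fn)
  # identifier map: every gene has an upper-case alias form
  idmap <- id_map(genes, setNames(genes, paste0("ALIAS_", toupper(genes))))
  # MS detection
  mem <- membership$membership[match(genes, membership$gene_id)]
  in_target <- mem %in% c("housekeeping", "target_both", "target_sham_only",
                          "target_mi_only")
  is_target_pm <- in_target & truth$class == "plasma_membrane"
  p <- ifelse(is_target_pm, cfg$ms_detection_prob, cfg$ms_background_prob)
  detected <- stats::runif(n) < p
  sym <- genes
  style <- stats::runif(n)
  sym[style < 0.2] <- toupper(genes[style < 0.2])
  sym[style >= 0.2 & style < 0.4] <-
    paste0("ALIAS_", toupper(genes[style >= 0.2 & style < 0.4]))
  ms <- data.frame(protein_id = sprintf("MS_%s", genes[detected]),
                   gene_symbol = sym[detected],
                   membrane_flag = truth$class[detected] %in%
                     c("plasma_membrane", "ER_resident"),
                   stringsAsFactors = FALSE)
  list(ms = ms, annotation = ann, idmap = idmap,
       ms_detected = genes[detected & is_target_pm])
}

#' Simulate a clustered single-cell count matrix
#'
#' Per cluster and gene, counts are Bernoulli(expression rate) times
#' 1 + NB(mu, size). In the designated co-expression cluster the two
#' marker genes are switched on jointly (one Bernoulli draw gates both),
#' planting elevated joint expression; in every other cluster the markers
#' are independent at the base rate.
#'
#' @param cfg a [sim_config].
#' @return list with `cells` (a [cell_matrix]) and `truth` (the planted
#'   co-expression cluster name).
#' @export
simulate_single_cell <- function(cfg) {
  set.seed(stream_seed(cfg, 4L))
  sc <- cfg$sc
  genes <- c(sc$markers, sprintf("sc_g%03d", seq_len(sc$n_filler_genes)))
  clusters <- rep(sc$clusters, each = sc$cells_per_cluster)
  n_cells <- length(clusters)
  m <- matrix(0, n_cells, length(genes),
              dimnames = list(sprintf("cell%05d", seq_len(n_cells)), genes))
  draw <- function(n, rate) {
    on <- stats::runif(n) < rate
    ifelse(on, 1 + stats::rnbinom(n, size = sc$size, mu = sc$mu), 0)
  }
  for (k in sc$clusters) {
    idx <- which(clusters == k)
    if (k == sc$coexpr_cluster) {
      on <- stats::runif(length(idx)) < sc$coexpr_rate
      for (g in sc$markers)
        m[idx, g] <- ifelse(on, 1 + stats::rnbinom(length(idx), size = sc$size,
                                                   mu = sc$mu), 0)
    } else {
      for (g in sc$markers) m[idx, g] <- draw(length(idx), sc$base_rate)
    }
    for (g in setdiff(genes, sc$markers))
      m[idx, g] <- draw(length(idx), sc$base_rate)
  }
  list(cells = cell_matrix(m, clusters), truth = sc$coexpr_cluster)
}

#' Simulate a complete study
#'
#' Runs all four generators under one seed and assembles the planted final
#' candidate set: genes expressed in the target population under both
#' conditions and nowhere else, of plasma-membrane protein class, and
#' MS-detected. At the zero-noise preset the full pipeline recovers this
#' set exactly.
#'
#' @param cfg a [sim_config].
#' @return a `membranome_sim` list: `config`, `proteins`, `truth`
#'   (per-gene data.frame joining class, planted signals and membership),
#'   `expression`, `annotation`, `ms`, `idmap`, `sc`, and `final_truth`
#'   (character vector of planted final candidates).
#' @export
simulate_study <- function(cfg) {
  prot <- simulate_proteins(cfg)
  expr <- simulate_expression(cfg)
  msann <- simulate_ms_and_annotation(cfg, prot$truth, expr$membership)
  sc <- simulate_single_cell(cfg)
  truth <- merge(prot$truth, expr$membership, by = "gene_id", sort = TRUE)
  final_truth <- truth$gene_id[truth$membership == "target_both" &
                                 truth$class == "plasma_membrane" &
                                 truth$gene_id %in% msann$ms_detected]
  structure(list(config = cfg, proteins = prot$proteins, truth = truth,
                 expression = expr, annotation = msann$annotation,
                 ms = msann$ms, idmap = msann$idmap, sc = sc,
                 final_truth = sort(final_truth)),
            class = "membranome_sim")
}

#' @export
print.membranome_sim <- function(x, ...) {
  cat(sprintf("simulated membranome study: %d genes, %d samples, seed %d\n",
              x$config$n_genes, sum(x$config$groups$n_samples),
              x$config$seed))
  cat(sprintf("  planted final candidate set: %d gene(s)\n",
              length(x$final_truth)))
  invisible(x)
}

#' Write a simulated study to a directory
#'
#' Emits every pipeline input as plain text: `proteins.fasta`,
#' `counts_<population>_<condition>.tsv`, `gene_models.tsv`,
#' `sample_info.tsv`, `annotation.tsv`, `ms_list.tsv`, `id_map.tsv`,
#' `sc_counts.mtx` (+ sidecars), `truth.json`, `config_used.yaml`.
#'
#' @param sim a `membranome_sim` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$proteins, file.path(dir, "proteins.fasta"))
  for (key in names(sim$expression$counts)) {
    fname <- sprintf("counts_%s.tsv", gsub(":", "_", key))
    write_count_table(sim$expression$counts[[key]],
                      sim$expression$gene_models, file.path(dir, fname))
  }
  utils::write.table(sim$expression$gene_models,
                     file.path(dir, "gene_models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$expression$sample_info,
                     file.path(dir, "sample_info.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_annotation_table(sim$annotation, file.path(dir, "annotation.tsv"))
  utils::write.table(
    data.frame(protein_id = sim$ms$protein_id,
               gene_symbol = sim$ms$gene_symbol,
               membrane_flag = as.integer(sim$ms$membrane_flag)),
    file.path(dir, "ms_list.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(raw_id = c(sim$idmap$canonical,
                          paste0("ALIAS_", toupper(sim$idmap$canonical))),
               canonical = c(sim$idmap$canonical, sim$idmap$canonical),
               aliases = ""),
    file.path(dir, "id_map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_cell_matrix(sim$sc$cells, file.path(dir, "sc_counts"))
  jsonlite::write_json(
    list(final_candidates = sim$final_truth,
         coexpr_cluster = sim$sc$truth,
         genes = sim$truth),
    file.path(dir, "truth.json"), dataframe = "rows", auto_unbox = TRUE)
  cfg <- sim$config
  cfg$groups <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config_used.yaml"))
  invisible(dir)
}
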