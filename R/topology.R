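# Sorting-signal predictors. These are transparent surrogates for the classic
# server-based predictors (SignalP, TMHMM, NLStradamus, WolfPsort-style
# compartment calls) built from the canonical published mechanisms: the
# von Heijne -3,-1 cleavage rule, Kyte-Doolittle windowed hydropathy, a
# two-state NLS HMM with posterior decoding, leucine-rich NES and C-terminal
# ER-retention regexes, and the Eisenberg hydrophobic moment for
# mitochondrial presequences. Every threshold is exposed.

#' Hydropathy scales
#'
#' `kd`: Kyte-Doolittle. `ges`: Goldman-Engelman-Steitz transfer free
#' energies. `eisenberg`: Eisenberg normalized consensus (used for
#' hydrophobic-moment computation). Unknown residue X scores 0 on every
#' scale.
#'
#' @param name one of `"kd"`, `"ges"`, `"eisenberg"`.
#' @return named numeric vector over the 20 residues plus X.
#' @export
hydropathy_scale <- function(name = c("kd", "ges", "eisenberg")) {
  name <- match.arg(name)
  s <- switch(name,
    kd = c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
           E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
           M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
           Y = -1.3, V = 4.2),
    ges = c(F = 3.7, M = 3.4, I = 3.1, L = 2.8, V = 2.6, C = 2.0,
            W = 1.9, A = 1.6, T = 1.2, G = 1.0, S = 0.6, P = -0.2,
            Y = -0.7, H = -3.0, Q = -4.1, N = -4.8, E = -8.2, K = -8.8,
            D = -9.2, R = -12.3),
    eisenberg = c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
                  Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
                  L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
                  S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08))
  c(s, X = 0)
}

seq_chars <- function(seq) strsplit(toupper(seq), "", fixed = TRUE)[[1L]]

#' Smoothed per-residue hydropathy profile
#'
#' Value at position i is the mean scale value over the window centered at
#' i; windows are truncated at the sequence ends, so the profile has the
#' same length as the sequence.
#'
#' @param seq amino-acid sequence string.
#' @param scale named hydropathy vector (see [hydropathy_scale()]).
#' @param window odd window width, `>= 5` and `<=` sequence length.
#' @return numeric vector, one value per residue.
#' @export
hydropathy_profile <- function(seq, scale = hydropathy_scale("kd"), window = 19L) {
  ch <- seq_chars(seq)
  n <- length(ch)
  if (window %% 2L == 0L || window < 5L) stop("window must be odd and >= 5")
  if (window > n) stop("window larger than sequence")
  v <- unname(scale[ch])
  if (anyNA(v)) stop("residue not covered by hydropathy scale")
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  # scale values live on a 0.1 grid, so window means sit on a coarse grid;
  # rounding removes binary accumulation noise ahead of threshold tests
  round((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L), 9)
}

#' Predict transmembrane segments by windowed hydropathy
#'
#' Maximal runs of residues whose smoothed hydropathy exceeds
#' `tm_threshold`; runs separated by fewer than `merge_gap` residues are
#' merged before the length filter; runs shorter than `min_tm_len` are
#' discarded. Intervals are 0-based half-open and sorted by start.
#'
#' @param seq amino-acid sequence.
#' @param scale hydropathy scale vector.
#' @param window odd smoothing window (default 19).
#' @param tm_threshold smoothed-hydropathy cutoff (default 1.6).
#' @param min_tm_len minimum segment length in residues (default 15).
#' @param merge_gap runs closer than this many residues are merged
#'   (default 3, i.e. gaps of 1-2 residues close).
#' @return data.frame with columns start, end, score (mean smoothed
#'   hydropathy over the segment). A sequence shorter than the window
#'   yields zero rows with a warning.
#' @export
predict_tm_segments <- function(seq, scale = hydropathy_scale("kd"),
                                window = 19L, tm_threshold = 1.6,
                                min_tm_len = 15L, merge_gap = 3L) {
  n <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0), score = numeric(0))
  if (n < window) {
    warning("sequence shorter than hydropathy window; no TM call attempted")
    return(empty)
  }
  prof <- hydropathy_profile(seq, scale, window)
  runs <- runs_above(prof > tm_threshold)
  if (nrow(runs) == 0L) return(empty)
  # merge runs separated by < merge_gap residues
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] < merge_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  merged <- merged[merged$end - merged$start >= min_tm_len, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty)
  merged$score <- vapply(seq_len(nrow(merged)), function(i)
    mean(prof[(merged$start[i] + 1L):merged$end[i]]), numeric(1))
  rownames(merged) <- NULL
  merged
}

# maximal TRUE-runs of a logical vector as 0-based half-open intervals
runs_above <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Signal-peptide model parameters
#'
#' Tripartite model: a non-negative net charge over the n-region (first
#' `n_region_len` residues; K/R = +1, D/E = -1), a hydrophobic h-region
#' (a run of at least `h_min_len` residues within positions
#' `[h_lo, h_hi]` with mean hydropathy `>= h_mean_min`), and a c-region
#' cleavage site obeying the von Heijne -3,-1 rule (small residue at
#' p-1, small-or-aliphatic at p-3) located `c_dist_lo`..`c_dist_hi`
#' residues after the h-region end, with cleavage position p in
#' `[p_lo, p_hi]`. Positions are 0-based; p indexes the first mature
#' residue.
#'
#' @param n_region_len,h_min_len,h_lo,h_hi,h_mean_min,p_lo,p_hi,c_dist_lo,c_dist_hi
#'   model thresholds, defaults as described.
#' @return a `sp_params` list.
#' @export
sp_params <- function(n_region_len = 5L, h_min_len = 6L, h_lo = 3L, h_hi = 30L,
                      h_mean_min = 2.0, p_lo = 12L, p_hi = 40L,
                      c_dist_lo = 2L, c_dist_hi = 8L) {
  as.list(environment())
}

SP_MINUS1 <- c("A", "G", "S", "C", "T")
SP_MINUS3 <- c("A", "G", "S", "C", "T", "V", "L", "I")

#' Predict an N-terminal secretory signal peptide
#'
#' Scores the first 40 residues with the tripartite n/h/c-region model of
#' [sp_params()]. `present` requires all three region tests to hold;
#' `cleavage_pos` is the smallest valid cleavage position (0-based index
#' of the first mature residue); `score` is the best qualifying h-region
#' window's mean hydropathy.
#'
#' @param seq amino-acid sequence, length >= 25.
#' @param params an [sp_params] list.
#' @param scale hydropathy scale (default Kyte-Doolittle).
#' @return list with `present`, `cleavage_pos` (NA when absent), `score`.
#' @export
predict_signal_peptide <- function(seq, params = sp_params(),
                                   scale = hydropathy_scale("kd")) {
  ch <- seq_chars(seq)
  n <- length(ch)
  if (n < 25L) stop("sequence too short for signal-peptide scoring (< 25 aa)")
  absent <- list(present = FALSE, cleavage_pos = NA_integer_, score = NA_real_)
  # n-region: net charge of the first n_region_len residues
  nreg <- ch[seq_len(min(params$n_region_len, n))]
  charge <- sum(nreg %in% c("K", "R")) - sum(nreg %in% c("D", "E"))
  if (charge < 0) return(absent)
  # h-region: hydrophobic windows within [h_lo, h_hi] (0-based, inclusive)
  v <- unname(scale[ch])
  hi_bound <- min(params$h_hi, n - 1L)
  h_ends <- integer(0)    # exclusive end positions of qualifying windows
  best_mean <- -Inf
  for (s in params$h_lo:(hi_bound - params$h_min_len + 1L)) {
    if (s > hi_bound - params$h_min_len + 1L) break
    for (e in (s + params$h_min_len):(hi_bound + 1L)) {   # exclusive end
      m <- round(mean(v[(s + 1L):e]), 9)
      if (m >= params$h_mean_min) {
        h_ends <- c(h_ends, e)
        if (m > best_mean) best_mean <- m
      }
    }
  }
  if (length(h_ends) == 0L) return(absent)
  h_ends <- unique(h_ends)
  # c-region: smallest valid cleavage position p
  p_hi <- min(params$p_hi, n)
  for (p in params$p_lo:p_hi) {
    if (!(ch[p] %in% SP_MINUS1)) next        # residue at p-1 (0-based)
    if (!(ch[p - 2L] %in% SP_MINUS3)) next   # residue at p-3 (0-based)
    d <- p - h_ends
    if (any(d >= params$c_dist_lo & d <= params$c_dist_hi))
      return(list(present = TRUE, cleavage_pos = as.integer(p),
                  score = best_mean))
  }
  absent
}

motif_hits <- function(kind = character(0), start = integer(0),
                       end = integer(0), matched = character(0),
                       score = numeric(0), source = character(0)) {
  data.frame(kind = kind, start = as.integer(start), end = as.integer(end),
             matched = matched, score = score, source = source,
             stringsAsFactors = FALSE)
}

regex_hits <- function(seq, pattern, kind, source = "regex") {
  m <- gregexpr(pattern, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(motif_hits())
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  motif_hits(kind = rep(kind, length(starts)), start = starts,
             end = starts + lens,
             matched = substring(seq, starts + 1L, starts + lens),
             score = rep(1.0, length(starts)),
             source = rep(source, length(starts)))
}

#' Two-state NLS HMM parameters
#'
#' A background/NLS hidden Markov model over the 20 residues. The NLS state
#' is basic-residue-rich (defaults K = 0.30, R = 0.25, remaining mass
#' uniform over the other 18 residues); the background emission defaults to
#' the observed composition of the scored sequence. These are surrogate
#' defaults, not values recovered from any published predictor.
#'
#' @param emission_nls named emission distribution over the 20 residues
#'   (must sum to 1 within 1e-9).
#' @param emission_bg optional named background distribution; `NULL` means
#'   "use the observed sequence composition".
#' @param p_bg_nls,p_nls_bg transition probabilities, each in (0, 1).
#' @param posterior_threshold NLS-posterior cutoff for calling a hit.
#' @param min_run minimum consecutive above-threshold residues (>= 1).
#' @return an `nls_hmm_params` list.
#' @export
nls_hmm_params <- function(emission_nls = NULL, emission_bg = NULL,
                           p_bg_nls = 0.01, p_nls_bg = 0.10,
                           posterior_threshold = 0.5, min_run = 4L) {
  aa20 <- setdiff(AA_ALPHABET, "X")
  if (is.null(emission_nls)) {
    emission_nls <- setNames(rep(0.45 / 18, 20), aa20)
    emission_nls["K"] <- 0.30
    emission_nls["R"] <- 0.25
  }
  if (abs(sum(emission_nls) - 1) > 1e-9)
    stop("emission_nls must sum to 1")
  if (!is.null(emission_bg) && abs(sum(emission_bg) - 1) > 1e-9)
    stop("emission_bg must sum to 1")
  if (p_bg_nls <= 0 || p_bg_nls >= 1 || p_nls_bg <= 0 || p_nls_bg >= 1)
    stop("transition probabilities must lie in (0, 1)")
  if (min_run < 1L) stop("min_run must be >= 1")
  list(emission_nls = emission_nls, emission_bg = emission_bg,
       p_bg_nls = p_bg_nls, p_nls_bg = p_nls_bg,
       posterior_threshold = posterior_threshold, min_run = as.integer(min_run))
}

# Per-residue emission likelihoods for both states. X is uninformative
# (likelihood 1 in both states).
hmm_emissions <- function(ch, params) {
  bg <- params$emission_bg
  if (is.null(bg)) {
    tab <- table(ch[ch != "X"])
    bg <- setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  e_bg <- unname(bg[ch]); e_bg[is.na(e_bg)] <- 1e-9
  e_nls <- unname(params$emission_nls[ch]); e_nls[is.na(e_nls)] <- 1e-9
  e_bg[ch == "X"] <- 1; e_nls[ch == "X"] <- 1
  cbind(bg = e_bg, nls = e_nls)
}

hmm_initial <- function(params) {
  # stationary distribution of the 2-state chain
  c(bg = params$p_nls_bg, nls = params$p_bg_nls) /
    (params$p_bg_nls + params$p_nls_bg)
}

#' Posterior NLS-state probabilities (forward-backward)
#'
#' Scaled forward-backward decoding of the two-state NLS HMM. The chain is
#' initialized at its stationary distribution.
#'
#' @param seq amino-acid sequence.
#' @param params an [nls_hmm_params] list.
#' @return numeric vector of per-residue posterior probabilities of the
#'   NLS state (each in \[0, 1\]; the background posterior is its
#'   complement).
#' @export
nls_posterior <- function(seq, params = nls_hmm_params()) {
  ch <- seq_chars(seq)
  n <- length(ch)
  E <- hmm_emissions(ch, params)
  A <- rbind(bg = c(1 - params$p_bg_nls, params$p_bg_nls),
             nls = c(params$p_nls_bg, 1 - params$p_nls_bg))
  pi0 <- hmm_initial(params)
  alpha <- matrix(0, n, 2); scal <- numeric(n)
  alpha[1L, ] <- pi0 * E[1L, ]
  scal[1L] <- sum(alpha[1L, ]); alpha[1L, ] <- alpha[1L, ] / scal[1L]
  if (n > 1L) for (t in 2:n) {
    a <- (alpha[t - 1L, ] %*% A) * E[t, ]
    scal[t] <- sum(a)
    alpha[t, ] <- a / scal[t]
  }
  beta <- matrix(0, n, 2)
  beta[n, ] <- 1
  if (n > 1L) for (t in (n - 1L):1L) {
    b <- A %*% (E[t + 1L, ] * beta[t + 1L, ])
    beta[t, ] <- b / scal[t + 1L]
  }
  post <- alpha * beta
  post[, 2L] / rowSums(post)
}

#' Detect nuclear localization signals
#'
#' Union of (a) regex hits — monopartite `K[KR].[KR]` and bipartite
#' `[KR]{2}.{9,12}[KR]{3,5}` — and (b) HMM hits: maximal runs of at least
#' `min_run` residues whose NLS posterior exceeds `posterior_threshold`.
#' Overlapping hits are merged; the merged hit keeps the kind of the
#' higher-scoring source (regex hits score 1.0, HMM hits score their peak
#' posterior).
#'
#' @param seq amino-acid sequence.
#' @param params an [nls_hmm_params] list.
#' @return a motif-hit data.frame (kind, start, end, matched, score,
#'   source); kinds are `NLS_mono`, `NLS_bipartite`, `NLS_hmm`.
#' @export
detect_nls <- function(seq, params = nls_hmm_params()) {
  seq <- toupper(seq)
  hits <- rbind(regex_hits(seq, "K[KR].[KR]", "NLS_mono"),
                regex_hits(seq, "[KR]{2}.{9,12}[KR]{3,5}", "NLS_bipartite"))
  post <- nls_posterior(seq, params)
  runs <- runs_above(post > params$posterior_threshold)
  runs <- runs[runs$end - runs$start >= params$min_run, , drop = FALSE]
  if (nrow(runs) > 0L) {
    hmm <- motif_hits(kind = rep("NLS_hmm", nrow(runs)),
                      start = runs$start, end = runs$end,
                      matched = substring(seq, runs$start + 1L, runs$end),
                      score = vapply(seq_len(nrow(runs)), function(i)
                        max(post[(runs$start[i] + 1L):runs$end[i]]), numeric(1)),
                      source = rep("hmm", nrow(runs)))
    hits <- rbind(hits, hmm)
  }
  merge_hits(hits, seq)
}

# merge overlapping intervals; merged hit keeps the kind/source of the
# highest-scoring member and spans the union.
merge_hits <- function(hits, seq) {
  if (nrow(hits) <= 1L) return(hits)
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  out <- list()
  cur <- hits[1L, ]
  for (i in 2:nrow(hits)) {
    h <- hits[i, ]
    if (h$start < cur$end) {   # overlap
      if (h$score > cur$score) { cur$kind <- h$kind; cur$source <- h$source;
                                 cur$score <- h$score }
      cur$end <- max(cur$end, h$end)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- h
    }
  }
  out[[length(out) + 1L]] <- cur
  out <- do.call(rbind, out)
  out$matched <- substring(seq, out$start + 1L, out$end)
  rownames(out) <- NULL
  out
}

#' Detect leucine-rich nuclear export signals
#'
#' Regex `PhiX(2,3)PhiX(2,3)PhiXPhi` with Phi in L, I, V, F, M;
#' leftmost non-overlapping matches, greedy (longest-first) spacers.
#'
#' @param seq amino-acid sequence.
#' @return motif-hit data.frame with kind `NES`.
#' @export
detect_nes <- function(seq) {
  regex_hits(toupper(seq), "[LIVFM].{2,3}[LIVFM].{2,3}[LIVFM].[LIVFM]", "NES")
}

#' Detect C-terminal ER-retention motifs
#'
#' `ER_lumenal`: the C-terminal four residues match `[KRHQSA][DENQ]EL`
#' (KDEL class). `ER_dilysine`: lysine at position -3 and another at -4 or
#' -5 from the C-terminus (di-lysine class). Both are anchored — internal
#' occurrences do not count.
#'
#' @param seq amino-acid sequence, length >= 4.
#' @return motif-hit data.frame (possibly empty).
#' @export
detect_er_retention <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 4L) stop("sequence shorter than an ER-retention motif (< 4 aa)")
  ch <- seq_chars(seq)
  hits <- motif_hits()
  last4 <- substring(seq, n - 3L, n)
  if (grepl("^[KRHQSA][DENQ]EL$", last4))
    hits <- rbind(hits, motif_hits("ER_lumenal", n - 4L, n, last4, 1.0, "regex"))
  k3 <- ch[n - 2L] == "K"                       # position -3
  k45 <- (ch[n - 3L] == "K") || (n >= 5L && ch[n - 4L] == "K")  # -4 or -5
  if (k3 && k45) {
    start <- if (ch[n - 3L] == "K") n - 4L else n - 5L
    hits <- rbind(hits, motif_hits("ER_dilysine", start, n,
                                   substring(seq, start + 1L, n), 1.0, "rule"))
  }
  hits
}

#' Hydrophobic moment of a residue window
#'
#' `mu = |sum_k h_k exp(i k delta)| / n` with `delta` in degrees per
#' residue (100 for an alpha helix).
#'
#' @param seq amino-acid sequence (the whole window is used).
#' @param scale hydropathy scale (default Eisenberg normalized consensus).
#' @param delta_deg helical twist per residue in degrees.
#' @return the scalar moment.
#' @export
hydrophobic_moment <- function(seq, scale = hydropathy_scale("eisenberg"),
                               delta_deg = 100) {
  ch <- seq_chars(seq)
  h <- unname(scale[ch])
  k <- seq_along(h) - 1L
  ang <- k * delta_deg * pi / 180
  sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(h)
}

#' Detect an N-terminal mitochondrial targeting presequence
#'
#' Present iff, over residues 0-29: at least 3 arginines, at most one
#' acidic residue (D/E), the hydrophobic moment of residues 0-17 at 100
#' degrees on the normalized Eisenberg scale is `>= moment_threshold`,
#' and no signal peptide is predicted (a cleavable SP takes precedence).
#'
#' @param seq amino-acid sequence, length >= 30.
#' @param moment_threshold amphipathicity cutoff (default 0.32).
#' @param sp optional precomputed [predict_signal_peptide()] call; computed
#'   with default parameters when `NULL`.
#' @return motif-hit data.frame with zero rows or one `MTP` row whose score
#'   is the hydrophobic moment.
#' @export
detect_mtp <- function(seq, moment_threshold = 0.32, sp = NULL) {
  seq <- toupper(seq)
  if (nchar(seq) < 30L) stop("sequence too short for MTP scoring (< 30 aa)")
  ch <- seq_chars(seq)
  pre <- ch[1:30]
  if (sum(pre == "R") < 3L) return(motif_hits())
  if (sum(pre %in% c("D", "E")) > 1L) return(motif_hits())
  mu <- hydrophobic_moment(substring(seq, 1L, 18L))
  if (mu < moment_threshold) return(motif_hits())
  if (is.null(sp)) sp <- predict_signal_peptide(seq)
  if (sp$present) return(motif_hits())
  motif_hits("MTP", 0L, 30L, substring(seq, 1L, 30L), mu, "rule")
}

#' Topology predictor parameter bundle
#'
#' Collects every tunable threshold of the predictor stack in one list,
#' mirroring the `topology:` block of a pipeline YAML config.
#'
#' @param scale_name hydropathy scale for SP/TM detection (`"kd"` or
#'   `"ges"`).
#' @param window,tm_threshold,min_tm_len,merge_gap TM detection settings.
#' @param sp an [sp_params] list.
#' @param nls an [nls_hmm_params] list.
#' @param mtp_moment_threshold MTP amphipathicity cutoff.
#' @return a `topology_params` list.
#' @export
topology_params <- function(scale_name = "kd", window = 19L, tm_threshold = 1.6,
                            min_tm_len = 15L, merge_gap = 3L,
                            sp = sp_params(), nls = nls_hmm_params(),
                            mtp_moment_threshold = 0.32) {
  list(scale = hydropathy_scale(scale_name), window = window,
       tm_threshold = tm_threshold, min_tm_len = min_tm_len,
       merge_gap = merge_gap, sp = sp, nls = nls,
       mtp_moment_threshold = mtp_moment_threshold)
}

#' Run every sorting-signal predictor on one protein
#'
#' Runs signal-peptide, transmembrane, NLS, NES, ER-retention and MTP
#' prediction and assembles a `topology_report`. If a signal peptide is
#' present, TM segments wholly contained in `[0, cleavage_pos)` are removed
#' (a cleaved signal peptide is not a membrane anchor), and NES matches
#' lying inside the signal peptide or overlapping a TM segment are masked
#' (a functional export signal must be exposed to the cytosol; a
#' leucine-rich regex necessarily also matches hydrophobic helices).
#' The compartment
#' call follows the membranome decision table: SP + TM and no exclusion
#' signal is a plasma-membrane candidate; SP + ER-retention is ER
#' resident; SP without TM is secreted; an MTP is mitochondrial; an NLS
#' without SP is nuclear; anything else is "other".
#'
#' @param id protein identifier.
#' @param seq amino-acid sequence.
#' @param params a [topology_params] list.
#' @return a `topology_report`: list with `protein_id`, `signal_peptide`,
#'   `tm_segments`, `hits`, `compartment_call`.
#' @export
build_topology_report <- function(id, seq, params = topology_params()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  sp <- if (n >= 25L) predict_signal_peptide(seq, params$sp, params$scale)
        else list(present = FALSE, cleavage_pos = NA_integer_, score = NA_real_)
  tm <- suppressWarnings(
    predict_tm_segments(seq, params$scale, params$window, params$tm_threshold,
                        params$min_tm_len, params$merge_gap))
  if (sp$present && nrow(tm) > 0L)
    tm <- tm[!(tm$end <= sp$cleavage_pos), , drop = FALSE]
  nes <- detect_nes(seq)
  # an NES is a cytosolic-exposed motif: matches lying inside the signal
  # peptide or a hydrophobic TM helix are regex artifacts and are masked
  if (nrow(nes) > 0L) {
    in_sp <- if (sp$present) nes$start < sp$cleavage_pos else rep(FALSE, nrow(nes))
    in_tm <- rep(FALSE, nrow(nes))
    if (nrow(tm) > 0L)
      for (i in seq_len(nrow(tm)))
        in_tm <- in_tm | (nes$start < tm$end[i] & nes$end > tm$start[i])
    nes <- nes[!(in_sp | in_tm), , drop = FALSE]
  }
  hits <- rbind(detect_nls(seq, params$nls),
                nes,
                if (n >= 4L) detect_er_retention(seq) else motif_hits(),
                if (n >= 30L) detect_mtp(seq, params$mtp_moment_threshold, sp)
                else motif_hits())
  rownames(hits) <- NULL
  rep_ <- structure(list(protein_id = id, signal_peptide = sp,
                         tm_segments = tm, hits = hits),
                    class = "topology_report")
  rep_$compartment_call <- compartment_call(rep_)
  rep_
}

report_has <- function(report, kinds) any(report$hits$kind %in% kinds)
NLS_KINDS <- c("NLS_mono", "NLS_bipartite", "NLS_hmm")
ER_KINDS <- c("ER_lumenal", "ER_dilysine")

compartment_call <- function(report) {
  sp <- report$signal_peptide$present
  ntm <- nrow(report$tm_segments)
  nls <- report_has(report, NLS_KINDS)
  nes <- report_has(report, "NES")
  er <- report_has(report, ER_KINDS)
  mtp <- report_has(report, "MTP")
  if (sp && ntm >= 1L && !nls && !nes && !er && !mtp) return("plasma_membrane_candidate")
  if (sp && er) return("ER_resident")
  if (mtp) return("mitochondrial")
  if (nls && !sp) return("nuclear")
  if (sp && ntm == 0L && !nls && !nes && !er) return("secreted")
  "other"
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("topology report for %s\n", x$protein_id))
  cat(sprintf("  signal peptide: %s%s\n",
              if (x$signal_peptide$present) "present" else "absent",
              if (x$signal_peptide$present)
                sprintf(" (cleavage at %d)", x$signal_peptide$cleavage_pos) else ""))
  cat(sprintf("  TM segments: %d\n", nrow(x$tm_segments)))
  if (nrow(x$hits) > 0L)
    cat(sprintf("  motif hits: %s\n",
                paste(sprintf("%s[%d,%d)", x$hits$kind, x$hits$start, x$hits$end),
                      collapse = " ")))
  cat(sprintf("  compartment call: %s\n", x$compartment_call))
  invisible(x)
}

#' Topology reports for every sequence in a collection
#'
#' @param seqs a [seq_set] of amino-acid sequences.
#' @param params a [topology_params] list.
#' @return named list of `topology_report`s.
#' @export
build_topology_reports <- function(seqs, params = topology_params()) {
  stopifnot(inherits(seqs, "seq_set"))
  out <- lapply(seq_along(seqs), function(i)
    build_topology_report(names(seqs)[i], unclass(seqs)[[i]], params))
  names(out) <- names(seqs)
  out
}

#' Flatten topology reports to a data.frame
#'
#' One row per protein: signal-peptide flag and cleavage position, TM
#' count, per-class motif flags, compartment call, and the full hit list
#' JSON-encoded in one column (for TSV export).
#'
#' @param reports list of `topology_report`s.
#' @return data.frame.
#' @export
topology_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(protein_id = r$protein_id,
               signal_peptide = r$signal_peptide$present,
               cleavage_pos = if (r$signal_peptide$present)
                 r$signal_peptide$cleavage_pos else NA_integer_,
               n_tm = nrow(r$tm_segments),
               has_nls = report_has(r, NLS_KINDS),
               has_nes = report_has(r, "NES"),
               has_er_retention = report_has(r, ER_KINDS),
               has_mtp = report_has(r, "MTP"),
               compartment_call = r$compartment_call,
               hits_json = as.character(
                 jsonlite::toJSON(r$hits, dataframe = "rows")),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
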