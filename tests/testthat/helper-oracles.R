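# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops and direct transcriptions of each rule, used to
# freeze expected values and for property-style agreement tests.

KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
        G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
        P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)

AA20_TEST <- setdiff(names(KD), "X")

random_aa <- function(n, alphabet = AA20_TEST) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# windowed mean with truncated ends, one value per residue
oracle_windowed_mean <- function(seq, window) {
  ch <- strsplit(seq, "")[[1]]
  v <- unname(KD[ch])
  h <- (window - 1) / 2
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    lo <- max(1, i - h); hi <- min(length(v), i + h)
    out[i] <- mean(v[lo:hi])
  }
  round(out, 9)   # window means are reported on a 1e-9 grid
}

# TM segments by direct scanning: runs above threshold, merge close runs,
# drop short ones
oracle_tm_segments <- function(seq, window = 19, thr = 1.6, min_len = 15,
                               gap = 3) {
  prof <- oracle_windowed_mean(seq, window)
  above <- prof > thr
  runs <- list(); i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i - 1, j)   # 0-based half-open
      i <- j + 1
    } else i <- i + 1
  }
  if (length(runs) == 0) return(data.frame(start = integer(0), end = integer(0)))
  merged <- list(runs[[1]])
  if (length(runs) > 1) for (k in 2:length(runs)) {
    last <- merged[[length(merged)]]
    if (runs[[k]][1] - last[2] < gap) merged[[length(merged)]][2] <- runs[[k]][2]
    else merged[[length(merged) + 1]] <- runs[[k]]
  }
  keep <- Filter(function(r) r[2] - r[1] >= min_len, merged)
  data.frame(start = vapply(keep, `[`, numeric(1), 1),
             end = vapply(keep, `[`, numeric(1), 2))
}

# signal peptide rule, literal transcription with nested loops
oracle_sp <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  charge <- sum(ch[1:5] %in% c("K", "R")) - sum(ch[1:5] %in% c("D", "E"))
  if (charge < 0) return(list(present = FALSE, cleavage_pos = NA))
  v <- unname(KD[ch])
  h_ends <- c()
  hi <- min(30, n - 1)                      # 0-based inclusive bound
  for (s0 in 3:hi) for (e0 in s0:hi) {      # 0-based inclusive window
    if (e0 - s0 + 1 < 6) next
    if (round(mean(v[(s0 + 1):(e0 + 1)]), 9) >= 2.0)
      h_ends <- c(h_ends, e0 + 1)
  }
  if (length(h_ends) == 0) return(list(present = FALSE, cleavage_pos = NA))
  small1 <- c("A", "G", "S", "C", "T")
  small3 <- c(small1, "V", "L", "I")
  for (p in 12:min(40, n)) {
    if (!(ch[p] %in% small1)) next          # 0-based p-1
    if (!(ch[p - 2] %in% small3)) next      # 0-based p-3
    if (any(p - h_ends >= 2 & p - h_ends <= 8))
      return(list(present = TRUE, cleavage_pos = p))
  }
  list(present = FALSE, cleavage_pos = NA)
}

# NLS-HMM posterior by exhaustive enumeration of all 2^n state paths
oracle_hmm_posterior <- function(seq, p_bg_nls = 0.01, p_nls_bg = 0.10) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  aa20 <- AA20_TEST
  e_nls <- setNames(rep(0.45 / 18, 20), aa20)
  e_nls["K"] <- 0.30; e_nls["R"] <- 0.25
  tab <- table(ch)
  e_bg <- setNames(as.numeric(tab) / n, names(tab))
  A <- rbind(c(1 - p_bg_nls, p_bg_nls), c(p_nls_bg, 1 - p_nls_bg))
  pi0 <- c(p_nls_bg, p_bg_nls) / (p_bg_nls + p_nls_bg)
  total <- 0
  post_num <- numeric(n)
  for (code in 0:(2^n - 1)) {
    states <- as.integer(intToBits(code))[1:n] + 1L   # 1 = bg, 2 = nls
    p <- pi0[states[1]]
    p <- p * (if (states[1] == 1) e_bg[ch[1]] else e_nls[ch[1]])
    if (n > 1) for (t in 2:n) {
      p <- p * A[states[t - 1], states[t]]
      p <- p * (if (states[t] == 1) e_bg[ch[t]] else e_nls[ch[t]])
    }
    total <- total + p
    post_num <- post_num + p * (states == 2L)
  }
  unname(post_num / total)
}

# longest-ORF by exhaustive enumeration of (strand, frame, start, stop)
oracle_orf <- function(seq, frames = "forward3", min_aa = 1) {
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  strands <- list(list(s = seq, off = 0))
  if (frames == "all6") strands <- c(strands, list(list(s = rc(seq), off = 3)))
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (st in strands) for (f in 0:2) {
    n <- nchar(st$s)
    starts <- seq(f + 1, n - 2, by = 3)
    if (length(starts) < 1) next
    codons <- substring(st$s, starts, starts + 2)
    for (i in seq_along(codons)) {
      if (codons[i] != "ATG") next
      for (j in i:length(codons)) {
        if (codons[j] %in% stops) {
          len <- j - i
          # only the first ATG before this stop can be longest; but keep
          # full enumeration semantics: compare every (start, stop) pair
          cand <- list(frame = f + st$off, start = starts[i] - 1,
                       end = starts[j] - 1, len = len)
          if (len >= min_aa &&
              (is.null(best) || len > best$len ||
               (len == best$len && (cand$frame < best$frame ||
                (cand$frame == best$frame && cand$start < best$start)))))
            best <- cand
          break
        }
      }
    }
  }
  best
}

# groupby-sum of transcript rows to genes
oracle_aggregate <- function(m, gm) {
  genes <- unique(gm$gene_id[match(rownames(m), gm$transcript_id)])
  out <- matrix(0, length(genes), ncol(m), dimnames = list(genes, colnames(m)))
  for (tx in rownames(m)) {
    g <- gm$gene_id[gm$transcript_id == tx]
    out[g, ] <- out[g, ] + m[tx, ]
  }
  out
}

# expression filter by explicit per-row loop
oracle_filter_keep <- function(m, min_count, min_samples) {
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    n_over <- 0
    for (j in seq_len(ncol(m))) if (m[i, j] > min_count) n_over <- n_over + 1
    keep[i] <- n_over > min_samples
  }
  keep
}

# function histogram by explicit tally
oracle_histogram <- function(genes, ann_df) {
  classes <- c("receptor", "transporter", "enzyme", "ion_channel", "undefined")
  counts <- setNames(rep(0L, 5), classes)
  for (g in genes) {
    f <- ann_df$molecular_function[ann_df$gene_id == g]
    if (length(f) == 0 || !(f %in% classes)) f <- "undefined"
    counts[f] <- counts[f] + 1L
  }
  counts
}

tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}
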