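test_that("hydropathy profile equals the windowed mean, ends truncated", {
  expect_equal(hydropathy_profile(strrep("L", 30), window = 19),
               rep(3.8, 30))
  expect_equal(hydropathy_profile(strrep("G", 30), window = 19),
               rep(-0.4, 30))
  set.seed(21)
  for (rep in 1:10) {
    s <- random_aa(50)
    for (w in c(5, 9, 19)) {
      expect_equal(hydropathy_profile(s, window = w),
                   oracle_windowed_mean(s, w))
    }
  }
  expect_error(hydropathy_profile(random_aa(30), window = 10), "odd")
  expect_error(hydropathy_profile(random_aa(10), window = 19), "larger")
})

test_that("TM detection finds planted hydrophobic blocks at oracle bounds", {
  one <- paste0(strrep("S", 30), strrep("L", 21), strrep("S", 30))
  seg <- predict_tm_segments(one)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start, seg$end), c(30L, 51L))

  expect_equal(nrow(predict_tm_segments(strrep("S", 60))), 0L)

  two <- paste0(strrep("S", 25), strrep("L", 21), strrep("K", 25),
                strrep("L", 21), strrep("S", 25))
  seg2 <- predict_tm_segments(two)
  expect_equal(seg2$start, c(25L, 75L))
  expect_equal(seg2$end, c(42L, 92L))

  expect_warning(predict_tm_segments(random_aa(10)), "shorter")
})

test_that("TM segments match brute force, never overlap and are ordered", {
  set.seed(22)
  for (rep in 1:25) {
    s <- random_aa(sample(19:250, 1),
                   alphabet = c(AA20_TEST, rep(c("L", "I", "V", "F"), 6)))
    got <- predict_tm_segments(s)
    want <- oracle_tm_segments(s)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    if (nrow(got) > 1L) {
      expect_true(all(diff(got$start) > 0))
      expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
    }
  }
})

test_that("signal-peptide prediction implements the tripartite n/h/c model", {
  sp_seq <- paste0("MK", strrep("L", 10), "ASA", strrep("S", 20),
                   strrep("T", 20))
  call <- predict_signal_peptide(sp_seq)
  expect_true(call$present)
  expect_equal(call$cleavage_pos, 13L)   # frozen from the rule oracle
  expect_gte(call$cleavage_pos, 10L)
  expect_lte(call$cleavage_pos, 40L)

  # no hydrophobic core
  expect_false(predict_signal_peptide(paste0(strrep("K", 40),
                                             strrep("S", 10)))$present)
  # negative n-region charge
  expect_false(predict_signal_peptide(paste0("MDE", strrep("L", 10), "ASA",
                                             strrep("S", 25)))$present)
  expect_error(predict_signal_peptide(random_aa(20)), "short")
})

test_that("signal-peptide calls agree with the rule oracle on random input", {
  set.seed(23)
  n_present <- 0
  for (rep in 1:200) {
    # enriched alphabet so both outcomes occur
    s <- paste0(sample(c("M", "MK", "MR", "MD"), 1),
                random_aa(sample(28:60, 1),
                          alphabet = c(AA20_TEST, rep(c("L", "A", "S"), 8))))
    got <- predict_signal_peptide(s)
    want <- oracle_sp(s)
    expect_equal(got$present, want$present)
    if (want$present) {
      expect_equal(got$cleavage_pos, want$cleavage_pos)
      n_present <- n_present + 1
    }
  }
  expect_gt(n_present, 10)   # the comparison exercised both branches
})

test_that("NLS forward-backward posteriors match exhaustive path enumeration", {
  set.seed(24)
  # all sequences of length <= 5 over the reduced {K, R, A, L} alphabet
  alpha <- c("K", "R", "A", "L")
  for (len in 1:5) {
    grid <- do.call(expand.grid, rep(list(alpha), len))
    seqs <- apply(as.matrix(grid), 1, paste, collapse = "")
    for (s in seqs) {
      expect_lt(max(abs(nls_posterior(s) - oracle_hmm_posterior(s))), 1e-9)
    }
  }
  # sampled longer sequences up to length 10, full 2^L enumeration each
  for (rep in 1:60) {
    s <- random_aa(sample(6:10, 1), alphabet = alpha)
    post <- nls_posterior(s)
    expect_lt(max(abs(post - oracle_hmm_posterior(s))), 1e-9)
    expect_true(all(post >= 0 & post <= 1))
  }
})

test_that("NLS detection unites regex and HMM evidence", {
  s <- paste0(strrep("A", 30), "PKKKRKV", strrep("A", 23))
  hits <- detect_nls(s)
  expect_equal(nrow(hits), 1L)
  expect_true(hits$start >= 30 && hits$end <= 38)   # covers the K/R run
  expect_true(hits$kind %in% c("NLS_mono", "NLS_bipartite", "NLS_hmm"))
  expect_equal(hits$matched, substring(s, hits$start + 1, hits$end))

  expect_equal(nrow(detect_nls(strrep("A", 50))), 0L)   # no K or R at all

  bip <- paste0(strrep("G", 10), "KR", strrep("A", 10), "KKKK",
                strrep("G", 10))
  expect_true(any(detect_nls(bip)$kind == "NLS_bipartite"))
})

test_that("NES regex finds leucine-rich exports, leftmost non-overlapping", {
  h <- detect_nes("LAAALAALAL")
  expect_equal(nrow(h), 1L)
  expect_equal(h$kind, "NES")
  expect_equal(nrow(detect_nes(strrep("K", 30))), 0L)
  two <- paste0("LAQLAELSL", strrep("G", 20), "IAQIAEISI")
  expect_equal(nrow(detect_nes(two)), 2L)
})

test_that("ER-retention motifs are strictly C-terminal", {
  h <- detect_er_retention(paste0(random_aa(30, alphabet = c("G", "A", "S")),
                                  "WKDEL"))
  expect_true("ER_lumenal" %in% h$kind)
  expect_equal(nrow(detect_er_retention(paste0(strrep("G", 30), "KDELA"))), 0L)
  h2 <- detect_er_retention(paste0(strrep("G", 30), "GGKKAA"))
  expect_equal(h2$kind, "ER_dilysine")
  # hit coordinates track the C-terminus when the sequence grows
  base <- paste0(strrep("G", 20), "KDEL")
  grown <- paste0(strrep("G", 40), "KDEL")
  expect_equal(detect_er_retention(base)$start + 20L,
               detect_er_retention(grown)$start)
  expect_error(detect_er_retention("KDE"), "shorter")
})

test_that("hydrophobic moment and MTP detection follow the helical-wheel rule", {
  # single residue: mu is |h| of that residue (one-term closed form)
  expect_equal(hydrophobic_moment("L"), 1.06)
  expect_equal(hydrophobic_moment("R"), 2.53)
  # direct evaluation of the moment formula on a random window
  set.seed(25)
  s <- random_aa(18)
  eis <- hydropathy_scale("eisenberg")
  h <- unname(eis[strsplit(s, "")[[1]]])
  k <- 0:17; ang <- k * 100 * pi / 180
  mu <- sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / 18
  expect_equal(hydrophobic_moment(s), mu)

  # idealized amphipathic R-rich presequence is called
  amphi <- paste0(paste(ifelse(cos((0:17) * 100 * pi / 180) > 0, "A", "R"),
                        collapse = ""),
                  strrep("S", 12), strrep("G", 70))
  hit <- detect_mtp(amphi)
  expect_equal(hit$kind, "MTP")
  expect_gte(hit$score, 0.32)
  # acidic N-terminus is excluded
  expect_equal(nrow(detect_mtp(paste0("MDDE", random_aa(40,
    alphabet = c("A", "S", "G"))))), 0L)
  expect_error(detect_mtp(random_aa(20)), "short")
})

test_that("topology reports apply the decision table and SP/TM/NES masking", {
  pm <- paste0("MK", strrep("L", 10), "ASA", strrep("S", 25), strrep("L", 21),
               strrep("T", 40))
  r <- build_topology_report("pm", pm)
  expect_true(r$signal_peptide$present)
  expect_gte(nrow(r$tm_segments), 1L)
  expect_equal(r$compartment_call, "plasma_membrane_candidate")
  # the leucine-rich SP and TM regions must not surface as NES hits
  expect_false(any(r$hits$kind == "NES"))

  er <- paste0("MK", strrep("L", 10), "ASA", strrep("S", 25), strrep("L", 21),
               strrep("T", 36), "KDEL")
  expect_equal(build_topology_report("er", er)$compartment_call, "ER_resident")

  sec <- paste0("MK", strrep("L", 10), "ASA", strrep("S", 60))
  r3 <- build_topology_report("sec", sec)
  expect_equal(nrow(r3$tm_segments), 0L)
  expect_equal(r3$compartment_call, "secreted")

  nuc <- paste0("M", strrep("G", 25), "PKKKRKV", strrep("A", 60))
  expect_equal(build_topology_report("nuc", nuc)$compartment_call, "nuclear")
})
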