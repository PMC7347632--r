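test_that("protein generator plants exactly the signals of each class", {
  cfg <- sim_config(seed = 61, n_genes = 120)
  pr <- simulate_proteins(cfg)
  expect_length(pr$proteins, 120L)
  reports <- build_topology_reports(pr$proteins)
  tab <- topology_table(reports)
  truth <- pr$truth
  # pipeline-consistency at zero noise: every planted signal detected,
  # nothing spurious
  expect_equal(tab$signal_peptide, truth$sp)
  expect_equal(tab$n_tm >= 1, truth$n_tm >= 1)
  expect_equal(tab$has_nls, truth$nls)
  expect_equal(tab$has_nes, truth$nes)
  expect_equal(tab$has_er_retention, truth$er)
  expect_equal(tab$has_mtp, truth$mtp)
  # class-to-compartment consistency
  expect_true(all(tab$compartment_call[truth$class == "plasma_membrane"] ==
                    "plasma_membrane_candidate"))
  expect_true(all(tab$compartment_call[truth$class == "nuclear"] == "nuclear"))
  expect_true(all(!tab$signal_peptide[truth$class == "nuclear"]))
  expect_true(all(tab$n_tm[truth$class == "nuclear"] == 0L))
})

test_that("generators are byte-identical under a repeated seed", {
  a <- simulate_study(sim_config(seed = 62, n_genes = 50))
  b <- simulate_study(sim_config(seed = 62, n_genes = 50))
  expect_identical(unclass(a$proteins), unclass(b$proteins))
  expect_identical(a$expression$counts, b$expression$counts)
  expect_identical(a$ms, b$ms)
  expect_identical(a$annotation$compartments, b$annotation$compartments)
  expect_identical(a$sc$cells$counts, b$sc$cells$counts)
  expect_identical(a$final_truth, b$final_truth)
  # and a different seed actually changes the draw
  c_ <- simulate_study(sim_config(seed = 63, n_genes = 50))
  expect_false(identical(unclass(a$proteins), unclass(c_$proteins)))
})

test_that("zero-noise expression recovers planted membership exactly", {
  cfg <- sim_config(seed = 64, n_genes = 150, noise = "zero")
  ex <- simulate_expression(cfg)
  for (key in names(ex$counts)) {
    gm <- aggregate_genes(ex$counts[[key]], ex$gene_models)
    ns <- ncol(gm)
    es <- expressed_set(gm, filter_params(10, min(2L, ns - 1L)),
                        sub(":.*", "", key), sub(".*:", "", key))
    planted <- ex$membership$gene_id[vapply(
      ex$membership$membership,
      function(mm) key %in% membranome:::membership_groups(mm, cfg$groups),
      logical(1))]
    expect_equal(es$gene_ids, sort(planted))
  }
})

test_that("expressed-gene column mass scales linearly with the planted mean", {
  totals <- sapply(c(100, 200, 400), function(mu) {
    vals <- sapply(1:10, function(s) {
      cfg <- sim_config(seed = s, n_genes = 100)
      cfg$mu_hi <- mu; cfg$mu_lo <- 0
      ex <- simulate_expression(cfg)
      sum(ex$counts[["PW1:sham"]])
    })
    mean(vals)
  })
  expect_lt(abs(totals[2] / totals[1] - 2), 0.1 * 2)
  expect_lt(abs(totals[3] / totals[2] - 2), 0.1 * 2)
})

test_that("MS and annotation generators honor their probability contracts", {
  cfg <- sim_config(seed = 65, n_genes = 100, noise = "zero")
  sim <- simulate_study(cfg)
  target_pm <- sim$truth$gene_id[sim$truth$class == "plasma_membrane" &
    sim$truth$membership %in% c("housekeeping", "target_both",
                                "target_sham_only", "target_mi_only")]
  # detection probability 1: every target pm protein present and recovered
  prot <- filter_membrane_proteins(sim$ms, sim$annotation, sim$idmap)
  expect_true(all(target_pm %in% prot$gene_ids))

  # detection probability 0: empty proteomic arm, empty final set
  cfg0 <- sim_config(seed = 65, n_genes = 100, noise = "zero")
  cfg0$ms_detection_prob <- 0; cfg0$ms_background_prob <- 0
  sim0 <- simulate_study(cfg0)
  expect_equal(nrow(sim0$ms), 0L)
  prot0 <- filter_membrane_proteins(sim0$ms, sim0$annotation, sim0$idmap)
  res0 <- cross_validate(candidate_set(c("g0001")), prot0, sim0$annotation)
  expect_length(res0$final_candidates$gene_ids, 0L)

  # full corruption: planted pm genes leave the annotation screen
  cfg1 <- sim_config(seed = 65, n_genes = 100, noise = "zero")
  cfg1$annotation_error_rate <- 1
  sim1 <- simulate_study(cfg1)
  pm_genes <- sim1$truth$gene_id[sim1$truth$class == "plasma_membrane"]
  screened <- plasma_membrane_screen(candidate_set(pm_genes), sim1$annotation)
  expect_length(screened$gene_ids, 0L)
})

test_that("single-cell generator plants recoverable joint expression", {
  sc <- simulate_single_cell(sim_config(seed = 66))
  expect_equal(sort(unique(sc$cells$clusters)),
               sort(sim_config(seed = 1)$sc$clusters))
  je <- joint_expression(sc$cells, "Peg3", "Itgav")
  expect_equal(je$top_cluster, sc$truth)

  cfg <- sim_config(seed = 66)
  cfg$sc$base_rate <- 0; cfg$sc$coexpr_rate <- 0
  off <- simulate_single_cell(cfg)
  expect_true(all(off$cells$counts == 0))
  expect_true(all(marker_summary(off$cells, "Peg3")$fraction_expressing == 0))
})

test_that("a simulated study written to disk feeds the pipeline identically", {
  cfg <- sim_config(seed = 67, n_genes = 80, noise = "zero")
  sim <- simulate_study(cfg)
  dir <- file.path(tempdir(), "simdir67")
  write_simulation(sim, dir)
  for (f in c("proteins.fasta", "gene_models.tsv", "annotation.tsv",
              "ms_list.tsv", "id_map.tsv", "sample_info.tsv", "truth.json",
              "config_used.yaml", "counts_PW1_sham.tsv", "sc_counts.mtx"))
    expect_true(file.exists(file.path(dir, f)), info = f)
  rep_mem <- run_pipeline(sim)
  rep_dir <- run_pipeline(dir)
  expect_equal(rep_dir$sets$final$gene_ids, rep_mem$sets$final$gene_ids)
  expect_equal(rep_dir$funnel, rep_mem$funnel)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(sort(truth$final_candidates), sim$final_truth)
})
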