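mk_report <- function(sp = FALSE, tm = 0L, kinds = character(0)) {
  hits <- if (length(kinds) > 0)
    data.frame(kind = kinds, start = 0L, end = 4L, matched = "XXXX",
               score = 1, source = "regex", stringsAsFactors = FALSE)
  else data.frame(kind = character(0), start = integer(0), end = integer(0),
                  matched = character(0), score = numeric(0),
                  source = character(0))
  structure(list(protein_id = "p",
                 signal_peptide = list(present = sp,
                                       cleavage_pos = if (sp) 15L else NA,
                                       score = if (sp) 3 else NA),
                 tm_segments = if (tm > 0)
                   data.frame(start = 20L * seq_len(tm),
                              end = 20L * seq_len(tm) + 21L, score = 3)
                 else data.frame(start = integer(0), end = integer(0),
                                 score = numeric(0)),
                 hits = hits),
            class = "topology_report")
}

test_that("membranome decision requires SP + TM and lists every violated clause", {
  d <- decide_membranome(mk_report(sp = TRUE, tm = 1L))
  expect_true(d$is_candidate)
  expect_length(d$failed_filters, 0L)

  d <- decide_membranome(mk_report(sp = TRUE, tm = 1L, kinds = "NLS_mono"))
  expect_false(d$is_candidate)
  expect_equal(d$failed_filters, "has_nls")

  d <- decide_membranome(mk_report(sp = FALSE, tm = 0L, kinds = "NLS_hmm"))
  expect_equal(d$failed_filters, c("no_signal_peptide", "no_tm", "has_nls"))

  # each exclusion toggles independently
  rules <- membranome_rules(exclude_nes = FALSE)
  d <- decide_membranome(mk_report(sp = TRUE, tm = 1L, kinds = "NES"), rules)
  expect_true(d$is_candidate)
})

test_that("condition intersection is set intersection with label provenance", {
  a <- candidate_set(c("A", "B"), "sham")
  b <- candidate_set(c("B", "C"), "MI")
  expect_equal(condition_intersection(list(a, b))$gene_ids, "B")
  expect_equal(condition_intersection(list(a, a))$gene_ids, a$gene_ids)
  expect_error(condition_intersection(list(a)), "two sets")

  set.seed(31)
  for (rep in 1:20) {
    x <- candidate_set(sample(letters, sample(5:20, 1)))
    y <- candidate_set(sample(letters, sample(5:20, 1)))
    inter <- length(condition_intersection(list(x, y)))
    onlyx <- length(setdiff(x$gene_ids, y$gene_ids))
    onlyy <- length(setdiff(y$gene_ids, x$gene_ids))
    expect_equal(inter + onlyx + onlyy,
                 length(union(x$gene_ids, y$gene_ids)))
  }
})

test_that("plasma-membrane screen keeps annotated pm genes and reports the rest", {
  ann <- annotation_table(c("g1", "g2"),
                          list(c("plasma_membrane", "cytosol"), "nucleus"),
                          c("receptor", "undefined"))
  res <- plasma_membrane_screen(candidate_set(c("g1", "g2", "g3")), ann)
  expect_equal(res$gene_ids, "g1")
  expect_equal(attr(res, "unannotated"), "g3")
  expect_equal(attr(res, "not_pm"), "g2")

  # planted pm genes among decoys are recovered exactly
  set.seed(32)
  genes <- sprintf("g%03d", 1:100)
  pm <- sample(genes, 20)
  ann2 <- annotation_table(genes,
                           lapply(genes, function(g)
                             if (g %in% pm) "plasma_membrane" else "cytosol"))
  expect_equal(plasma_membrane_screen(candidate_set(genes), ann2)$gene_ids,
               sort(pm))
})

test_that("specificity screen supports difference and intersection modes", {
  target <- candidate_set(c("A", "B", "C"), "PW1")
  others <- list(candidate_set("B"), candidate_set("C"))
  expect_equal(specificity_screen(target, others, "specific")$gene_ids, "A")
  expect_equal(specificity_screen(target, others, "shared")$gene_ids,
               c("B", "C"))
  covering <- list(candidate_set(c("A", "B", "C", "D")))
  expect_length(specificity_screen(target, covering, "specific")$gene_ids, 0L)
  expect_error(specificity_screen(target, list()), "at least one")
})

test_that("function histogram tallies classes with undefined fallback", {
  genes <- sprintf("g%d", 1:9)
  ann <- annotation_table(genes, as.list(rep("plasma_membrane", 9)),
                          c(rep("transporter", 3), rep("receptor", 4),
                            rep("enzyme", 2)))
  h <- categorize_functions(candidate_set(genes), ann)
  expect_equal(h$count[h$class == "transporter"], 3L)
  expect_equal(h$count[h$class == "receptor"], 4L)
  expect_equal(h$count[h$class == "enzyme"], 2L)
  expect_equal(sum(h$count), 9L)
  expect_equal(sum(h$proportion), 1)

  empty <- categorize_functions(candidate_set(character(0)), ann)
  expect_true(all(empty$count == 0L))

  set.seed(33)
  g2 <- sprintf("x%03d", 1:100)
  fn <- sample(c("receptor", "transporter", "enzyme", "ion_channel",
                 "undefined"), 100, TRUE)
  ann2 <- annotation_table(g2, as.list(rep("cytosol", 100)), fn)
  got <- categorize_functions(candidate_set(g2), ann2)
  want <- oracle_histogram(g2, data.frame(gene_id = g2,
                                          molecular_function = fn,
                                          stringsAsFactors = FALSE))
  expect_equal(setNames(got$count, got$class), want)
})

test_that("candidate sets and annotation tables round-trip through TSV", {
  cs <- candidate_set(c("Itgav", "Pdgfra", "Sirpa"), "final")
  p <- tempfile(fileext = ".tsv")
  write_candidate_set(cs, p)
  back <- read_candidate_set(p)
  expect_equal(back$gene_ids, cs$gene_ids)
  expect_equal(back$label, "final")

  ann <- annotation_table(c("a", "b"), list(c("plasma_membrane", "ER"),
                                            "cytosol"),
                          c("receptor", "undefined"))
  p2 <- tempfile(fileext = ".tsv")
  write_annotation_table(ann, p2)
  back2 <- read_annotation_table(p2)
  expect_equal(back2$gene_id, ann$gene_id)
  expect_equal(back2$compartments, ann$compartments)
  expect_equal(back2$molecular_function, ann$molecular_function)
})
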