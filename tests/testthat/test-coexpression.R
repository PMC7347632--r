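mk_cells <- function(counts, clusters, genes = c("Peg3", "Itgav")) {
  colnames(counts) <- genes
  cell_matrix(counts, clusters)
}

test_that("marker summary computes per-cluster fractions and log-means", {
  m <- mk_cells(cbind(c(0, 1, 2, 0), c(1, 1, 0, 0)), rep("fib", 4))
  s <- marker_summary(m, "Peg3")
  expect_equal(s$fraction_expressing, 0.5)
  expect_equal(s$n_cells, 4L)

  zero <- mk_cells(cbind(rep(0, 6), rep(0, 6)), rep(c("a", "b"), each = 3))
  sz <- marker_summary(zero, "Peg3")
  expect_equal(sz$fraction_expressing, c(0, 0))
  expect_equal(sz$mean_expression, c(0, 0))

  expect_error(marker_summary(m, "nope"), "nope")
})

test_that("marker summary matches a brute-force tally on random matrices", {
  set.seed(51)
  counts <- matrix(rnbinom(200 * 50, mu = 1, size = 0.5), 200, 50)
  colnames(counts) <- sprintf("g%02d", 1:50)
  cl <- sample(c("fib", "peri", "schwann", "myl"), 200, TRUE)
  m <- cell_matrix(counts, cl)
  for (g in sample(colnames(counts), 5)) {
    s <- marker_summary(m, g)
    for (k in unique(cl)) {
      idx <- which(cl == k)
      expect_equal(s$fraction_expressing[s$cluster == k],
                   sum(counts[idx, g] > 0) / length(idx))
      # brute-force log-normalization
      tot <- rowSums(counts)[idx]
      ln <- log1p(ifelse(tot > 0, counts[idx, g] * 1e4 / tot, 0))
      expect_equal(s$mean_expression[s$cluster == k], mean(ln))
    }
  }
  # invariance to cell order permutation
  perm <- sample(200)
  mp <- cell_matrix(counts[perm, ], cl[perm])
  expect_equal(marker_summary(mp, "g01"), marker_summary(m, "g01"))
})

test_that("joint expression bounds, argmax and tie-breaks are honored", {
  m <- mk_cells(cbind(c(2, 3), c(1, 0)), c("fib", "fib"))
  je <- joint_expression(m, "Peg3", "Itgav")
  expect_equal(je$summary$fraction_joint, 0.5)

  set.seed(52)
  for (rep in 1:50) {
    counts <- matrix(rbinom(60 * 2, 3, 0.4), 60, 2)
    cl <- sample(c("a", "b", "c"), 60, TRUE)
    je <- joint_expression(mk_cells(counts, cl), "Peg3", "Itgav")
    expect_true(all(je$summary$fraction_joint <=
                      pmin(je$summary$fraction_a, je$summary$fraction_b) + 1e-12))
  }

  # planted co-expression cluster is the argmax
  sc <- simulate_single_cell(sim_config(seed = 7))
  je <- joint_expression(sc$cells, "Peg3", "Itgav")
  expect_equal(je$top_cluster, sc$truth)

  # deterministic tie handling: identical clusters tie and sort by label
  tied <- mk_cells(cbind(c(1, 1, 1, 1), c(1, 1, 1, 1)),
                   c("b", "b", "a", "a"))
  jt <- joint_expression(tied, "Peg3", "Itgav")
  expect_equal(jt$top_cluster, "a")
  expect_equal(jt$ties, c("a", "b"))
})

test_that("population dendrogram clusters by correlation with average linkage", {
  set.seed(53)
  base <- runif(20)
  panel <- rbind(p1 = base, p2 = base, p3 = max(base) - base + runif(20, 0, 1e-3))
  colnames(panel) <- sprintf("g%02d", 1:20)
  dd <- population_dendrogram(panel)
  # identical populations merge first, at distance ~0
  first <- dd$hclust$merge[1, ]
  expect_true(all(sort(dd$hclust$labels[-first]) == c("p1", "p2")))
  expect_lt(dd$hclust$height[1], 1e-9)
  expect_gt(dd$hclust$height[2], 1.5)   # anti-correlated joins near 2
  # merge heights are non-decreasing and the tree serializes to Newick
  expect_true(all(diff(dd$hclust$height) >= -1e-12))
  expect_s3_class(ape::read.tree(text = dd$newick), "phylo")

  for (rep in 1:10) {
    rp <- matrix(runif(5 * 20), 5, dimnames = list(paste0("p", 1:5), NULL))
    dr <- population_dendrogram(rp)
    expect_true(all(diff(dr$hclust$height) >= -1e-12))
  }

  const <- rbind(a = rep(1, 5), b = runif(5))
  expect_warning(population_dendrogram(const), "zero-variance")
  expect_error(population_dendrogram(panel[1, , drop = FALSE]), "two populations")
})

test_that("cell matrices round-trip through MatrixMarket sidecar layout", {
  sc <- simulate_single_cell(sim_config(seed = 9))
  prefix <- file.path(tempdir(), "scrt")
  write_cell_matrix(sc$cells, prefix)
  back <- read_cell_matrix(paste0(prefix, ".mtx"))
  expect_equal(unname(back$counts), unname(sc$cells$counts))
  expect_equal(back$clusters, sc$cells$clusters)
})
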