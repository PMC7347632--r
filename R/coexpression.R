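# Single-cell and population-level marker summaries: per-cluster fraction
# expressing, log-normalized means, joint expression of marker pairs, and
# hierarchical clustering of populations over a marker panel.

#' Cell-by-gene matrix with cluster labels
#'
#' @param counts non-negative matrix, rows = cells, cols = genes (named).
#' @param clusters character vector of per-cell cluster labels (length =
#'   nrow(counts)).
#' @return a `cell_matrix` list.
#' @export
cell_matrix <- function(counts, clusters) {
  if (any(counts < 0)) stop("cell counts must be non-negative")
  if (is.null(colnames(counts))) stop("cell matrix needs gene names")
  if (length(clusters) != nrow(counts))
    stop("one cluster label per cell required")
  structure(list(counts = counts, clusters = as.character(clusters)),
            class = "cell_matrix")
}

# library-size normalization to a fixed per-cell total, then log1p
lognorm <- function(counts, target_total = 1e4) {
  totals <- rowSums(counts)
  sf <- ifelse(totals > 0, target_total / totals, 0)
  log1p(counts * sf)
}

#' Per-cluster expression summary for one marker
#'
#' For each cluster: number of cells, fraction of cells with count
#' strictly above `expr_threshold` (default 0: the droplet sparsity
#' convention), and mean log-normalized expression (counts scaled to
#' `target_total` per cell, then `log1p`).
#'
#' @param m a [cell_matrix].
#' @param gene gene name (must be present).
#' @param expr_threshold count threshold defining "expressing" (strict
#'   `>`).
#' @param target_total per-cell normalization total (default 10,000).
#' @return data.frame with columns cluster, n_cells, fraction_expressing,
#'   mean_expression, ordered by cluster label.
#' @export
marker_summary <- function(m, gene, expr_threshold = 0, target_total = 1e4) {
  stopifnot(inherits(m, "cell_matrix"))
  if (!(gene %in% colnames(m$counts)))
    stop("gene not present in cell matrix: ", gene)
  cl <- sort(unique(m$clusters))
  v <- m$counts[, gene]
  ln <- lognorm(m$counts, target_total)[, gene]
  do.call(rbind, lapply(cl, function(k) {
    in_k <- m$clusters == k
    data.frame(cluster = k, n_cells = sum(in_k),
               fraction_expressing = mean(v[in_k] > expr_threshold),
               mean_expression = mean(ln[in_k]),
               stringsAsFactors = FALSE)
  }))
}

#' Joint expression of two markers per cluster
#'
#' Adds the per-cluster fraction of cells expressing both genes
#' simultaneously, and calls the cluster maximizing that fraction
#' (deterministic tie-break by cluster label sort order; ties reported).
#'
#' @param m a [cell_matrix].
#' @param gene_a,gene_b marker gene names.
#' @param expr_threshold count threshold (strict `>`).
#' @param target_total per-cell normalization total.
#' @return list with `summary` (data.frame: cluster, n_cells, fraction_a,
#'   fraction_b, fraction_joint), `top_cluster`, and `ties` (all clusters
#'   attaining the maximum).
#' @export
joint_expression <- function(m, gene_a, gene_b, expr_threshold = 0,
                             target_total = 1e4) {
  sa <- marker_summary(m, gene_a, expr_threshold, target_total)
  sb <- marker_summary(m, gene_b, expr_threshold, target_total)
  va <- m$counts[, gene_a] > expr_threshold
  vb <- m$counts[, gene_b] > expr_threshold
  joint <- vapply(sa$cluster, function(k)
    mean(va[m$clusters == k] & vb[m$clusters == k]), numeric(1))
  out <- data.frame(cluster = sa$cluster, n_cells = sa$n_cells,
                    fraction_a = sa$fraction_expressing,
                    fraction_b = sb$fraction_expressing,
                    fraction_joint = joint, stringsAsFactors = FALSE)
  top <- out$cluster[out$fraction_joint == max(out$fraction_joint)]
  list(summary = out, top_cluster = top[1L], ties = top)
}

#' Hierarchical clustering of populations over a marker panel
#'
#' Agglomerative clustering with distance `1 - Pearson correlation` across
#' the gene panel and average linkage. Population pairs with a
#' zero-variance profile (correlation undefined) fall back to scaled
#' Euclidean distance, with a warning. Leaf order is deterministic
#' (ties broken by label).
#'
#' @param panel numeric matrix, rows = populations (named), cols = genes.
#' @param method linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return list with `hclust` (the tree), `newick` (serialized tree), and
#'   `distance` (the dist object used).
#' @export
population_dendrogram <- function(panel, method = "average") {
  if (nrow(panel) < 2L) stop("need at least two populations")
  if (ncol(panel) < 1L) stop("need at least one gene")
  sds <- apply(panel, 1L, stats::sd)
  d <- matrix(0, nrow(panel), nrow(panel),
              dimnames = list(rownames(panel), rownames(panel)))
  fallback <- FALSE
  for (i in seq_len(nrow(panel) - 1L)) for (j in (i + 1L):nrow(panel)) {
    if (ncol(panel) >= 2L && sds[i] > 0 && sds[j] > 0) {
      dij <- 1 - stats::cor(panel[i, ], panel[j, ])
    } else {
      fallback <- TRUE
      dij <- sqrt(sum((panel[i, ] - panel[j, ])^2)) / max(1, sqrt(ncol(panel)))
    }
    d[i, j] <- dij; d[j, i] <- dij
  }
  if (fallback)
    warning("zero-variance population profile: Euclidean fallback used for affected pairs")
  # deterministic label order before clustering so ties break by label
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = method)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, newick = nwk, distance = stats::as.dist(d))
}

#' Read a cell matrix from MatrixMarket or dense TSV
#'
#' MTX layout: `<prefix>.mtx` (cells x genes), `<prefix>_genes.tsv`,
#' `<prefix>_cells.tsv` (one id per line), `<prefix>_clusters.tsv`
#' (columns cell_id, cluster). Dense layout: one TSV, first column
#' `cell_id`, second `cluster`, remaining columns genes.
#'
#' @param path `.mtx` prefix path or dense TSV path.
#' @return a [cell_matrix].
#' @export
read_cell_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    prefix <- sub("\\.mtx$", "", path)
    mm <- as.matrix(Matrix::readMM(path))
    genes <- readLines(paste0(prefix, "_genes.tsv"))
    cells <- readLines(paste0(prefix, "_cells.tsv"))
    colnames(mm) <- genes; rownames(mm) <- cells
    cl <- utils::read.delim(paste0(prefix, "_clusters.tsv"),
                            stringsAsFactors = FALSE)
    cell_matrix(mm, cl$cluster[match(cells, cl$cell_id)])
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, -(1:2), drop = FALSE])
    rownames(m) <- df[[1L]]
    cell_matrix(m, df[[2L]])
  }
}

#' Write a cell matrix as MatrixMarket plus sidecars
#'
#' @param m a [cell_matrix].
#' @param prefix output path prefix (files `<prefix>.mtx`,
#'   `<prefix>_genes.tsv`, `<prefix>_cells.tsv`, `<prefix>_clusters.tsv`).
#' @export
write_cell_matrix <- function(m, prefix) {
  counts <- m$counts
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  paste0(prefix, ".mtx"))
  writeLines(colnames(counts), paste0(prefix, "_genes.tsv"))
  writeLines(rownames(counts), paste0(prefix, "_cells.tsv"))
  utils::write.table(data.frame(cell_id = rownames(counts),
                                cluster = m$clusters),
                     paste0(prefix, "_clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
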