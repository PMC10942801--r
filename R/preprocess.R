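#' Normalize a batch for autoencoder input
#'
#' Three steps, each within the batch: (1) library-size normalization of every
#' cell to a common total `target_total`; (2) `log(1 + x)`; (3) per-gene
#' min-max scaling to \[0, 1\]. The \[0, 1\] range is what the autoencoder's
#' sigmoid output layer reconstructs, so scaling is min-max rather than
#' z-scoring. Genes with zero range across the batch (including the
#' single-cell case) map to 0.
#'
#' @param X An [expression_matrix()] with non-negative values.
#' @param target_total Common library size after step (1).
#' @return An `ExpressionMatrix` with values in \[0, 1\].
#' @export
normalize_expression <- function(X, target_total = 1e4) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  v <- X$values
  if (any(v < 0)) stop("negative values in batch '", X$batch_id, "'")
  totals <- rowSums(v)
  if (any(totals == 0)) {
    bad <- X$cell_ids[which(totals == 0)[1]]
    stop("cell '", bad, "' in batch '", X$batch_id,
         "' has zero total counts and cannot be normalized")
  }
  v <- log1p(v * (target_total / totals))
  mins <- apply(v, 2, min)
  maxs <- apply(v, 2, max)
  rng <- maxs - mins
  scale <- ifelse(rng > 0, 1 / rng, 0)
  v <- sweep(v, 2, mins, "-")
  v <- sweep(v, 2, scale, "*")
  expression_matrix(v, batch_id = X$batch_id, cell_ids = X$cell_ids,
                    gene_ids = X$gene_ids, labels = X$labels,
                    check_negative = FALSE)
}

# Per-gene dispersion (var/mean of log1p library-size-normalized values);
# genes with zero mean get dispersion 0.
.gene_dispersion <- function(X, target_total = 1e4) {
  v <- X$values
  totals <- rowSums(v)
  totals[totals == 0] <- 1
  v <- log1p(v * (target_total / totals))
  mu <- colMeans(v)
  va <- apply(v, 2, stats::var)
  if (nrow(v) < 2) va <- rep(0, ncol(v))
  d <- ifelse(mu > 0, va / mu, 0)
  names(d) <- X$gene_ids
  d
}

#' Select highly variable genes shared by all batches
#'
#' Dispersion (variance / mean of log-normalized expression) is computed per
#' gene within each batch and averaged over batches, restricted to genes
#' present in every batch. The top `num_hvg` genes are returned; ties are
#' broken lexicographically by gene id so the selection is deterministic.
#'
#' @param batches List of [expression_matrix()] (raw counts).
#' @param num_hvg Number of genes to return.
#' @return Character vector of `num_hvg` gene ids, ranked.
#' @export
select_hvg <- function(batches, num_hvg) {
  stopifnot(length(batches) >= 1)
  shared <- Reduce(intersect, lapply(batches, function(b) b$gene_ids))
  if (length(shared) == 0) stop("batches share no genes")
  if (num_hvg > length(shared))
    stop("num_hvg (", num_hvg, ") exceeds the ", length(shared),
         " genes shared by all batches")
  shared <- sort(shared)
  disp <- rowMeans(vapply(batches,
                          function(b) .gene_dispersion(b)[shared],
                          numeric(length(shared))))
  ord <- order(-disp, shared)
  shared[ord][seq_len(num_hvg)]
}

#' Restrict a batch to a gene subset, in the given order
#'
#' @param X An [expression_matrix()].
#' @param genes Gene ids, all present in `X`.
#' @return An `ExpressionMatrix` over `genes`.
#' @export
subset_genes <- function(X, genes) {
  missing <- setdiff(genes, X$gene_ids)
  if (length(missing))
    stop(length(missing), " gene(s) absent from batch '", X$batch_id, "'")
  expression_matrix(X$values[, genes, drop = FALSE], batch_id = X$batch_id,
                    cell_ids = X$cell_ids, gene_ids = genes,
                    labels = X$labels, check_negative = FALSE)
}

# kNN graph (undirected union of directed k-nearest-neighbour edges) on the
# rows of a coordinate matrix. Returns an igraph graph.
.knn_graph <- function(coords, k) {
  n <- nrow(coords)
  if (k >= n) stop("knn_k (", k, ") must be < number of cells (", n, ")")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  nbr <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  edges <- rbind(rep(seq_len(n), each = k), as.vector(t(nbr)))
  g <- igraph::graph_from_edgelist(t(edges), directed = FALSE)
  igraph::simplify(g)
}

#' Cluster one batch with PCA -> kNN graph -> Louvain
#'
#' The essence of the standard graph-based scRNA-seq clustering pipeline:
#' PCA on the (normalized) expression matrix, a k-nearest-neighbour graph in
#' PC space (Euclidean), then Louvain community detection at the given
#' resolution. Deterministic for a fixed seed.
#'
#' @param X Normalized [expression_matrix()].
#' @param knn_k Number of neighbours.
#' @param resolution Louvain resolution parameter.
#' @param seed Integer seed.
#' @param n_pcs Number of principal components (capped by the data).
#' @return A `ClusterAssignment`: list with `batch_id`, `cluster_of` (named
#'   integer vector of 0-based contiguous cluster indices per cell) and
#'   `n_clusters`.
#' @export
cluster_cells <- function(X, knn_k = 15, resolution = 1, seed = 0,
                          n_pcs = 50) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  n <- nrow(X$values)
  if (n < knn_k + 1)
    stop("need at least knn_k + 1 = ", knn_k + 1, " cells, got ", n)
  pcs <- .pca_embed(X$values, n_pcs)
  g <- .knn_graph(pcs, knn_k)
  comm <- withr::with_seed(as.integer(seed),
    igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  # relabel to 0-based contiguous, largest cluster first for stability
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  cluster_of <- unname(relab[as.character(memb)])
  names(cluster_of) <- X$cell_ids
  structure(list(batch_id = X$batch_id, cluster_of = cluster_of,
                 n_clusters = length(sizes)),
            class = "ClusterAssignment")
}

# PCA embedding of the rows of a matrix; rank capped by dimensions.
.pca_embed <- function(values, n_pcs) {
  r <- min(n_pcs, nrow(values) - 1L, ncol(values))
  p <- stats::prcomp(values, center = TRUE, scale. = FALSE, rank. = r)
  coords <- p$x
  rownames(coords) <- rownames(values)
  coords
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment '", x$batch_id, "': ", length(x$cluster_of),
      " cells in ", x$n_clusters, " cluster(s)\n", sep = "")
  invisible(x)
}
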