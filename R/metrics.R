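#' Batch-mixing divergence between two embeddings
#'
#' Symmetric k-nearest-neighbour estimate of the Kullback-Leibler divergence
#' between the two batches' embedding distributions, restricted to cell
#' types present in both batches (so batch-exclusive populations cannot
#' inflate the estimate), averaged over the two directions and clipped below
#' at 0. Lower is better: 0 means the shared-type cells of the two batches
#' are drawn from indistinguishable distributions.
#'
#' The one-directional estimator is the classical nearest-neighbour form
#' `KL(P||Q) ~= (d/n) * sum_i log(nu_k(i) / rho_k(i)) + log(m / (n - 1))`
#' with `rho_k` the distance of a P-point to its k-th neighbour within P and
#' `nu_k` to its k-th neighbour in Q.
#'
#' @param Z_a,Z_b Embedding matrices (cells x dims, equal dims).
#' @param labels_a,labels_b Per-cell type labels.
#' @param k Neighbour order; effective k is `min(k, floor(n/10))`, at least 1.
#' @return Non-negative scalar.
#' @export
divergence_score <- function(Z_a, Z_b, labels_a, labels_b, k = 25) {
  Z_a <- as.matrix(Z_a); Z_b <- as.matrix(Z_b)
  if (ncol(Z_a) != ncol(Z_b)) stop("embedding dimensions differ")
  if (nrow(Z_a) != length(labels_a) || nrow(Z_b) != length(labels_b))
    stop("labels must have one entry per embedded cell")
  shared <- intersect(unique(labels_a), unique(labels_b))
  if (!length(shared)) stop("batches share no cell types")
  A <- Z_a[labels_a %in% shared, , drop = FALSE]
  B <- Z_b[labels_b %in% shared, , drop = FALSE]
  kl <- function(P, Q) {
    n <- nrow(P); m <- nrow(Q); d <- ncol(P)
    kk <- max(1L, min(as.integer(k), floor(n / 10), n - 1L, m))
    dPP <- sqrt(.sqdist(P, P))
    dPQ <- sqrt(.sqdist(P, Q))
    rho <- apply(dPP, 1, function(r) sort(r)[kk + 1])  # skip self
    nu <- apply(dPQ, 1, function(r) sort(r)[kk])
    eps <- 1e-12
    (d / n) * sum(log((nu + eps) / (rho + eps))) + log(m / (n - 1))
  }
  max(0, (kl(A, B) + kl(B, A)) / 2)
}

#' Mean silhouette width
#'
#' For each cell, `a` is the mean distance to cells sharing its label and
#' `b` the smallest mean distance to any other label; the cell's score is
#' `(b - a) / max(a, b)`, and cells in singleton labels score 0. Returns the
#' mean over cells. Higher means labels form tighter, better-separated
#' clusters in the embedding.
#'
#' @param Z Embedding matrix (cells x dims).
#' @param labels Per-cell labels; at least two distinct values required.
#' @return Scalar in \[-1, 1\].
#' @export
silhouette_score <- function(Z, labels) {
  Z <- as.matrix(Z)
  labels <- as.character(labels)
  if (nrow(Z) != length(labels)) stop("one label per cell required")
  if (length(unique(labels)) < 2)
    stop("silhouette requires at least two distinct labels")
  d <- as.matrix(stats::dist(Z))
  uniq <- unique(labels)
  sizes <- table(labels)
  s <- numeric(nrow(Z))
  for (i in seq_len(nrow(Z))) {
    li <- labels[i]
    if (sizes[[li]] == 1) { s[i] <- 0; next }
    a <- sum(d[i, labels == li]) / (sizes[[li]] - 1)
    b <- min(vapply(uniq[uniq != li],
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same cells,
#' computed from the contingency table with the standard expected-index
#' correction. 1 means identical partitions (up to label names); values
#' near 0 mean chance-level agreement.
#'
#' @param pred,truth Equal-length label vectors.
#' @return Scalar `<= 1`.
#' @export
ari <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors differ in length")
  if (!length(pred)) stop("empty labelings")
  tab <- table(pred, truth)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(pred)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Evaluate a corrected embedding against ground truth
#'
#' Clusters the combined embedding with the same kNN-graph + Louvain
#' machinery used for per-batch clustering and scores it with ARI against
#' the true labels; computes the mean silhouette on the true labels; and
#' averages [divergence_score()] over all unordered batch pairs. Because
#' Louvain's granularity is resolution-dependent, each clustering run scans
#' a small resolution grid and keeps the best ARI (the convention of
#' embedding-quality benchmarks); the identical protocol applies to any
#' embedding, so corrected/uncorrected comparisons stay fair. Clustering is
#' repeated over `n_runs` seeds derived from `config$seed` and the report
#' gives mean and sd for each metric (silhouette and divergence are
#' deterministic given the embedding, so their sd is 0).
#'
#' @param result An `EmbeddingResult`, or any data.frame/matrix embedding
#'   with `cell_id`/`batch_id` columns.
#' @param true_labels Named character vector (names = cell ids) or unnamed
#'   vector in combined-row order.
#' @param config A [bermad_config()]; supplies seed and knn_k.
#' @param n_runs Number of clustering repeats.
#' @param resolutions Louvain resolution grid scanned for the ARI.
#' @return A `MetricsReport`: list with `divergence`, `silhouette`, `ari`
#'   (each `c(mean, sd)`), and `n_runs`.
#' @export
evaluate_embedding <- function(result, true_labels, config = bermad_config(),
                               n_runs = 3,
                               resolutions = c(0.1, 0.25, 0.5, 0.75, 1)) {
  df <- if (inherits(result, "EmbeddingResult")) result$combined else
    as.data.frame(result)
  zcols <- grep("^z_", colnames(df))
  Z <- as.matrix(df[, zcols, drop = FALSE])
  if (!is.null(names(true_labels))) {
    missing <- setdiff(df$cell_id, names(true_labels))
    if (length(missing))
      stop("labels missing for ", length(missing), " cells")
    labs <- unname(true_labels[df$cell_id])
  } else {
    if (length(true_labels) != nrow(df))
      stop("labels must cover all cells")
    labs <- as.character(true_labels)
  }
  sil <- silhouette_score(Z, labs)
  bids <- unique(df$batch_id)
  divs <- c()
  if (length(bids) >= 2) {
    for (i in seq_len(length(bids) - 1)) for (j in seq(i + 1, length(bids))) {
      ra <- df$batch_id == bids[i]; rb <- df$batch_id == bids[j]
      divs <- c(divs, divergence_score(Z[ra, , drop = FALSE],
                                       Z[rb, , drop = FALSE],
                                       labs[ra], labs[rb]))
    }
  }
  div <- if (length(divs)) mean(divs) else NA_real_
  # build the graph once; Louvain is re-run per seed and resolution
  pcs <- .pca_embed(Z, config$n_pcs)
  g <- .knn_graph(pcs, min(config$knn_k, nrow(Z) - 1L))
  aris <- vapply(seq_len(n_runs), function(r) {
    max(vapply(resolutions, function(res) {
      memb <- withr::with_seed(derive_seed(config$seed, 1000 + r),
        igraph::membership(igraph::cluster_louvain(g, resolution = res)))
      ari(as.integer(memb), labs)
    }, numeric(1)))
  }, numeric(1))
  structure(list(
    divergence = c(mean = div, sd = 0),
    silhouette = c(mean = sil, sd = 0),
    ari = c(mean = mean(aris), sd = stats::sd(aris)),
    n_runs = n_runs), class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  fmt <- function(v) sprintf("%.2f±%.2f", v["mean"], v["sd"])
  cat("MetricsReport (", x$n_runs, " clustering runs)\n",
      "  Divergence: ", fmt(x$divergence), "\n",
      "  Silhouette: ", fmt(x$silhouette), "\n",
      "  ARI:        ", fmt(x$ari), "\n", sep = "")
  invisible(x)
}

#' Write a metrics report as JSON and/or a one-row CSV
#'
#' @param report A `MetricsReport`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @export
write_metrics_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(list(divergence = as.list(report$divergence),
                              silhouette = as.list(report$silhouette),
                              ari = as.list(report$ari),
                              n_runs = report$n_runs),
                         json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    data.table::fwrite(data.frame(
      Divergence = report$divergence["mean"],
      Silhouette = report$silhouette["mean"],
      ARI = report$ari["mean"]), csv_path)
  invisible(report)
}
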