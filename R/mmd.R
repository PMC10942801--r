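#' Multi-scale Gaussian kernel specification
#'
#' The kernel used by the transfer loss is a sum of Gaussians
#' `k(x, y) = sum_s exp(-||x - y||^2 / (2 * sigma2 * m_s))` over the scale
#' multipliers `m_s`, with the base bandwidth `sigma2` either fixed or set by
#' the median heuristic (median squared pairwise distance over the pooled
#' samples, recomputed per call and treated as a constant under
#' differentiation).
#'
#' @param base_bandwidth Positive number, or `"median"` for the median
#'   heuristic.
#' @param scale_multipliers Positive multipliers applied to the base
#'   bandwidth; default `c(0.25, 0.5, 1, 2, 4)`.
#' @return A `KernelSpec` list.
#' @export
kernel_spec <- function(base_bandwidth = "median",
                        scale_multipliers = c(0.25, 0.5, 1, 2, 4)) {
  if (!identical(base_bandwidth, "median")) {
    if (!is.numeric(base_bandwidth) || base_bandwidth <= 0)
      stop("'base_bandwidth' must be positive or \"median\"")
  }
  if (length(scale_multipliers) < 1 || any(scale_multipliers <= 0))
    stop("need at least one positive scale multiplier")
  structure(list(base_bandwidth = base_bandwidth,
                 scale_multipliers = scale_multipliers),
            class = "KernelSpec")
}

# Squared Euclidean distance matrix between rows of A and rows of B.
.sqdist <- function(A, B) {
  an <- rowSums(A * A)
  bn <- rowSums(B * B)
  d <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}

# Base bandwidth sigma2 for a pair of samples.
.bandwidth <- function(A, B, kernel) {
  if (!identical(kernel$base_bandwidth, "median"))
    return(kernel$base_bandwidth)
  m <- .median_sqdist_cpp(rbind(A, B))
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Squared maximum mean discrepancy between two samples
#'
#' Biased (V-statistic) estimator
#' `MMD^2 = mean(k(A, A)) + mean(k(B, B)) - 2 * mean(k(A, B))`, which is
#' non-negative and well defined down to single-observation samples. The
#' kernel is the multi-scale Gaussian of [kernel_spec()].
#'
#' @param A,B Numeric matrices (observations x dimensions), equal column
#'   counts.
#' @param kernel A [kernel_spec()].
#' @return Non-negative scalar.
#' @export
mmd2 <- function(A, B, kernel = kernel_spec()) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("dimension mismatch: ", ncol(A), " vs ", ncol(B), " columns")
  if (nrow(A) < 1 || nrow(B) < 1) stop("samples must be non-empty")
  s2 <- .bandwidth(A, B, kernel)
  .mmd2_grad_cpp(A, B, s2, kernel$scale_multipliers, FALSE)$value
}

# mmd2 together with gradients with respect to the rows of A and B.
# The bandwidth is treated as a constant (not differentiated through).
.mmd2_grad <- function(A, B, kernel = kernel_spec()) {
  s2 <- .bandwidth(A, B, kernel)
  .mmd2_grad_cpp(A, B, s2, kernel$scale_multipliers, TRUE)
}

#' Cluster-pair transfer loss
#'
#' Sum of [mmd2()] over exactly the cluster pairs whose binarized mask is 1;
#' pairs with mask 0 contribute nothing (the similarity-weighted sum with
#' binary weights).
#'
#' @param embeddings_by_cluster Named list keyed `"<batch>|<cluster>"`, each
#'   element an embedding matrix of that cluster's cells.
#' @param table A binarized `SimilarityTable`.
#' @param kernel A [kernel_spec()].
#' @return Non-negative scalar.
#' @export
transfer_loss <- function(embeddings_by_cluster, table,
                          kernel = kernel_spec()) {
  if (any(is.na(table$mask)))
    stop("similarity table is not binarized; call binarize_similarity() first")
  total <- 0
  for (r in which(table$mask == 1)) {
    ka <- paste0(table$batch_a[r], "|", table$cluster_a[r])
    kb <- paste0(table$batch_b[r], "|", table$cluster_b[r])
    A <- embeddings_by_cluster[[ka]]
    B <- embeddings_by_cluster[[kb]]
    if (is.null(A) || is.null(B) || nrow(A) == 0 || nrow(B) == 0)
      stop("masked pair (", ka, ", ", kb, ") has no embedded cells")
    total <- total + mmd2(A, B, kernel)
  }
  total
}
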