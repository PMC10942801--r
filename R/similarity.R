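#' Score cross-batch cluster pairs by neighbour voting (MetaNeighbor-style)
#'
#' For every unordered pair of batches and every cross-batch pair of their
#' clusters, computes a replicability score in \[0, 1\]: each cell's HVG
#' profile is rank-standardized within the cell, a cell-cell Spearman
#' correlation network is built between the two batches, cells of cluster i
#' in batch a vote for cells of batch b (mean correlation to the cluster),
#' and the votes are summarized as the AUROC of cluster j's cells versus the
#' rest of batch b. The two directions' AUROCs are averaged, which makes the
#' score symmetric. This is the deterministic "fast" formulation of
#' MetaNeighbor (rank-based voting, one-vs-rest AUROC) rather than the
#' original cross-validated form.
#'
#' Within-batch pairs are never scored. Pairs involving a cluster with fewer
#' than 2 cells are still scored but flagged in the `small` column.
#'
#' @param batches List of normalized [expression_matrix()] objects.
#' @param clusters List of `ClusterAssignment`s, parallel to `batches`.
#' @param hvg Character vector of genes to vote on (present in all batches).
#' @return A `SimilarityTable` data.frame with columns `batch_a`,
#'   `cluster_a`, `batch_b`, `cluster_b`, `score`, `mask` (NA until
#'   [binarize_similarity()] is applied) and `small`.
#' @export
metaneighbor_scores <- function(batches, clusters, hvg) {
  if (length(batches) < 2) stop("need >= 2 batches to score cluster pairs")
  if (length(clusters) != length(batches))
    stop("'clusters' must parallel 'batches'")
  if (length(hvg) == 0) stop("empty HVG list")
  ranked <- lapply(batches, function(b) {
    v <- subset_genes(b, hvg)$values
    t(apply(v, 1, rank))  # rank genes within each cell (average ties)
  })
  rows <- list()
  for (a in seq_len(length(batches) - 1)) {
    for (b in seq(a + 1, length(batches))) {
      C <- stats::cor(t(ranked[[a]]), t(ranked[[b]]))  # Spearman via ranks
      ca <- clusters[[a]]$cluster_of
      cb <- clusters[[b]]$cluster_of
      for (i in sort(unique(ca))) {
        for (j in sort(unique(cb))) {
          mem_a <- which(ca == i)
          mem_b <- which(cb == j)
          # direction a -> b: cluster i votes over batch b's cells
          votes_b <- colMeans(C[mem_a, , drop = FALSE])
          au_ab <- .auroc(votes_b, seq_along(votes_b) %in% mem_b)
          votes_a <- rowMeans(C[, mem_b, drop = FALSE])
          au_ba <- .auroc(votes_a, seq_along(votes_a) %in% mem_a)
          rows[[length(rows) + 1L]] <- data.frame(
            batch_a = batches[[a]]$batch_id, cluster_a = i,
            batch_b = batches[[b]]$batch_id, cluster_b = j,
            score = mean(c(au_ab, au_ba)), mask = NA_integer_,
            small = length(mem_a) < 2 || length(mem_b) < 2,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("SimilarityTable", class(tab))
  tab
}

# Rank-sum (Mann-Whitney) AUROC of scores for positives vs the rest.
.auroc <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binarize cluster-pair similarity scores
#'
#' Sets `mask = 1` for pairs with `score >= thr` (the boundary is inclusive)
#' and 0 otherwise; scores are left untouched. Only masked pairs contribute
#' to the transfer loss during training.
#'
#' @param table A `SimilarityTable`.
#' @param thr Threshold in \[0, 1\].
#' @return The table with its `mask` column filled.
#' @export
binarize_similarity <- function(table, thr) {
  if (!is.numeric(thr) || thr < 0 || thr > 1) stop("'thr' must lie in [0, 1]")
  table$mask <- as.integer(table$score >= thr)
  table
}
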