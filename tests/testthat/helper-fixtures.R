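# Small in-code fixtures shared across test files.

# Gaussian blob data with known group labels: one matrix per batch.
make_blobs <- function(n_per_group, centers, noise = 0.5, seed = 1,
                       batch_id = "batch1", shift = 0) {
  withr::with_seed(seed, {
    k <- nrow(centers)
    X <- do.call(rbind, lapply(seq_len(k), function(g)
      matrix(rnorm(n_per_group * ncol(centers), mean = 0, sd = noise),
             n_per_group) + matrix(centers[g, ], n_per_group,
                                   ncol(centers), byrow = TRUE)))
    X <- X + shift
    labels <- rep(paste0("G", seq_len(k)), each = n_per_group)
    rownames(X) <- paste0(batch_id, "_c", seq_len(nrow(X)))
    colnames(X) <- paste0("gene", seq_len(ncol(X)))
    list(X = X, labels = labels)
  })
}

# wrap a plain matrix (possibly with negatives) as an ExpressionMatrix
as_expr <- function(X, batch_id = "batch1", labels = NULL) {
  expression_matrix(X, batch_id = batch_id, labels = labels,
                    check_negative = FALSE)
}

# a ClusterAssignment built directly from known labels
make_clusters <- function(batch_id, labels, cell_ids) {
  ids <- sort(unique(labels))
  cluster_of <- match(labels, ids) - 1L
  names(cluster_of) <- cell_ids
  structure(list(batch_id = batch_id, cluster_of = cluster_of,
                 n_clusters = length(ids)), class = "ClusterAssignment")
}

# tiny raw-count simulation for fast pipeline tests
small_sim <- function(seed = 11, batch_sizes = c(120L, 100L), n_groups = 3,
                      n_genes = 300, ...) {
  simulate_batches(simulation_params(
    n_genes = n_genes, batch_sizes = batch_sizes, n_groups = n_groups,
    de_prob = 0.2, de_factor = 8, batch_factor_scale = 0.4,
    library_size_mean = 2000, seed = seed, ...))
}

sim_labels <- function(sim) {
  stats::setNames(unlist(lapply(sim$batches, function(b) b$labels)),
                  unlist(lapply(sim$batches, function(b) b$cell_ids)))
}
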