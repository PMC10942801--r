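#' Parameters for the multi-batch count simulator
#'
#' The generator emulates the statistical structure of splatter-style
#' multi-batch scRNA-seq data: gamma-distributed baseline gene means, a
#' `de_prob` fraction of genes per cell group carrying multiplicative
#' differential-expression factors (group identity), a log-normal per-batch
#' per-gene multiplicative factor (batch effect), per-cell log-normal
#' library sizes, and Poisson sampling of counts. `group_probs` is a
#' batches x groups matrix of mixing proportions; zero entries create
#' batch-exclusive cell types.
#'
#' @param n_genes Number of genes.
#' @param batch_sizes Integer vector of cells per batch (default
#'   `c(2000, 1000)`, the two-batch benchmark shape).
#' @param n_groups Number of cell groups (types).
#' @param group_probs Optional batches x groups probability matrix, rows
#'   summing to 1; default uniform over groups for every batch.
#' @param de_prob Fraction of genes differentially expressed per group.
#' @param de_factor Multiplicative strength of DE genes (applied as
#'   `de_factor` or `1/de_factor` with equal probability).
#' @param batch_factor_scale sdlog of the per-batch per-gene log-normal
#'   factor; 0 disables batch effect.
#' @param library_size_mean Expected per-cell total count.
#' @param seed Integer seed; generation is deterministic given it.
#' @return A `SimulationParams` list.
#' @export
simulation_params <- function(n_genes = 2000, batch_sizes = c(2000L, 1000L),
                              n_groups = 3, group_probs = NULL,
                              de_prob = 0.1, de_factor = 4,
                              batch_factor_scale = 0.25,
                              library_size_mean = 5000, seed = 0L) {
  nb <- length(batch_sizes)
  if (is.null(group_probs))
    group_probs <- matrix(1 / n_groups, nb, n_groups)
  group_probs <- as.matrix(group_probs)
  if (nrow(group_probs) != nb || ncol(group_probs) != n_groups)
    stop("group_probs must be ", nb, " x ", n_groups)
  if (any(abs(rowSums(group_probs) - 1) > 1e-8))
    stop("group_probs rows must sum to 1")
  if (any(colSums(group_probs) == 0))
    stop("group ", which(colSums(group_probs) == 0)[1],
         " has zero probability in every batch")
  if (n_genes < 1 || any(batch_sizes < 1) || de_prob < 0 || de_prob > 1 ||
      de_factor < 1 || batch_factor_scale < 0 || library_size_mean <= 0)
    stop("invalid simulation parameters")
  structure(list(n_genes = as.integer(n_genes),
                 batch_sizes = as.integer(batch_sizes),
                 n_groups = as.integer(n_groups), group_probs = group_probs,
                 de_prob = de_prob, de_factor = de_factor,
                 batch_factor_scale = batch_factor_scale,
                 library_size_mean = library_size_mean,
                 seed = as.integer(seed)), class = "SimulationParams")
}

#' Simulate multi-batch scRNA-seq counts with ground truth
#'
#' Gamma-Poisson generative model: per-gene base means
#' `~ Gamma(shape 0.6, rate 0.3)`; per-group DE multipliers on a random
#' `de_prob` fraction of genes; per-batch log-normal factors on every gene;
#' per-cell library-size scaling so the expected total count equals
#' `library_size_mean`; Poisson counts.
#'
#' @param params A [simulation_params()].
#' @return List with `batches` (list of labelled [expression_matrix()]s) and
#'   `truth` (group means, DE gene sets, batch factors, parameters).
#' @export
simulate_batches <- function(params = simulation_params()) {
  stopifnot(inherits(params, "SimulationParams"))
  G <- params$n_genes; K <- params$n_groups
  nb <- length(params$batch_sizes)
  withr::with_seed(params$seed, {
    base_mean <- stats::rgamma(G, shape = 0.6, rate = 0.3)
    de_sets <- list(); group_mean <- matrix(rep(base_mean, K), G, K)
    n_de <- max(1L, round(params$de_prob * G))
    for (k in seq_len(K)) {
      idx <- sample.int(G, n_de)
      fac <- ifelse(stats::runif(n_de) < 0.5, params$de_factor,
                    1 / params$de_factor)
      group_mean[idx, k] <- group_mean[idx, k] * fac
      de_sets[[k]] <- idx
    }
    batch_factors <- matrix(
      stats::rlnorm(G * nb,
                    meanlog = -params$batch_factor_scale^2 / 2,
                    sdlog = params$batch_factor_scale), G, nb)
    sdlog_lib <- 0.35
    batches <- vector("list", nb)
    for (b in seq_len(nb)) {
      n <- params$batch_sizes[b]
      groups <- sample.int(K, n, replace = TRUE,
                           prob = params$group_probs[b, ])
      libs <- stats::rlnorm(n, meanlog = log(params$library_size_mean) -
                              sdlog_lib^2 / 2, sdlog = sdlog_lib)
      mu <- group_mean * batch_factors[, b]       # G x K
      prop <- sweep(mu, 2, colSums(mu), "/")      # expression proportions
      lam <- t(prop[, groups, drop = FALSE]) * libs
      counts <- matrix(stats::rpois(n * G, as.vector(lam)), n, G)
      rownames(counts) <- sprintf("b%d_cell%04d", b, seq_len(n))
      colnames(counts) <- sprintf("gene%04d", seq_len(G))
      batches[[b]] <- expression_matrix(
        counts, batch_id = paste0("batch", b),
        labels = paste0("Group", groups))
    }
    list(batches = batches,
         truth = list(group_mean = group_mean, de_sets = de_sets,
                      batch_factors = batch_factors, params = params))
  })
}

# pinned fixture definitions: the package's stated desk-scale worlds
.fixture_params <- function(name) {
  switch(name,
    two_batch_same = simulation_params(
      n_genes = 1000, batch_sizes = c(2000L, 1000L), n_groups = 3,
      de_prob = 0.2, de_factor = 8, batch_factor_scale = 0.4,
      library_size_mean = 4000, seed = 20240301L),
    two_batch_diff = simulation_params(
      n_genes = 1000, batch_sizes = c(800L, 600L), n_groups = 5,
      group_probs = rbind(c(0.28, 0.28, 0.24, 0.20, 0),
                          c(0.28, 0.28, 0.24, 0, 0.20)),
      de_prob = 0.2, de_factor = 8, batch_factor_scale = 0.4,
      library_size_mean = 4000, seed = 20240302L),
    three_batch = simulation_params(
      n_genes = 1000, batch_sizes = c(500L, 800L, 600L), n_groups = 4,
      group_probs = rbind(c(0.36, 0.34, 0.30, 0),
                          c(0.28, 0.26, 0.24, 0.22),
                          c(0.36, 0.34, 0, 0.30)),
      de_prob = 0.2, de_factor = 8, batch_factor_scale = 0.4,
      library_size_mean = 4000, seed = 20240303L),
    stop("unknown fixture name: ", name))
}

#' Write a named simulation fixture to disk
#'
#' Three pinned scenarios: `two_batch_same` (2000 + 1000 cells, 3 shared
#' groups), `two_batch_diff` (one batch-exclusive group per batch) and
#' `three_batch` (3 batches with a shared core plus batch-specific absences,
#' the multi-batch shape). Writes one expression CSV and one (cell_id,
#' label) CSV per batch; seeds are pinned so repeated calls are
#' byte-identical.
#'
#' @param name One of `"two_batch_same"`, `"two_batch_diff"`,
#'   `"three_batch"`.
#' @param dir Output directory (created if needed).
#' @param seed Optional seed override (default: the scenario's pinned seed).
#' @return Invisibly, a list of the written file paths and the parameters.
#' @export
make_fixture <- function(name = c("two_batch_same", "two_batch_diff",
                                  "three_batch"), dir, seed = NULL) {
  name <- match.arg(name)
  params <- .fixture_params(name)
  if (!is.null(seed)) params$seed <- as.integer(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_batches(params)
  files <- list(matrices = character(0), labels = character(0))
  for (b in sim$batches) {
    mpath <- file.path(dir, paste0(name, "_", b$batch_id, ".csv"))
    lpath <- file.path(dir, paste0(name, "_", b$batch_id, "_labels.csv"))
    df <- data.frame(cell_id = b$cell_ids, b$values, check.names = FALSE)
    data.table::fwrite(df, mpath)
    data.table::fwrite(data.frame(cell_id = b$cell_ids, label = b$labels),
                       lpath)
    files$matrices <- c(files$matrices, mpath)
    files$labels <- c(files$labels, lpath)
  }
  invisible(c(files, list(params = params)))
}
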