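#' Run the full batch-correction pipeline
#'
#' End to end: select highly variable genes shared by all batches, normalize
#' each batch (library size, log1p, per-gene min-max), cluster each batch
#' independently (PCA -> kNN -> Louvain), score cross-batch cluster-pair
#' similarity by neighbour voting, binarize at `config$thr`, train the
#' dual-channel autoencoders with the multi-layer MMD transfer loss, and
#' extract the corrected embedding.
#'
#' @param batches List of raw-count [expression_matrix()]s, or a character
#'   vector of file paths understood by [read_expression()].
#' @param config A [bermad_config()].
#' @param verbose Print stage progress.
#' @return A `bermad_fit` list: `embedding` (`EmbeddingResult`), `models`,
#'   `history`, `similarity` (binarized table), `clusters`, `hvg`,
#'   `normalized` (the training inputs) and `config`.
#' @export
bermad_run <- function(batches, config = bermad_config(), verbose = FALSE) {
  if (is.character(batches))
    batches <- lapply(batches, read_expression)
  stopifnot(length(batches) >= 1,
            all(vapply(batches, inherits, logical(1), "ExpressionMatrix")))
  say <- function(...) if (verbose) message(...)

  say("selecting ", config$num_hvg, " highly variable genes")
  hvg <- select_hvg(batches, config$num_hvg)
  norm <- lapply(batches, function(b)
    normalize_expression(subset_genes(b, hvg)))

  say("clustering each batch")
  clusters <- lapply(seq_along(norm), function(i)
    cluster_cells(norm[[i]], knn_k = config$knn_k,
                  resolution = config$cluster_resolution,
                  seed = derive_seed(config$seed, 100 + i),
                  n_pcs = config$n_pcs))

  table <- NULL
  if (length(batches) >= 2) {
    say("scoring cross-batch cluster pairs")
    table <- metaneighbor_scores(norm, clusters, hvg)
    table <- binarize_similarity(table, config$thr)
    say(sum(table$mask), " of ", nrow(table), " cluster pairs masked in")
  }

  say("training (", config$epochs, " epochs, mode ", config$ablation_mode, ")")
  fit <- train_bermad(norm, clusters, table, config)
  embedding <- extract_embedding(fit$models, norm)

  structure(list(embedding = embedding, models = fit$models,
                 history = fit$history, similarity = table,
                 clusters = clusters, hvg = hvg, normalized = norm,
                 config = config), class = "bermad_fit")
}

#' @export
print.bermad_fit <- function(x, ...) {
  cat("bermad_fit: ", length(x$models), " channel(s), ",
      nrow(x$embedding$combined), " cells, ", length(x$hvg), " HVGs, ",
      nrow(x$history), " epochs\n", sep = "")
  if (!is.null(x$similarity))
    cat("  masked cluster pairs: ", sum(x$similarity$mask), " / ",
        nrow(x$similarity), "\n", sep = "")
  invisible(x)
}

#' Command-line interface
#'
#' Subcommands: `run` (correct batches), `simulate` (write a fixture
#' scenario), `evaluate` (score an embedding CSV against a label file). This
#' function backs the installed `exec/bermad` script.
#'
#' @param args Character vector of command-line arguments (first element the
#'   subcommand).
#' @return Exit status, invisibly.
#' @export
bermad_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: bermad <run|simulate|evaluate> [options]",
    "  run      --batches f1.csv,f2.csv [--labels l1.csv,l2.csv]",
    "           [--thr 0.85 --alpha 0.2 --beta 0.2 --gamma 0.2]",
    "           [--epochs N --seed S --num-hvg 2000 --config file]",
    "           [--ablation woMultiLayer|woDualChannel] --out dir/",
    "  simulate --scenario two_batch_same|two_batch_diff|three_batch",
    "           [--seed S] --out dir/",
    "  evaluate --embedding z.csv --labels l.csv [--out report.json]",
    sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  rest <- args[-1]
  switch(cmd,
         run = .cli_run(rest),
         simulate = .cli_simulate(rest),
         evaluate = .cli_evaluate(rest),
         { cat(usage, "\n"); invisible(1L) })
}

.cli_run <- function(args) {
  ol <- list(
    optparse::make_option("--batches", type = "character"),
    optparse::make_option("--labels", type = "character", default = NULL),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--thr", type = "double", default = NA),
    optparse::make_option("--alpha", type = "double", default = NA),
    optparse::make_option("--beta", type = "double", default = NA),
    optparse::make_option("--gamma", type = "double", default = NA),
    optparse::make_option("--epochs", type = "integer", default = NA),
    optparse::make_option("--seed", type = "integer", default = NA),
    optparse::make_option("--num-hvg", dest = "num_hvg", type = "integer",
                          default = NA),
    optparse::make_option("--ablation", type = "character", default = NA),
    optparse::make_option("--out", type = "character"))
  o <- optparse::parse_args(optparse::OptionParser(option_list = ol),
                            args = args)
  if (is.null(o$batches) || is.null(o$out))
    stop("run: --batches and --out are required")
  overrides <- list(thr = o$thr, alpha = o$alpha, beta = o$beta,
                    gamma = o$gamma, epochs = o$epochs, seed = o$seed,
                    num_hvg = o$num_hvg, ablation_mode = o$ablation)
  overrides <- overrides[!vapply(overrides, function(v)
    is.null(v) || (is.atomic(v) && is.na(v)), logical(1))]
  config <- read_config(o$config, overrides)
  paths <- strsplit(o$batches, ",")[[1]]
  lpaths <- if (!is.null(o$labels)) strsplit(o$labels, ",")[[1]] else NULL
  batches <- lapply(seq_along(paths), function(i)
    read_expression(paths[i],
                    labels_path = if (!is.null(lpaths)) lpaths[i]))
  fit <- bermad_run(batches, config, verbose = TRUE)
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  write_embedding(fit$embedding, file.path(o$out, "embedding.csv"))
  if (!is.null(fit$similarity))
    write_similarity(fit$similarity, file.path(o$out, "similarity.csv"))
  save_checkpoint(list(models = fit$models, history = fit$history,
                       config = config), file.path(o$out, "checkpoint"))
  message("wrote ", file.path(o$out, "embedding.csv"))
  invisible(0L)
}

.cli_simulate <- function(args) {
  ol <- list(
    optparse::make_option("--scenario", type = "character",
                          default = "two_batch_same"),
    optparse::make_option("--seed", type = "integer", default = NA),
    optparse::make_option("--out", type = "character"))
  o <- optparse::parse_args(optparse::OptionParser(option_list = ol),
                            args = args)
  if (is.null(o$out)) stop("simulate: --out is required")
  seed <- if (is.na(o$seed)) NULL else o$seed
  files <- make_fixture(o$scenario, o$out, seed = seed)
  message("wrote ", length(files$matrices), " matrix file(s) to ", o$out)
  invisible(0L)
}

.cli_evaluate <- function(args) {
  ol <- list(
    optparse::make_option("--embedding", type = "character"),
    optparse::make_option("--labels", type = "character"),
    optparse::make_option("--seed", type = "integer", default = 0L),
    optparse::make_option("--out", type = "character", default = NULL))
  o <- optparse::parse_args(optparse::OptionParser(option_list = ol),
                            args = args)
  if (is.null(o$embedding) || is.null(o$labels))
    stop("evaluate: --embedding and --labels are required")
  emb <- read_embedding(o$embedding)
  labs <- read_labels(o$labels)
  report <- evaluate_embedding(emb, labs, bermad_config(seed = o$seed))
  print(report)
  if (!is.null(o$out)) write_metrics_report(report, json_path = o$out)
  invisible(0L)
}
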