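#' Transfer-loss weight schedule
#'
#' `lambda(p) = 2 / (1 + exp(-10 p / n)) - 1`, increasing from 0 at `p = 0`
#' towards (but never reaching) 1 at `p = n`. Early training therefore
#' optimizes reconstruction (finding a good low-dimensional representation)
#' and later training phases in the cluster-matching transfer loss.
#'
#' @param p Current epoch, `0 <= p <= n`.
#' @param n Total number of epochs, `>= 1`.
#' @return Scalar in \[0, 1).
#' @export
lambda_schedule <- function(p, n) {
  if (any(n < 1)) stop("'n' must be >= 1")
  if (any(p < 0) || any(p > n)) stop("'p' must lie in [0, n]")
  2 / (1 + exp(-10 * p / n)) - 1
}

# layer -> Eq.4 weight, honouring the woMultiLayer ablation.
.layer_weights <- function(config) {
  w <- c(h1 = config$alpha, h2 = config$beta, z = config$gamma)
  if (config$ablation_mode == "woMultiLayer") w[c("h1", "h2")] <- 0
  w
}

#' Train the dual-channel autoencoders
#'
#' One autoencoder (channel) per batch, identical architecture, unshared
#' weights (`ablation_mode = "woDualChannel"` shares a single model across
#' all batches instead). Every epoch performs one full-batch Adam step on
#' the total loss: the per-channel reconstruction losses plus the
#' schedule-weighted multi-layer transfer loss, where the transfer loss is
#' the sum over all mask = 1 cross-batch cluster pairs of the multi-scale
#' Gaussian-kernel squared MMD computed at layers h1, h2 and z (weighted by
#' alpha, beta, gamma). With more than two batches the sum simply extends
#' over the masked pairs of every unordered batch pair, so a batch sharing
#' no cell type with the others trains as a plain autoencoder.
#'
#' @param batches List of normalized, HVG-restricted [expression_matrix()]s.
#' @param clusters List of `ClusterAssignment`s parallel to `batches`.
#' @param table Binarized `SimilarityTable` (may have zero masked rows; with
#'   a single batch pass `NULL` for pure autoencoding).
#' @param config A [bermad_config()].
#' @param kernel A [kernel_spec()] for the transfer MMD.
#' @return List with `models` (one `ChannelModel` per batch; under
#'   woDualChannel the same model repeated), `history` (one `LossBreakdown`
#'   row per epoch: per-channel mean reconstruction losses, per-layer
#'   transfer losses, `l_tran`, `lambda_p`, `total`) and `config`.
#' @export
train_bermad <- function(batches, clusters, table, config = bermad_config(),
                         kernel = kernel_spec()) {
  B <- length(batches)
  stopifnot(B >= 1)
  D <- ncol(batches[[1]]$values)
  for (b in batches) if (ncol(b$values) != D)
    stop("all batches must share the same gene set")
  batch_ids <- vapply(batches, function(b) b$batch_id, character(1))
  shared <- config$ablation_mode == "woDualChannel"

  if (shared) {
    m0 <- init_channel(D, seed = derive_seed(config$seed, 1),
                       hidden_dims = config$hidden_dims,
                       batch_id = paste(batch_ids, collapse = "+"))
    models <- rep(list(m0), B)
    states <- list(.adam_init(m0$params))
  } else {
    models <- lapply(seq_len(B), function(b)
      init_channel(D, seed = derive_seed(config$seed, b),
                   hidden_dims = config$hidden_dims, batch_id = batch_ids[b]))
    states <- lapply(models, function(m) .adam_init(m$params))
  }

  # resolve masked pairs once: batch indices + member row indices
  pairs <- list()
  if (!is.null(table) && nrow(table)) {
    if (any(is.na(table$mask)))
      stop("similarity table is not binarized; call binarize_similarity()")
    for (r in which(table$mask == 1)) {
      a <- match(table$batch_a[r], batch_ids)
      b <- match(table$batch_b[r], batch_ids)
      if (is.na(a) || is.na(b))
        stop("similarity table names batch absent from 'batches'")
      ra <- which(clusters[[a]]$cluster_of == table$cluster_a[r])
      rb <- which(clusters[[b]]$cluster_of == table$cluster_b[r])
      if (!length(ra) || !length(rb))
        stop("masked pair row ", r, " resolves to an empty cluster")
      # cap cluster size entering the kernel estimator (fixed, seeded draw)
      cap <- config$mmd_max_cells
      if (is.finite(cap)) {
        if (length(ra) > cap)
          ra <- withr::with_seed(derive_seed(config$seed, 500 + r),
                                 sort(sample(ra, cap)))
        if (length(rb) > cap)
          rb <- withr::with_seed(derive_seed(config$seed, 700 + r),
                                 sort(sample(rb, cap)))
      }
      pairs[[length(pairs) + 1L]] <- list(a = a, b = b, ra = ra, rb = rb)
    }
  }

  lw <- .layer_weights(config)
  Xs <- lapply(batches, function(b) b$values)
  ns <- vapply(Xs, nrow, integer(1))
  layers <- c("h1", "z", "h2")
  hist_rows <- vector("list", config$epochs)

  for (p in seq_len(config$epochs)) {
    lam <- lambda_schedule(p, config$epochs)
    fcs <- lapply(seq_len(B), function(b) .forward_cache(models[[b]], Xs[[b]]))
    rec <- vapply(seq_len(B),
                  function(b) sum((Xs[[b]] - fcs[[b]]$x_prime)^2) / ns[b],
                  numeric(1))
    g_xp <- lapply(seq_len(B),
                   function(b) 2 * (fcs[[b]]$x_prime - Xs[[b]]) / ns[b])

    ltr <- c(h1 = 0, z = 0, h2 = 0)
    g_tr <- NULL
    if (lam > 0 && length(pairs)) {
      g_tr <- lapply(seq_len(B), function(b)
        lapply(stats::setNames(layers, layers), function(l) NULL))
      for (pr in pairs) {
        for (l in layers[lw[layers] > 0]) {
          res <- .mmd2_grad(fcs[[pr$a]][[l]][pr$ra, , drop = FALSE],
                            fcs[[pr$b]][[l]][pr$rb, , drop = FALSE], kernel)
          ltr[l] <- ltr[l] + res$value
          if (lw[l] > 0) {
            for (side in c("a", "b")) {
              bi <- pr[[side]]
              g <- if (side == "a") res$gA else res$gB
              if (is.null(g_tr[[bi]][[l]]))
                g_tr[[bi]][[l]] <- matrix(0, ns[bi], ncol(g))
              rows <- if (side == "a") pr$ra else pr$rb
              g_tr[[bi]][[l]][rows, ] <- g_tr[[bi]][[l]][rows, ] +
                lam * lw[l] * g
            }
          }
        }
      }
    }

    if (!all(is.finite(rec)))
      stop("non-finite reconstruction loss at epoch ", p)
    if (!all(is.finite(ltr)))
      stop("non-finite transfer loss at epoch ", p)
    l_tran <- multilayer_transfer_loss(ltr["h1"], ltr["h2"], ltr["z"],
                                       config$alpha, config$beta,
                                       config$gamma, config$ablation_mode)
    total <- total_loss(rec, l_tran, lam)

    grads <- lapply(seq_len(B), function(b)
      .backward(models[[b]], fcs[[b]], g_xp[[b]],
                g_h1 = if (!is.null(g_tr)) g_tr[[b]]$h1,
                g_z  = if (!is.null(g_tr)) g_tr[[b]]$z,
                g_h2 = if (!is.null(g_tr)) g_tr[[b]]$h2))

    if (shared) {
      gsum <- grads[[1]]
      if (B > 1) for (b in 2:B) for (nm in names(gsum))
        gsum[[nm]] <- gsum[[nm]] + grads[[b]][[nm]]
      upd <- .adam_step(models[[1]]$params, gsum, states[[1]],
                        config$learning_rate)
      models[[1]]$params <- upd$params
      states[[1]] <- upd$state
      for (b in seq_len(B)) models[[b]]$params <- models[[1]]$params
    } else {
      for (b in seq_len(B)) {
        upd <- .adam_step(models[[b]]$params, grads[[b]], states[[b]],
                          config$learning_rate)
        models[[b]]$params <- upd$params
        states[[b]] <- upd$state
      }
    }

    row <- c(list(epoch = p), as.list(stats::setNames(rec, paste0(
      "rec_", batch_ids))), list(l_h1 = unname(ltr["h1"]),
      l_h2 = unname(ltr["h2"]), l_z = unname(ltr["z"]),
      l_tran = unname(l_tran), lambda_p = lam, total = unname(total)))
    hist_rows[[p]] <- row
  }

  history <- do.call(rbind, lapply(hist_rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  list(models = models, history = history, config = config)
}

#' Extract the corrected embedding
#'
#' Runs every batch through its channel's encoder and returns the
#' 20-dimensional codes, per batch and row-concatenated in input order.
#'
#' @param models List of `ChannelModel`s parallel to `batches` (as returned
#'   by [train_bermad()]).
#' @param batches The normalized, HVG-restricted batches that were trained.
#' @return An `EmbeddingResult`: list with `per_batch` (named list of
#'   cells x code matrices) and `combined` (data.frame `cell_id`,
#'   `batch_id`, `z_1..z_k`).
#' @export
extract_embedding <- function(models, batches) {
  if (length(models) != length(batches))
    stop("need one channel per batch (got ", length(models), " channels, ",
         length(batches), " batches)")
  per_batch <- list()
  combined <- list()
  for (i in seq_along(batches)) {
    b <- batches[[i]]
    Z <- channel_forward(models[[i]], b$values)$z
    rownames(Z) <- b$cell_ids
    per_batch[[b$batch_id]] <- Z
    df <- data.frame(cell_id = b$cell_ids, batch_id = b$batch_id,
                     stringsAsFactors = FALSE)
    zdf <- as.data.frame(Z)
    colnames(zdf) <- paste0("z_", seq_len(ncol(Z)))
    combined[[i]] <- cbind(df, zdf, row.names = NULL)
  }
  structure(list(per_batch = per_batch,
                 combined = do.call(rbind, combined)),
            class = "EmbeddingResult")
}

#' @export
print.EmbeddingResult <- function(x, ...) {
  cat("EmbeddingResult: ", nrow(x$combined), " cells from ",
      length(x$per_batch), " batch(es), code dimension ",
      ncol(x$per_batch[[1]]), "\n", sep = "")
  invisible(x)
}

#' Save a training run as a checkpoint directory
#'
#' Writes one plain-text weight file per channel, the configuration as a
#' flat key=value file, and the loss history as CSV.
#'
#' @param fit Result of [train_bermad()].
#' @param dir Output directory (created if needed).
#' @export
save_checkpoint <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(fit$models))
    save_channel(fit$models[[i]], file.path(dir, paste0("channel_", i, ".txt")))
  cfg <- fit$config
  scal <- vapply(cfg, function(v) paste(v, collapse = " "), character(1))
  writeLines(paste(names(scal), scal, sep = " = "),
             file.path(dir, "config.txt"))
  data.table::fwrite(fit$history, file.path(dir, "history.csv"))
  invisible(dir)
}
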