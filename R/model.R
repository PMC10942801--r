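#' Initialize one channel's autoencoder
#'
#' The architecture is fixed to four affine maps
#' `D -> d1 -> d2 -> d3 -> D` (defaults 200, 20, 200), with ReLU on the three
#' hidden layers (outputs h1, z, h2) and a sigmoid output layer so the
#' reconstruction lives in \[0, 1\], matching min-max-scaled inputs. Weights
#' use Glorot uniform initialization seeded per channel, so channels are
#' independent but reproducible.
#'
#' @param input_dim Number of input features D (genes after HVG selection).
#' @param seed Integer seed for this channel's initialization.
#' @param hidden_dims Three hidden widths, default `c(200, 20, 200)`.
#' @param batch_id Batch this channel serves (bookkeeping only).
#' @return A `ChannelModel`.
#' @export
init_channel <- function(input_dim, seed = 0, hidden_dims = c(200L, 20L, 200L),
                         batch_id = NA_character_) {
  stopifnot(length(hidden_dims) == 3, input_dim >= 1)
  dims <- c(input_dim, hidden_dims, input_dim)
  pars <- withr::with_seed(as.integer(seed), {
    p <- list()
    for (l in 1:4) {
      fan_in <- dims[l]; fan_out <- dims[l + 1]
      lim <- sqrt(6 / (fan_in + fan_out))
      p[[paste0("W", l)]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim),
                                    fan_in, fan_out)
      p[[paste0("b", l)]] <- rep(0, fan_out)
    }
    p
  })
  structure(list(batch_id = batch_id, dims = dims, params = pars),
            class = "ChannelModel")
}

#' @export
print.ChannelModel <- function(x, ...) {
  cat("ChannelModel '", x$batch_id, "': ",
      paste(x$dims, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

.relu <- function(x) { x[x < 0] <- 0; x }
.sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass keeping pre-activations for backprop.
.forward_cache <- function(model, X) {
  p <- model$params
  A1 <- sweep(X %*% p$W1, 2, p$b1, "+");  h1 <- .relu(A1)
  A2 <- sweep(h1 %*% p$W2, 2, p$b2, "+"); z  <- .relu(A2)
  A3 <- sweep(z %*% p$W3, 2, p$b3, "+");  h2 <- .relu(A3)
  A4 <- sweep(h2 %*% p$W4, 2, p$b4, "+"); xp <- .sigmoid(A4)
  list(X = X, A1 = A1, h1 = h1, A2 = A2, z = z, A3 = A3, h2 = h2,
       A4 = A4, x_prime = xp)
}

#' Forward pass of a channel
#'
#' @param model A [init_channel()] model.
#' @param X Input matrix, `ncol(X)` must equal the channel's input dimension.
#' @return List with `h1` (n x d1), `z` (n x d2, the code), `h2` (n x d3) and
#'   `x_prime` (n x D, in \[0, 1\]).
#' @export
channel_forward <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$dims[1])
    stop("input has ", ncol(X), " columns; channel expects ", model$dims[1])
  fc <- .forward_cache(model, X)
  fc[c("h1", "z", "h2", "x_prime")]
}

# Backward pass: gradients of the scalar loss with respect to parameters,
# given upstream gradients at x_prime and (optionally) injected gradients at
# the intermediate outputs h1, z, h2 (from the transfer loss).
.backward <- function(model, fc, g_xp, g_h1 = NULL, g_z = NULL, g_h2 = NULL) {
  p <- model$params
  dA4 <- g_xp * fc$x_prime * (1 - fc$x_prime)
  gW4 <- crossprod(fc$h2, dA4); gb4 <- colSums(dA4)
  gh2 <- tcrossprod(dA4, p$W4)
  if (!is.null(g_h2)) gh2 <- gh2 + g_h2
  dA3 <- gh2 * (fc$A3 > 0)
  gW3 <- crossprod(fc$z, dA3); gb3 <- colSums(dA3)
  gz <- tcrossprod(dA3, p$W3)
  if (!is.null(g_z)) gz <- gz + g_z
  dA2 <- gz * (fc$A2 > 0)
  gW2 <- crossprod(fc$h1, dA2); gb2 <- colSums(dA2)
  gh1 <- tcrossprod(dA2, p$W2)
  if (!is.null(g_h1)) gh1 <- gh1 + g_h1
  dA1 <- gh1 * (fc$A1 > 0)
  gW1 <- crossprod(fc$X, dA1); gb1 <- colSums(dA1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

#' Reconstruction loss (sum of squared errors over cells)
#'
#' `sum_i ||x_i - x'_i||^2`, a sum over cells, not a mean. (The trainer
#' internally optimizes the per-cell mean so that reconstruction and
#' cluster-level transfer gradients stay on comparable scales; see the
#' methods vignette.)
#'
#' @param X,X_prime Matrices of identical shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(X, X_prime) {
  if (!all(dim(X) == dim(X_prime)))
    stop("shape mismatch between input and reconstruction")
  sum((X - X_prime)^2)
}

#' Weighted multi-layer transfer loss
#'
#' `alpha * l_h1 + beta * l_h2 + gamma * l_z`. Under
#' `ablation_mode = "woMultiLayer"` only the code layer z is matched: alpha
#' and beta are forced to 0.
#'
#' @param l_h1,l_h2,l_z Per-layer transfer losses (each >= 0).
#' @param alpha,beta,gamma Non-negative weights.
#' @param ablation_mode `"full"`, `"woMultiLayer"` or `"woDualChannel"`.
#' @return Scalar.
#' @export
multilayer_transfer_loss <- function(l_h1, l_h2, l_z, alpha = 0.2, beta = 0.2,
                                     gamma = 0.2, ablation_mode = "full") {
  if (any(c(alpha, beta, gamma) < 0)) stop("weights must be >= 0")
  if (identical(ablation_mode, "woMultiLayer")) alpha <- beta <- 0
  alpha * l_h1 + beta * l_h2 + gamma * l_z
}

#' Total training loss
#'
#' Reconstruction plus schedule-weighted transfer:
#' `sum(rec_losses) + lambda_p * l_tran`.
#'
#' @param rec_losses Per-channel reconstruction losses.
#' @param l_tran Weighted multi-layer transfer loss.
#' @param lambda_p Current schedule value in \[0, 1).
#' @return Scalar.
#' @export
total_loss <- function(rec_losses, l_tran, lambda_p) {
  if (any(rec_losses < 0) || l_tran < 0) stop("loss components must be >= 0")
  sum(rec_losses) + lambda_p * l_tran
}

# Adam optimizer state + step (full-batch; deterministic).
.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Save / load channel weights
#'
#' Plain-text checkpoint (one file per channel) enabling deterministic
#' resume: dims on the first line, then each parameter flattened.
#'
#' @param model A `ChannelModel`.
#' @param path Checkpoint file path.
#' @export
save_channel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ChannelModel ", model$batch_id), con)
  writeLines(paste("dims", paste(model$dims, collapse = " ")), con)
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    dims <- if (is.matrix(p)) dim(p) else c(length(p), 0L)
    writeLines(paste(nm, dims[1], dims[2]), con)
    writeLines(paste(format(as.vector(p), digits = 17), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname save_channel
#' @return `load_channel` returns the restored `ChannelModel`.
#' @export
load_channel <- function(path) {
  lines <- readLines(path)
  batch_id <- sub("^# ChannelModel ", "", lines[1])
  dims <- as.integer(strsplit(lines[2], " ")[[1]][-1])
  pars <- list()
  i <- 3
  while (i < length(lines)) {
    hdr <- strsplit(lines[i], " ")[[1]]
    vals <- as.numeric(strsplit(trimws(lines[i + 1]), " +")[[1]])
    pars[[hdr[1]]] <- if (as.integer(hdr[3]) > 0)
      matrix(vals, as.integer(hdr[2]), as.integer(hdr[3])) else vals
    i <- i + 2
  }
  structure(list(batch_id = batch_id, dims = dims, params = pars),
            class = "ChannelModel")
}
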