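test_that("lambda schedule follows the closed form and is monotone", {
  expect_identical(lambda_schedule(0, 10), 0)       # 2/(1+1) - 1
  expect_equal(lambda_schedule(10, 10), 2 / (1 + exp(-10)) - 1,
               tolerance = 1e-12)
  expect_equal(lambda_schedule(10, 10), 0.9999092, tolerance = 1e-7)
  expect_equal(lambda_schedule(5, 10), 2 / (1 + exp(-5)) - 1,
               tolerance = 1e-12)
  expect_equal(lambda_schedule(5, 10), 0.9866143, tolerance = 1e-7)
  grid <- lambda_schedule(0:50, 50)
  expect_true(all(diff(grid) > 0))
  expect_true(all(grid >= 0 & grid < 1))
  expect_error(lambda_schedule(1, 0), "n")
  expect_error(lambda_schedule(-1, 10), "p")
  expect_error(lambda_schedule(11, 10), "p")
})

# small normalized two-batch world used by the training tests
trainer_world <- function(seed = 41, n1 = 40, n2 = 30) {
  sim <- simulate_batches(simulation_params(
    n_genes = 120, batch_sizes = c(n1, n2), n_groups = 2, de_prob = 0.25,
    de_factor = 8, batch_factor_scale = 0.3, library_size_mean = 1500,
    seed = seed))
  norm <- lapply(sim$batches, normalize_expression)
  cls <- lapply(seq_along(norm), function(i)
    make_clusters(norm[[i]]$batch_id, sim$batches[[i]]$labels,
                  norm[[i]]$cell_ids))
  tab <- data.frame(batch_a = "batch1", cluster_a = c(0L, 1L),
                    batch_b = "batch2", cluster_b = c(0L, 1L),
                    score = 0.99, mask = 1L, small = FALSE)
  class(tab) <- c("SimilarityTable", class(tab))
  list(norm = norm, cls = cls, tab = tab, sim = sim)
}

test_that("with no masked pairs, joint training equals solo training bitwise", {
  w <- trainer_world()
  cfg <- bermad_config(epochs = 8, seed = 10, hidden_dims = c(16L, 4L, 16L))
  tab0 <- w$tab; tab0$mask <- 0L
  joint <- train_bermad(w$norm, w$cls, tab0, cfg)
  solo1 <- train_bermad(w$norm[1], w$cls[1], NULL, cfg)
  # channel 2's seed in the joint run is derive_seed(seed, 2); reproduce it
  # solo by shifting the master seed one derivation step
  cfg2 <- cfg; cfg2$seed <- cfg$seed + 7919L
  solo2 <- train_bermad(w$norm[2], w$cls[2], NULL, cfg2)
  expect_identical(joint$models[[1]]$params, solo1$models[[1]]$params)
  expect_identical(joint$models[[2]]$params, solo2$models[[1]]$params)
})

test_that("training is deterministic and logs a consistent LossBreakdown", {
  w <- trainer_world()
  cfg <- bermad_config(epochs = 10, seed = 3, hidden_dims = c(16L, 4L, 16L))
  f1 <- train_bermad(w$norm, w$cls, w$tab, cfg)
  f2 <- train_bermad(w$norm, w$cls, w$tab, cfg)
  expect_identical(f1$models[[1]]$params, f2$models[[1]]$params)
  expect_identical(f1$history, f2$history)
  h <- f1$history
  expect_equal(nrow(h), 10L)
  # total == sum(rec) + lambda * l_tran at every epoch
  expect_equal(h$total, h$rec_batch1 + h$rec_batch2 + h$lambda_p * h$l_tran,
               tolerance = 1e-9)
  # l_tran == alpha l_h1 + beta l_h2 + gamma l_z
  expect_equal(h$l_tran, 0.2 * h$l_h1 + 0.2 * h$l_h2 + 0.2 * h$l_z,
               tolerance = 1e-9)
  expect_true(all(h$l_h1 >= 0 & h$l_h2 >= 0 & h$l_z >= 0))
  expect_equal(h$lambda_p, lambda_schedule(1:10, 10), tolerance = 1e-12)
})

test_that("matched-cluster training reduces the code-space MMD", {
  w <- trainer_world(seed = 43)
  cfg <- bermad_config(epochs = 120, seed = 4, learning_rate = 3e-3,
                       hidden_dims = c(32L, 8L, 32L))
  models0 <- lapply(1:2, function(b)
    init_channel(ncol(w$norm[[b]]$values),
                 seed = bermad:::derive_seed(cfg$seed, b),
                 hidden_dims = cfg$hidden_dims))
  z0 <- lapply(1:2, function(b)
    channel_forward(models0[[b]], w$norm[[b]]$values)$z)
  before <- mmd2(z0[[1]], z0[[2]])
  fit <- train_bermad(w$norm, w$cls, w$tab, cfg)
  emb <- extract_embedding(fit$models, w$norm)
  after <- mmd2(emb$per_batch$batch1, emb$per_batch$batch2)
  expect_lt(after, before)
})

test_that("a batch with no masked pairs trains as a pure autoencoder", {
  w <- trainer_world()
  # three batches: pair (1,2) matched, batch 3 unconnected
  b3 <- expression_matrix(w$norm[[1]]$values, batch_id = "batch3",
                          cell_ids = sub("b1", "b3", w$norm[[1]]$cell_ids),
                          check_negative = FALSE)
  cl3 <- make_clusters("batch3", w$sim$batches[[1]]$labels, b3$cell_ids)
  cfg <- bermad_config(epochs = 6, seed = 2, hidden_dims = c(16L, 4L, 16L))
  fit <- train_bermad(c(w$norm, list(b3)), c(w$cls, list(cl3)), w$tab, cfg)
  cfg3 <- cfg; cfg3$seed <- cfg$seed + 2L * 7919L
  solo3 <- train_bermad(list(b3), list(cl3), NULL, cfg3)
  expect_identical(fit$models[[3]]$params, solo3$models[[1]]$params)
})

test_that("woDualChannel shares one model across batches", {
  w <- trainer_world()
  cfg <- bermad_config(epochs = 6, seed = 2, hidden_dims = c(16L, 4L, 16L),
                       ablation_mode = "woDualChannel")
  fit <- train_bermad(w$norm, w$cls, w$tab, cfg)
  expect_identical(fit$models[[1]]$params, fit$models[[2]]$params)
})

test_that("non-finite losses abort with a diagnostic", {
  w <- trainer_world()
  bad <- w$norm[[1]]
  bad$values[1, 1] <- NaN
  cfg <- bermad_config(epochs = 3, seed = 1, hidden_dims = c(8L, 4L, 8L))
  expect_error(train_bermad(list(bad, w$norm[[2]]), w$cls, NULL, cfg),
               "epoch")
})

test_that("extract_embedding stacks per-batch codes in input order", {
  w <- trainer_world(n1 = 12, n2 = 8)
  cfg <- bermad_config(epochs = 2, seed = 1, hidden_dims = c(8L, 4L, 8L))
  fit <- train_bermad(w$norm, w$cls, NULL, cfg)
  emb <- extract_embedding(fit$models, w$norm)
  expect_equal(nrow(emb$combined), 20L)
  expect_equal(emb$combined$cell_id[1:12], w$norm[[1]]$cell_ids)
  expect_equal(ncol(emb$per_batch$batch1), 4L)
  expect_equal(as.numeric(as.matrix(emb$combined[1:12, -(1:2)])),
               as.numeric(emb$per_batch$batch1))
  # identical inputs + identical weights -> identical codes
  twin <- expression_matrix(w$norm[[1]]$values, batch_id = "twin",
                            cell_ids = paste0("t", 1:12),
                            check_negative = FALSE)
  emb2 <- extract_embedding(fit$models[c(1, 1)], list(w$norm[[1]], twin))
  expect_equal(unname(emb2$per_batch[[1]]), unname(emb2$per_batch[[2]]))
  expect_error(extract_embedding(fit$models[1], w$norm), "one channel")
  # disk round trip
  d <- withr::local_tempdir()
  write_embedding(emb, file.path(d, "e.csv"))
  back <- read_embedding(file.path(d, "e.csv"))
  expect_equal(as.matrix(back[, -(1:2)]),
               as.matrix(emb$combined[, -(1:2)]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("checkpoints record weights, config and history", {
  w <- trainer_world(n1 = 10, n2 = 10)
  cfg <- bermad_config(epochs = 2, seed = 1, hidden_dims = c(8L, 4L, 8L))
  fit <- train_bermad(w$norm, w$cls, NULL, cfg)
  d <- withr::local_tempdir()
  save_checkpoint(fit, d)
  expect_true(file.exists(file.path(d, "channel_1.txt")))
  expect_true(file.exists(file.path(d, "config.txt")))
  back <- load_channel(file.path(d, "channel_2.txt"))
  expect_equal(back$params$W1, fit$models[[2]]$params$W1,
               tolerance = 1e-12, ignore_attr = TRUE)
  h <- data.table::fread(file.path(d, "history.csv"))
  expect_equal(nrow(h), 2L)
})
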