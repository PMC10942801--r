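test_that("ari handles the canonical hand cases", {
  expect_equal(ari(c(1, 1, 2, 2, 3), c(1, 1, 2, 2, 3)), 1)
  # invariant to label renaming
  expect_equal(ari(c("x", "x", "y", "y", "z"), c(5, 5, 9, 9, 2)), 1)
  # pred [0,0,1,1] vs truth [0,1,0,1]: contingency all ones ->
  # index 0, expected 2*2/6, max 2 -> ARI = -0.5
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_error(ari(1:3, 1:4), "length")
})

test_that("ari matches the pair-counting oracle and is symmetric", {
  withr::with_seed(51, {
    for (rep in 1:10) {
      n <- sample(8:25, 1)
      pred <- sample(1:3, n, replace = TRUE)
      truth <- sample(1:4, n, replace = TRUE)
      expect_equal(ari(pred, truth), oracle_ari(pred, truth),
                   tolerance = 1e-12)
      expect_equal(ari(pred, truth), ari(truth, pred), tolerance = 1e-12)
    }
  })
})

test_that("silhouette matches hand computation and the brute-force oracle", {
  # two tight distant 1-D clusters
  Z <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  lab <- c("a", "a", "b", "b")
  s <- silhouette_score(Z, lab)
  expect_equal(s, mean(c((10.05 - 0.1) / 10.05, (9.95 - 0.1) / 9.95,
                         (9.95 - 0.1) / 9.95, (10.05 - 0.1) / 10.05)),
               tolerance = 1e-12)
  expect_gt(s, 0.98)
  withr::with_seed(52, {
    for (rep in 1:10) {
      n <- 20
      Z <- matrix(rnorm(n * 3), n, 3)
      lab <- sample(letters[1:3], n, replace = TRUE)
      if (length(unique(lab)) < 2) next
      expect_equal(silhouette_score(Z, lab), oracle_silhouette(Z, lab),
                   tolerance = 1e-12)
    }
    # random labels on one blob: near zero
    Z <- matrix(rnorm(400 * 2), 400, 2)
    lab <- sample(c("a", "b"), 400, replace = TRUE)
    expect_lt(abs(silhouette_score(Z, lab)), 0.1)
  })
  expect_error(silhouette_score(matrix(rnorm(10), 5, 2), rep("a", 5)),
               "two distinct")
})

test_that("silhouette scores singleton-label cells as 0", {
  Z <- matrix(c(0, 0.1, 5), 3, 1)
  lab <- c("a", "a", "solo")
  # solo cell scores 0; the two a-cells are near-perfect
  expect_equal(silhouette_score(Z, lab),
               mean(c((5 - 0.1) / 5, (4.9 - 0.1) / 4.9, 0)),
               tolerance = 1e-12)
})

test_that("divergence estimator tracks the Gaussian closed form", {
  withr::with_seed(53, {
    n <- 2000
    mu <- 1
    A <- matrix(rnorm(n), n, 1)
    B <- matrix(rnorm(n, mean = mu), n, 1)
    lab <- rep("t", n)
    est <- divergence_score(A, B, lab, lab)
    # symmetric KL between N(0,1) and N(mu,1) is mu^2/2
    expect_lt(abs(est - mu^2 / 2) / (mu^2 / 2), 0.15)
  })
})

test_that("divergence is higher for shifted batches, ~0 for identical ones", {
  withr::with_seed(54, {
    A <- matrix(rnorm(600 * 2), 600, 2)
    B <- matrix(rnorm(600 * 2), 600, 2)
    Bs <- B + 5
    lab <- rep("t", 600)
    d_same <- divergence_score(A, B, lab, lab)
    d_shift <- divergence_score(A, Bs, lab, lab)
    expect_gte(d_same, 0)
    expect_lt(d_same, 0.2)
    expect_gt(d_shift, d_same + 1)
  })
})

test_that("divergence is restricted to shared cell types", {
  withr::with_seed(55, {
    A <- rbind(matrix(rnorm(200), 100, 2),
               matrix(rnorm(200, mean = 50), 100, 2))  # exclusive type far
    B <- matrix(rnorm(200), 100, 2)
    la <- rep(c("shared", "exclusiveA"), each = 100)
    lb <- rep("shared", 100)
    d <- divergence_score(A, B, la, lb)
    expect_lt(d, 0.5)  # the far-away exclusive type is excluded
    expect_error(divergence_score(A, B, rep("x", 200), lb), "share")
  })
})

test_that("evaluate_embedding scores a perfect embedding as perfect", {
  withr::with_seed(56, {
    centers <- rbind(c(0, 0), c(20, 0), c(0, 20))
    Z <- do.call(rbind, lapply(1:3, function(g)
      matrix(rnorm(120 * 2, sd = 0.3), 120, 2) +
        matrix(centers[g, ], 120, 2, byrow = TRUE)))
    labs <- rep(paste0("G", 1:3), each = 120)
    # interleave two batches over the same positions
    df <- data.frame(cell_id = paste0("c", 1:360),
                     batch_id = rep(c("b1", "b2"), 180),
                     z_1 = Z[, 1], z_2 = Z[, 2])
    cfg <- bermad_config(seed = 1, knn_k = 10)
    rep1 <- evaluate_embedding(df, labs, cfg)
    expect_equal(unname(rep1$ari["mean"]), 1)
    expect_lt(unname(rep1$divergence["mean"]), 0.2)
    expect_gt(unname(rep1$silhouette["mean"]), 0.8)
    rep2 <- evaluate_embedding(df, labs, cfg)
    expect_identical(rep1, rep2)  # same seed -> identical report
    # named labels join by cell id
    rep3 <- evaluate_embedding(df, setNames(labs, df$cell_id), cfg)
    expect_equal(rep3$ari, rep1$ari)
  })
})

test_that("metrics are invariant to cell-order permutation", {
  withr::with_seed(57, {
    Z <- matrix(rnorm(60 * 2), 60, 2)
    lab <- sample(c("a", "b", "c"), 60, replace = TRUE)
    perm <- sample(60)
    expect_equal(silhouette_score(Z, lab),
                 silhouette_score(Z[perm, ], lab[perm]), tolerance = 1e-12)
    pred <- sample(c("x", "y"), 60, replace = TRUE)
    expect_equal(ari(lab, pred), ari(lab[perm], pred[perm]))
    A <- matrix(rnorm(80), 40, 2); B <- matrix(rnorm(80, 1), 40, 2)
    la <- rep("t", 40)
    pa <- sample(40)
    expect_equal(divergence_score(A, B, la, la),
                 divergence_score(A[pa, ], B, la, la), tolerance = 1e-12)
  })
})
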