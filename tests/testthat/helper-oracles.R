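# Independent brute-force oracles. Deliberately naive double-loop
# implementations, kept free of any package internals so they can arbitrate.

oracle_mmd2 <- function(A, B, sigma2, mults) {
  k <- function(x, y) sum(exp(-sum((x - y)^2) / (2 * sigma2 * mults)))
  n <- nrow(A); m <- nrow(B)
  kaa <- 0; kbb <- 0; kab <- 0
  for (i in 1:n) for (j in 1:n) kaa <- kaa + k(A[i, ], A[j, ])
  for (i in 1:m) for (j in 1:m) kbb <- kbb + k(B[i, ], B[j, ])
  for (i in 1:n) for (j in 1:m) kab <- kab + k(A[i, ], B[j, ])
  kaa / n^2 + kbb / m^2 - 2 * kab / (n * m)
}

oracle_median_bandwidth <- function(A, B) {
  X <- rbind(A, B)
  n <- nrow(X)
  d <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    d <- c(d, sum((X[i, ] - X[j, ])^2))
  stats::median(d)
}

oracle_recloss <- function(X, Xp) {
  tot <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X)))
    tot <- tot + (X[i, j] - Xp[i, j])^2
  tot
}

oracle_silhouette <- function(Z, labels) {
  n <- nrow(Z)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d[i, j] <- sqrt(sum((Z[i, ] - Z[j, ])^2))
  s <- numeric(n)
  for (i in 1:n) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (l in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(d[i, labels == l]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# pair-counting ARI: agreement over all unordered cell pairs
oracle_ari <- function(pred, truth) {
  n <- length(pred)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sp <- pred[i] == pred[j]; st <- truth[i] == truth[j]
    if (sp && st) n11 <- n11 + 1
    else if (!sp && !st) n00 <- n00 + 1
    else if (sp) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  tot <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / tot
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxi == expected) return(1)
  (n11 - expected) / (maxi - expected)
}
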