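# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity with naive loops/enumeration, independent of the
# package internals they check.

# All permutations of 1..k, one per row (iterative construction).
perms_of <- function(k) {
  out <- matrix(1L, 1L, 1L)
  for (j in 2:k) {
    blocks <- lapply(seq_len(j), function(pos) {
      t(apply(out, 1L, function(v) append(v, j, after = pos - 1L)))
    })
    out <- do.call(rbind, blocks)
  }
  out
}

# Squared Euclidean distances by explicit double loop.
sqdist_loop <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum((x[i, ] - x[j, ])^2)
  }
  d
}

# Bray-Curtis dissimilarity by literal double loop over features.
bray_loop <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ])
  }
  d
}

# The three-term V-statistic expansion of the empirical HSIC, evaluated by
# explicit quadruple loops.
hsic_vstat_loop <- function(KX, KY) {
  n <- nrow(KX)
  t1 <- 0
  for (i in 1:n) for (j in 1:n) t1 <- t1 + KX[i, j] * KY[i, j]
  t2 <- 0
  for (i in 1:n) for (j in 1:n) for (u in 1:n) for (v in 1:n) {
    t2 <- t2 + KX[i, j] * KY[u, v]
  }
  t3 <- 0
  for (i in 1:n) for (j in 1:n) for (u in 1:n) {
    t3 <- t3 + KX[i, j] * KY[i, u]
  }
  t1 / n^2 + t2 / n^4 - 2 * t3 / n^3
}

# Cluster-block mean by literal loops.
block_mean_loop <- function(K, labels) {
  lv <- unique(labels)
  m <- length(lv)
  out <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    out[a, b] <- mean(K[labels == lv[a], labels == lv[b]])
  }
  out
}

# Exhaustive permutation distribution of T = sum_ij A_ij B_{p(i)p(j)}.
enum_perm_stats <- function(A, B) {
  pm <- perms_of(nrow(A))
  apply(pm, 1L, function(p) sum(A * B[p, p]))
}

enum_perm_moments <- function(A, B) {
  tv <- enum_perm_stats(A, B)
  mu <- mean(tv)
  list(mu = mu, sigma2 = mean((tv - mu)^2),
       gamma = mean((tv - mu)^3) / mean((tv - mu)^2)^1.5)
}

# A random PSD matrix.
rand_psd <- function(n) {
  z <- matrix(rnorm(n * (n + 2)), n, n + 2)
  tcrossprod(z) / (n + 2)
}

# A random symmetric doubly centered matrix.
rand_centered <- function(n) {
  z <- matrix(rnorm(n * n), n, n)
  double_center(z + t(z))
}

expect_rel_equal <- function(actual, expected, digits = 10) {
  scale <- max(abs(expected), .Machine$double.eps)
  expect_lt(max(abs(actual - expected)) / scale, 10^(-digits))
}
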