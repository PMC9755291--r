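test_that("pairwise squared distances match geometry and brute force", {
  d <- pairwise_sq_distances(rbind(c(0, 0), c(3, 4)))
  expect_equal(d, matrix(c(0, 25, 25, 0), 2, 2), ignore_attr = TRUE)

  same <- matrix(1, 4, 3)
  expect_equal(pairwise_sq_distances(same), matrix(0, 4, 4),
               ignore_attr = TRUE)

  set.seed(10)
  x <- matrix(rnorm(9), 3, 3)
  expect_rel_equal(pairwise_sq_distances(x), sqdist_loop(x))

  xbad <- x; xbad[2, 1] <- NA
  expect_error(pairwise_sq_distances(xbad), "row: 2")
})

test_that("median heuristic is the median over distinct pairs", {
  expect_equal(median_heuristic(rbind(c(0, 0), c(3, 4))), 5)
  # collinear points at pairwise distances {1, 1, 2}
  expect_equal(median_heuristic(cbind(c(0, 1, 2))), 1)

  set.seed(11)
  x <- matrix(rnorm(40), 20, 2)
  pairs <- combn(20, 2)
  dists <- apply(pairs, 2L, function(ij) {
    sqrt(sum((x[ij[1], ] - x[ij[2], ])^2))
  })
  expect_equal(median_heuristic(x), median(sort(dists)))

  expect_error(median_heuristic(matrix(1, 3, 2)), "bandwidth")
})

test_that("gaussian kernel follows exp(-d^2/h^2) with unit diagonal", {
  expect_equal(gaussian_kernel(matrix(2, 3, 2), bandwidth = 1),
               matrix(1, 3, 3), ignore_attr = TRUE)

  # two points at distance equal to the bandwidth -> entry exp(-1)
  x <- rbind(0, 3)
  K <- gaussian_kernel(x, bandwidth = 3)
  expect_equal(K[1, 2], exp(-1))

  set.seed(12)
  x <- matrix(rnorm(15), 5, 3)
  h <- median_heuristic(x)
  K <- gaussian_kernel(x)
  expect_equal(attr(K, "bandwidth"), h)
  expect_rel_equal(unclass(K), exp(-sqdist_loop(x) / h^2))
  expect_true(all(K > 0 & K <= 1))
  expect_equal(diag(K), rep(1, 5), ignore_attr = TRUE)

  # joint row permutation permutes the kernel consistently
  p <- c(3, 1, 5, 2, 4)
  expect_equal(unclass(gaussian_kernel(x[p, ], bandwidth = h)),
               unclass(K)[p, p], ignore_attr = TRUE)

  expect_error(gaussian_kernel(x, bandwidth = 0), "positive")
})

test_that("bray-curtis dissimilarities and kernel behave", {
  same <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_equal(bray_curtis_kernel(same), matrix(0, 4, 4),
               ignore_attr = TRUE, tolerance = 1e-12)

  # disjoint support -> maximal dissimilarity 1
  x <- rbind(c(1, 2, 0, 0), c(0, 0, 3, 1))
  expect_equal(bray_loop(x)[1, 2], 1)

  set.seed(13)
  comp <- matrix(rexp(30), 6, 5)
  D <- as.matrix(vegan::vegdist(comp, method = "bray"))
  expect_rel_equal(D, bray_loop(comp))
  expect_true(all(D >= 0 & D <= 1) && all(diag(D) == 0))

  K <- bray_curtis_kernel(comp)
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)

  expect_error(bray_curtis_kernel(rbind(c(1, -1), c(1, 1))), "nonnegative")
  expect_error(bray_curtis_kernel(rbind(c(0, 0), c(1, 1))), "zero row sum")
})

test_that("double centering zeroes margins, is idempotent, matches oracle", {
  expect_equal(double_center(matrix(7, 5, 5)), matrix(0, 5, 5),
               ignore_attr = TRUE)

  set.seed(14)
  K <- rand_psd(5)
  Kc <- double_center(K)
  expect_lt(max(abs(rowSums(Kc))), 1e-12)
  expect_lt(max(abs(colSums(Kc))), 1e-12)
  expect_equal(double_center(Kc), Kc, tolerance = 1e-12)

  oracle <- K - outer(rowMeans(K), rep(1, 5)) -
    outer(rep(1, 5), colMeans(K)) + mean(K)
  expect_rel_equal(Kc, oracle)
})

test_that("psd projection clamps negative eigenvalues and is a projection", {
  expect_equal(psd_project(diag(3)), diag(3), ignore_attr = TRUE)
  expect_equal(psd_project(diag(c(1, -1))), diag(c(1, 0)),
               ignore_attr = TRUE, tolerance = 1e-12)

  set.seed(15)
  S <- matrix(rnorm(36), 6, 6); S <- S + t(S)
  P <- psd_project(S)
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  expect_equal(psd_project(P), P, tolerance = 1e-10)
})
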