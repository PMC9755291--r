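test_that("permutation p-values are valid, seeded, and match enumeration", {
  set.seed(50)
  A <- rand_centered(6); B <- rand_centered(6)

  res <- permutation_pvalue(A, B, n_perms = 99, seed = 1)
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
  res2 <- permutation_pvalue(A, B, n_perms = 99, seed = 1)
  expect_identical(res$perm_values, res2$perm_values)

  # exhaustive enumeration at k = 4 vs a long Monte-Carlo run
  A4 <- rand_centered(4); B4 <- rand_centered(4)
  t_obs <- sum(A4 * B4)
  p_exact <- mean(enum_perm_stats(A4, B4) >= t_obs)
  p_mc <- permutation_pvalue(A4, B4, n_perms = 4000, seed = 2)$p_value
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 4000) +
              1 / 4000)

  expect_error(permutation_pvalue(A, rand_centered(5)), "same size")
})

test_that("pearson type III tail handles limits and boundaries", {
  # symmetric limit: p at the mean is 1/2
  expect_equal(pearson3_pvalue(2, list(mu = 2, sigma2 = 4, gamma = 0)), 0.5)

  # positive skewness: below the support boundary lambda the tail is 1
  mom <- list(mu = 1, sigma2 = 1, gamma = 0.8)
  lambda <- 1 - 2 / 0.8
  expect_equal(pearson3_pvalue(lambda - 0.5, mom), 1)

  # negative skewness mirrors the positive case
  momn <- list(mu = 0, sigma2 = 1, gamma = -0.5)
  expect_equal(pearson3_pvalue(0 + 1, momn),
               1 - pearson3_pvalue(-1, list(mu = 0, sigma2 = 1, gamma = 0.5)),
               tolerance = 1e-12)

  expect_error(pearson3_pvalue(1, list(mu = 0, sigma2 = 0, gamma = 1)),
               "degenerate")
})

test_that("pearson approximation tracks the exhaustive permutation tail", {
  # k = 7: compare against all 5040 permutations across the quantile range;
  # the bound reflects the approximation's measured error profile
  set.seed(51)
  for (trial in 1:3) {
    x <- matrix(rnorm(21), 7, 3); y <- matrix(rnorm(21), 7, 3)
    A <- double_center(gaussian_kernel(x))
    B <- double_center(gaussian_kernel(y))
    tv <- enum_perm_stats(A, B)
    mom <- permutation_moments(A, B)
    grid <- quantile(tv, probs = seq(0.02, 0.98, by = 0.04))
    p_apx <- vapply(grid, pearson3_pvalue, numeric(1), moments = mom)
    p_ex <- vapply(grid, function(t) mean(tv >= t), numeric(1))
    expect_lt(max(abs(p_apx - p_ex)), 0.08)
    # shape consistency: the approximate tail decreases along the grid
    expect_true(all(diff(p_apx) <= 1e-12))
  }
})

test_that("hsic_test is invariant to simultaneous row reordering", {
  set.seed(52)
  x <- matrix(rnorm(60), 20, 3)
  y <- x + matrix(rnorm(60), 20, 3)
  cl <- rep(1:5, each = 4)
  base <- hsic_test(x, y, clusters = cl, method = "pearson3")
  ord <- sample(20)
  perm <- hsic_test(x[ord, ], y[ord, ], clusters = cl[ord],
                    method = "pearson3")
  expect_equal(unname(perm$statistic), unname(base$statistic),
               tolerance = 1e-10)
  expect_equal(perm$p.value, base$p.value, tolerance = 1e-10)
})

test_that("singleton clusters reduce to the unclustered test", {
  set.seed(53)
  x <- matrix(rnorm(60), 20, 3)
  y <- matrix(rnorm(60), 20, 3)

  a <- hsic_test(x, y, method = "permutation", n_perms = 200, seed = 7)
  b <- hsic_test(x, y, clusters = 1:20, statistic = "hsic_new",
                 method = "permutation", n_perms = 200, seed = 7)
  expect_identical(a$p.value, b$p.value)

  ap <- hsic_test(x, y, method = "pearson3")
  bp <- hsic_test(x, y, clusters = 1:20, statistic = "hsic_new",
                  method = "pearson3")
  expect_equal(ap$p.value, bp$p.value, tolerance = 1e-10)
})

test_that("null p-values are close to uniform (diagnostic)", {
  set.seed(54)
  pv <- replicate(300, {
    d <- generate_iid_pair(30, 5)
    hsic_test(d$x, d$y, method = "pearson3")$p.value
  })
  expect_lt(suppressWarnings(ks.test(pv, "punif")$statistic), 0.08)
})

test_that("method selection and guardrails work", {
  set.seed(55)
  x <- matrix(rnorm(30), 10, 3); y <- matrix(rnorm(30), 10, 3)
  # auto at small unit counts -> permutation; above threshold -> pearson3
  r1 <- hsic_test(x, y, method = "auto", n_perms = 50, seed = 1)
  expect_identical(r1$method, "permutation")
  r2 <- hsic_test(x, y, method = "auto", auto_threshold = 5)
  expect_identical(r2$method, "pearson3")

  expect_error(hsic_test(x, y, clusters = rep(1:2, 5), method = "pearson3"),
               "at least 4")
  expect_error(hsic_test(x, y[1:5, ]), "same number of rows")
})
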