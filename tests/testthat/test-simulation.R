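test_that("correlation builders produce the stated matrices", {
  expect_equal(ar1_covariance(0, 4), diag(4))
  S <- ar1_covariance(0.4, 3)
  expect_equal(S[1, 3], 0.16)
  expect_equal(S[1, 2], 0.4)

  expect_equal(exchangeable_covariance(0, 3), diag(3))
  E <- exchangeable_covariance(0.5, 4)
  expect_equal(E[2, 4], 0.5)

  # Cholesky succeeds across the study's parameter grid up to k = 400
  for (r in c(0.3, 0.5, 0.7)) {
    expect_silent(chol(ar1_covariance(r, 400)))
    expect_silent(chol(exchangeable_covariance(r, 400)))
  }
  expect_error(exchangeable_covariance(-0.6, 3), "not positive definite")
  expect_error(ar1_covariance(1, 3), "rho")
})

test_that("iid pairs have the intended covariance and independence", {
  set.seed(60)
  d <- generate_iid_pair(4000, 5)
  err <- norm(cov(d$x) - ar1_covariance(0.4, 5), "F")
  expect_lt(err, 0.15)
  # X and Y streams are independent draws
  expect_lt(max(abs(cor(d$x, d$y))), 0.08)

  dl <- generate_iid_pair(100, 4, dist = "lognormal")
  expect_true(all(dl$x > 0) && all(dl$y > 0))
})

test_that("clustered null has the Kronecker correlation layout", {
  set.seed(61)
  d <- generate_clustered_null(m = 1500, p = 4, rho_w = 0.5, rho_c = 0.7)
  expect_equal(dim(d$x), c(4500, 4))
  expect_equal(d$clusters, rep(1:1500, each = 3))
  t1 <- seq(1, 4500, by = 3)
  # within-cluster lag-1 temporal correlation of a fixed feature ~ rho_c
  expect_lt(abs(cor(d$x[t1, 2], d$x[t1 + 1, 2]) - 0.7), 0.05)
  # same-time cross-feature correlation ~ rho_w
  expect_lt(abs(cor(d$x[t1, 1], d$x[t1, 4]) - 0.5), 0.05)
  # X centered at 5, Y at 0
  expect_lt(abs(mean(d$x) - 5), 0.05)
  expect_lt(abs(mean(d$y)), 0.05)
})

test_that("alternative design reduces to the null at eta = 0", {
  set.seed(62); null <- generate_clustered_null(20, 6, 0.5, 0.5)
  set.seed(62); alt <- generate_clustered_alternative(20, 6, 0, 0.5, 0.5)
  expect_identical(alt$x, null$x)
  expect_identical(alt$y, null$y)
  expect_true(all(alt$beta == 0))
})

test_that("alternative effect sizes follow Uniform(0, sqrt(25/m))", {
  # at m = 100 the upper bound is sqrt(25/100) = 0.5
  set.seed(63)
  alt <- generate_clustered_alternative(100, 40, 1, 0.5, 0.5)
  expect_true(all(alt$beta >= 0 & alt$beta <= 0.5))
  expect_true(alt$exposure %in% 1:40)
  # first eta*p outcomes carry signal, the rest are zero
  alt2 <- generate_clustered_alternative(100, 40, 0.5, 0.5, 0.5)
  expect_true(all(alt2$beta[21:40] == 0))
  expect_true(all(alt2$beta[1:20] > 0))
})

test_that("power grows with the exposed proportion", {
  pow <- vapply(c(0.2, 0.8), function(eta) {
    run_experiment("clustered_alternative", m = 60, p = 30, rho_w = 0.5,
                   rho_c = 0.5, eta = eta,
                   tests = list(list(statistic = "hsic_new",
                                     method = "pearson3")),
                   n_replicates = 80, seed = 64)$rejection_rate
  }, numeric(1))
  expect_gt(pow[2], pow[1])
})

test_that("experiment runner is seeded, deterministic and level-exact", {
  r1 <- run_experiment("iid_normal", n = 20, p = 3,
                       tests = list(list(statistic = "hsic",
                                         method = "pearson3")),
                       n_replicates = 20, seed = 65)
  r2 <- run_experiment("iid_normal", n = 20, p = 3,
                       tests = list(list(statistic = "hsic",
                                         method = "pearson3")),
                       n_replicates = 20, seed = 65)
  expect_identical(r1, r2)

  # alpha = 1 rejects everything
  r3 <- run_experiment("iid_normal", n = 20, p = 3, alpha = 1,
                       tests = list(list(statistic = "hsic",
                                         method = "pearson3")),
                       n_replicates = 3, seed = 66)
  expect_equal(r3$rejection_rate, 1)
  expect_error(run_experiment("iid_normal", n = 20, p = 3,
                              n_replicates = 2),
               "seed")
})
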