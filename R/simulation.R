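# Synthetic-data generators for the numerical studies: i.i.d. settings
# (Gaussian / log-normal with AR(1) feature correlation), the clustered
# null with Kronecker covariance, and the single-exposure clustered
# alternative; plus the experiment runner that turns replicated tests into
# rejection-rate tables.

#' AR(1) correlation matrix
#'
#' Entry \eqn{(i,j) = \rho^{|i-j|}}; positive definite for \eqn{|\rho| < 1}.
#'
#' @param rho correlation parameter, \eqn{|\rho| < 1}.
#' @param k dimension.
#' @export
ar1_covariance <- function(rho, k) {
  if (abs(rho) >= 1) stop("AR(1) needs |rho| < 1", call. = FALSE)
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  rho^abs(outer(seq_len(k), seq_len(k), "-"))
}

#' Exchangeable (compound-symmetric) correlation matrix
#'
#' Ones on the diagonal and \eqn{\rho} everywhere else; positive definite
#' for \eqn{-1/(k-1) < \rho < 1}.
#'
#' @param rho off-diagonal correlation.
#' @param k dimension.
#' @export
exchangeable_covariance <- function(rho, k) {
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  if (rho >= 1 || (k > 1L && rho <= -1 / (k - 1))) {
    stop("exchangeable correlation is not positive definite for rho = ",
         rho, " at k = ", k, call. = FALSE)
  }
  m <- matrix(rho, k, k)
  diag(m) <- 1
  m
}

# Draw n rows from N(mu, Sigma) given the upper-triangular Cholesky factor
# U with Sigma = U'U.
.rmvnorm_chol <- function(n, chol_u, mu = 0) {
  d <- ncol(chol_u)
  matrix(stats::rnorm(n * d), n, d) %*% chol_u + mu
}

#' Independent i.i.d. sample pair (size study design)
#'
#' Draws \code{X} (N x p) and \code{Y} (N x q) independently of each other,
#' each row i.i.d. from \eqn{N(0, \Sigma)} with AR(1) feature correlation
#' \eqn{\Sigma_{ij} = \rho^{|i-j|}} (default \eqn{\rho = 0.4}); the
#' log-normal variant exponentiates the Gaussian draw elementwise. Because
#' X and Y are generated independently, the independence null holds by
#' construction.
#'
#' @param n number of samples.
#' @param p,q dimensions of X and Y.
#' @param dist \code{"normal"} or \code{"lognormal"}.
#' @param rho AR(1) feature-correlation parameter.
#' @return List with matrices \code{x}, \code{y}.
#' @export
generate_iid_pair <- function(n, p, q = p, dist = c("normal", "lognormal"),
                              rho = 0.4) {
  dist <- match.arg(dist)
  ux <- chol(ar1_covariance(rho, p))
  uy <- if (q == p) ux else chol(ar1_covariance(rho, q))
  x <- .rmvnorm_chol(n, ux)
  y <- .rmvnorm_chol(n, uy)
  if (dist == "lognormal") {
    x <- exp(x); y <- exp(y)
  }
  list(x = x, y = y)
}

# Kronecker covariance Sigma_W (p x p exchangeable, rho_W) (x) Sigma_c
# (l x l AR(1), rho_c), laid out feature-major with time innermost: the
# 3p-vector of a cluster is (feature 1: t1..tl, ..., feature p: t1..tl), so
# Sigma_c governs the l time points of each feature and Sigma_W the
# feature-feature correlation.
.clustered_chol <- function(p, rho_w, rho_c, l = 3L) {
  chol(kronecker(exchangeable_covariance(rho_w, p), ar1_covariance(rho_c, l)))
}

# Reshape an m x (l*p) matrix of cluster vectors (feature-major, time
# innermost) into the (m*l) x p sample matrix, samples ordered cluster by
# cluster, time within cluster.
.unfold_clusters <- function(v, m, p, l) {
  tmp <- array(t(v), dim = c(l, p, m))       # [time, feature, cluster]
  matrix(aperm(tmp, c(1L, 3L, 2L)), nrow = l * m)
}

#' Clustered null design (Kronecker-structured Gaussian)
#'
#' Generates \code{m} independent clusters of \code{l = 3} time points.
#' Each cluster's X is one draw of a \eqn{3p}-vector from
#' \eqn{N(5 \cdot 1, \Sigma_W \otimes \Sigma_c)} with exchangeable
#' feature correlation \eqn{\Sigma_W(\rho_W)} and AR(1) temporal
#' correlation \eqn{\Sigma_c(\rho_c)}; Y is an independent draw from
#' \eqn{N(0, \Sigma_W \otimes \Sigma_c)} (the alternative model's noise
#' with all effects zero), so the independence null holds while both
#' variables are strongly cluster-correlated.
#'
#' @param m number of clusters.
#' @param p dimension of X and Y.
#' @param rho_w exchangeable feature correlation.
#' @param rho_c AR(1) within-cluster (temporal) correlation.
#' @param l cluster size (time points per cluster), default 3.
#' @param chol_factor optional precomputed Cholesky factor of
#'   \eqn{\Sigma_W \otimes \Sigma_c} (reused across replicates for speed).
#' @return List with \code{x}, \code{y} (\eqn{(ml) \times p} matrices,
#'   samples ordered cluster by cluster) and \code{clusters} (integer
#'   labels 1..m).
#' @export
generate_clustered_null <- function(m, p, rho_w, rho_c, l = 3L,
                                    chol_factor = NULL) {
  if (is.null(chol_factor)) chol_factor <- .clustered_chol(p, rho_w, rho_c, l)
  x <- .unfold_clusters(.rmvnorm_chol(m, chol_factor, mu = 5), m, p, l)
  y <- .unfold_clusters(.rmvnorm_chol(m, chol_factor, mu = 0), m, p, l)
  list(x = x, y = y, clusters = rep(seq_len(m), each = l))
}

#' Clustered single-exposure alternative design
#'
#' X is generated as in \code{\link{generate_clustered_null}}. One exposure
#' variable \eqn{r} of X is chosen uniformly at random; the first
#' \eqn{\eta p} outcomes of Y depend on it,
#' \eqn{Y_{s,t} = \beta_s X_{r,t} + \epsilon_{s,t}}, with effect sizes
#' \eqn{\beta_s \sim \mathrm{Uniform}(0, \sqrt{25/m})} for
#' \eqn{s \le \eta p} and \eqn{\beta_s = 0} otherwise, and noise
#' \eqn{\epsilon \sim N(0, \Sigma_W \otimes \Sigma_c)} independent across
#' clusters. The exposure index and effect sizes are redrawn on every call.
#' With \code{eta = 0} the output reduces exactly to the null design at a
#' matched RNG state.
#'
#' @inheritParams generate_clustered_null
#' @param eta proportion of Y outcomes affected by the exposure,
#'   \eqn{0 \le \eta \le 1}.
#' @return List with \code{x}, \code{y}, \code{clusters}, plus the drawn
#'   \code{exposure} index and \code{beta} vector.
#' @export
generate_clustered_alternative <- function(m, p, eta, rho_w, rho_c, l = 3L,
                                           chol_factor = NULL) {
  if (eta < 0 || eta > 1) stop("'eta' must lie in [0, 1]", call. = FALSE)
  if (is.null(chol_factor)) chol_factor <- .clustered_chol(p, rho_w, rho_c, l)
  x <- .unfold_clusters(.rmvnorm_chol(m, chol_factor, mu = 5), m, p, l)
  eps <- .unfold_clusters(.rmvnorm_chol(m, chol_factor, mu = 0), m, p, l)
  n_sig <- round(eta * p)
  beta <- numeric(p)
  r <- NA_integer_
  if (n_sig > 0L) {
    r <- sample.int(p, 1L)
    beta[seq_len(n_sig)] <- stats::runif(n_sig, 0, sqrt(25 / m))
  }
  y <- outer(x[, if (is.na(r)) 1L else r], beta) + eps
  list(x = x, y = y, clusters = rep(seq_len(m), each = l),
       exposure = r, beta = beta)
}

#' Monte-Carlo size/power experiment runner
#'
#' Repeatedly generates data from one of the study designs, applies the
#' requested tests, and tabulates rejection rates at level \code{alpha}
#' with binomial standard errors. Replicates are driven by per-replicate
#' seeds derived once from \code{seed}, so results are reproducible and
#' independent of evaluation order.
#'
#' @param design \code{"iid_normal"}, \code{"iid_lognormal"},
#'   \code{"clustered_null"} or \code{"clustered_alternative"}.
#' @param n sample count (i.i.d. designs).
#' @param m,l cluster count and size (clustered designs).
#' @param p,q dimensions (q defaults to p).
#' @param rho_w,rho_c clustered-design correlations.
#' @param eta exposed-outcome proportion (alternative design).
#' @param tests data frame or list of \code{list(statistic=, method=)}
#'   pairs; statistics \code{"hsic"}, \code{"hsic_new"}, \code{"hsic_mean"},
#'   methods \code{"permutation"}, \code{"pearson3"}.
#' @param n_replicates Monte-Carlo replicates.
#' @param alpha significance level (default 0.05).
#' @param n_perms permutations for permutation-method tests.
#' @param seed integer seed (mandatory: the experiment is fully seeded).
#' @return Data frame with one row per test: design parameters, test,
#'   method, replicate count, rejection rate and its binomial SE.
#' @export
run_experiment <- function(design = c("iid_normal", "iid_lognormal",
                                      "clustered_null",
                                      "clustered_alternative"),
                           n = NULL, m = NULL, l = 3L, p, q = p,
                           rho_w = 0.5, rho_c = 0.5, eta = 0.5,
                           tests = list(list(statistic = "auto",
                                             method = "pearson3")),
                           n_replicates = 1000L, alpha = 0.05,
                           n_perms = 1000L, seed) {
  design <- match.arg(design)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]", call. = FALSE)
  if (is.data.frame(tests)) {
    tests <- lapply(seq_len(nrow(tests)),
                    function(i) as.list(tests[i, , drop = FALSE]))
  }
  clustered <- design %in% c("clustered_null", "clustered_alternative")
  if (clustered && is.null(m)) stop("clustered designs need 'm'",
                                    call. = FALSE)
  if (!clustered && is.null(n)) stop("i.i.d. designs need 'n'",
                                     call. = FALSE)
  # one Cholesky factor per configuration, shared across replicates
  chol_factor <- if (clustered) .clustered_chol(p, rho_w, rho_c, l)
  rep_seeds <- .with_seed(seed, sample.int(2147483646L, n_replicates))
  n_tests <- length(tests)
  rejects <- matrix(0L, n_replicates, n_tests)
  for (rep_i in seq_len(n_replicates)) {
    set.seed(rep_seeds[rep_i])
    dat <- switch(design,
      iid_normal = c(generate_iid_pair(n, p, q, "normal"),
                     list(clusters = NULL)),
      iid_lognormal = c(generate_iid_pair(n, p, q, "lognormal"),
                        list(clusters = NULL)),
      clustered_null = generate_clustered_null(m, p, rho_w, rho_c, l,
                                               chol_factor),
      clustered_alternative = generate_clustered_alternative(
        m, p, eta, rho_w, rho_c, l, chol_factor))
    for (t_i in seq_len(n_tests)) {
      tt <- tests[[t_i]]
      stat <- tt$statistic %||% "auto"
      # hsic on clustered data means: ignore the clustering (naive test)
      use_clusters <- if (identical(stat, "hsic")) NULL else dat$clusters
      res <- hsic_test(dat$x, dat$y, clusters = use_clusters,
                       statistic = stat,
                       method = tt$method %||% "pearson3",
                       n_perms = n_perms, seed = NULL)
      rejects[rep_i, t_i] <- as.integer(res$p.value <= alpha)
    }
  }
  rate <- colMeans(rejects)
  out <- data.frame(
    design = design,
    n = if (clustered) m * l else n,
    m = if (clustered) m else NA_integer_,
    p = p, q = q,
    rho_w = if (clustered) rho_w else NA_real_,
    rho_c = if (clustered) rho_c else NA_real_,
    eta = if (design == "clustered_alternative") eta else NA_real_,
    statistic = vapply(tests, function(t) t$statistic %||% "auto",
                       character(1L)),
    method = vapply(tests, function(t) t$method %||% "pearson3",
                    character(1L)),
    n_replicates = as.integer(n_replicates),
    n_reject = as.integer(colSums(rejects)),
    rejection_rate = rate,
    se = sqrt(rate * (1 - rate) / n_replicates),
    alpha = alpha,
    seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
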