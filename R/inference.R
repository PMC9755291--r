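# P-values for the HSIC family: Monte-Carlo/exhaustive permutation test and
# the Pearson type III moment-matching approximation, plus the top-level
# test front-end hsic_test().

# Run code with a locally seeded RNG, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Permutation p-value for the trace statistic
#'
#' Draws \code{n_perms} uniform permutations \eqn{\pi} of one side and
#' computes \eqn{T_\pi = \sum_{ij} A_{ij} B_{\pi(i)\pi(j)}}; the p-value is
#' \eqn{(1 + \#\{T_\pi \ge T_{obs}\}) / (1 + n_{perms})}. The +1 correction
#' guarantees a valid test (p-values can never be 0) and differs from the
#' raw proportion by less than Monte-Carlo resolution at the default 1000
#' permutations. Only \code{B} is permuted; by symmetry of the permutation
#' null the choice of side is immaterial.
#'
#' @param A,B symmetric centered matrices of equal size.
#' @param n_perms number of permutations (default 1000).
#' @param seed optional integer seed; the caller's RNG stream is left
#'   untouched.
#' @return List with \code{statistic} (\eqn{T_{obs}}), \code{p_value},
#'   \code{n_permutations}, \code{perm_values}.
#' @export
permutation_pvalue <- function(A, B, n_perms = 1000L, seed = NULL) {
  A <- unclass(as.matrix(A)); B <- unclass(as.matrix(B))
  k <- nrow(A)
  if (ncol(A) != k || nrow(B) != k || ncol(B) != k) {
    stop("'A' and 'B' must be square matrices of the same size",
         call. = FALSE)
  }
  if (n_perms < 1L) stop("'n_perms' must be >= 1", call. = FALSE)
  t_obs <- sum(A * B)
  tv <- .with_seed(seed, {
    vapply(seq_len(n_perms), function(i) {
      p <- sample.int(k)
      sum(A * B[p, p])
    }, numeric(1L))
  })
  list(statistic = t_obs,
       p_value = (1 + sum(tv >= t_obs)) / (1 + n_perms),
       n_permutations = as.integer(n_perms),
       perm_values = tv)
}

#' Pearson type III tail probability
#'
#' Upper-tail p-value of the permutation null approximated by a Pearson
#' type III (shifted, possibly reflected, gamma) distribution matched to
#' the exact permutation mean, variance and skewness: shape
#' \eqn{a = 4/\gamma^2}, scale \eqn{s = \sigma\gamma/2}, location
#' \eqn{\lambda = \mu - 2\sigma/\gamma}. For \eqn{\gamma > 0} this is the
#' upper gamma tail at \eqn{t - \lambda}; for \eqn{\gamma < 0} the
#' reflected lower tail; for \eqn{|\gamma|} below \code{1e-8} the normal
#' upper tail with \eqn{(\mu, \sigma)}.
#'
#' @param t_obs observed statistic.
#' @param moments a \code{\link{permutation_moments}} object (or list with
#'   \code{mu}, \code{sigma2}, \code{gamma}).
#' @return p-value in \eqn{[0, 1]}.
#' @export
pearson3_pvalue <- function(t_obs, moments) {
  mu <- moments$mu; sigma2 <- moments$sigma2; gam <- moments$gamma
  if (!is.finite(sigma2) || sigma2 <= 0 || isTRUE(moments$degenerate)) {
    stop("degenerate permutation distribution (sigma2 <= 0); ",
         "the Pearson type III approximation is undefined", call. = FALSE)
  }
  sigma <- sqrt(sigma2)
  if (!is.finite(gam) || abs(gam) < 1e-8) {
    return(stats::pnorm(t_obs, mean = mu, sd = sigma, lower.tail = FALSE))
  }
  a <- 4 / gam^2
  s <- sigma * gam / 2
  lambda <- mu - 2 * sigma / gam
  if (gam > 0) {
    stats::pgamma(t_obs - lambda, shape = a, scale = s, lower.tail = FALSE)
  } else {
    stats::pgamma(lambda - t_obs, shape = a, scale = -s, lower.tail = TRUE)
  }
}

#' Kernel independence test for i.i.d. or cluster-correlated samples
#'
#' Tests the null hypothesis that two multivariate variables are
#' independent, using the Hilbert-Schmidt independence criterion. With a
#' cluster assignment the sample kernels are first collapsed to
#' cluster-wise averaged kernels and the clustered statistic
#' \code{\link{hsic_new_statistic}} is used with permutations over the m
#' cluster indices (clusters, not samples, are the exchangeable units);
#' without clusters the plain \code{\link{hsic_statistic}} over the N
#' sample indices. P-values come from the permutation test or from the
#' Pearson type III approximation with exact permutation moments;
#' \code{method = "auto"} selects the approximation when the number of
#' exchangeable units exceeds \code{auto_threshold}.
#'
#' @param x,y numeric sample matrices with matching rows (one sample per
#'   row). If both carry row names they must agree row-by-row.
#' @param clusters optional cluster labels of length \code{nrow(x)}.
#' @param kernel_x,kernel_y \code{"gaussian"} (median-heuristic bandwidth)
#'   or \code{"braycurtis"}.
#' @param bandwidth_x,bandwidth_y optional Gaussian bandwidth overrides.
#' @param statistic \code{"auto"} (clustered statistic when clusters are
#'   given, plain HSIC otherwise), \code{"hsic"}, \code{"hsic_new"} or
#'   \code{"hsic_mean"} (cluster-averaged data baseline).
#' @param method \code{"auto"}, \code{"permutation"} or \code{"pearson3"}.
#' @param n_perms permutations for \code{method = "permutation"}.
#' @param seed optional integer seed for the permutation draw.
#' @param auto_threshold unit count above which \code{"auto"} switches from
#'   permutation to the Pearson type III approximation (default 100).
#' @return Object of class \code{"hsic_test"} (printable like an
#'   \code{htest}): statistic, p-value, method, unit count, kernel
#'   descriptions, permutation moments (Pearson III method) and seed.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 30, 2)
#' y <- x + matrix(rnorm(60, sd = 2), 30, 2)
#' hsic_test(x, y, method = "permutation", n_perms = 199, seed = 7)
#' @export
hsic_test <- function(x, y, clusters = NULL,
                      kernel_x = c("gaussian", "braycurtis"),
                      kernel_y = c("gaussian", "braycurtis"),
                      bandwidth_x = NULL, bandwidth_y = NULL,
                      statistic = c("auto", "hsic", "hsic_new", "hsic_mean"),
                      method = c("auto", "permutation", "pearson3"),
                      n_perms = 1000L, seed = NULL, auto_threshold = 100L) {
  cl_match <- match.call()
  kernel_x <- match.arg(kernel_x); kernel_y <- match.arg(kernel_y)
  statistic <- match.arg(statistic); method <- match.arg(method)
  x <- .as_sample_matrix(x, "x"); y <- .as_sample_matrix(y, "y")
  if (nrow(x) != nrow(y)) {
    stop("'x' and 'y' must have the same number of rows", call. = FALSE)
  }
  if (!is.null(rownames(x)) && !is.null(rownames(y))) {
    mism <- which(rownames(x) != rownames(y))
    if (length(mism) > 0L) {
      stop("sample IDs of 'x' and 'y' disagree (first mismatch: '",
           rownames(x)[mism[1L]], "' vs '", rownames(y)[mism[1L]], "')",
           call. = FALSE)
    }
  }
  if (statistic == "auto") {
    statistic <- if (is.null(clusters)) "hsic" else "hsic_new"
  }
  if (statistic %in% c("hsic_new", "hsic_mean") && is.null(clusters)) {
    stop("statistic '", statistic, "' needs a cluster assignment",
         call. = FALSE)
  }
  cl <- if (!is.null(clusters)) .check_clusters(clusters, nrow(x))

  cluster_sizes <- NULL
  if (statistic == "hsic_mean") {
    # average first, then run the plain test on the collapsed rows
    cluster_sizes <- as.vector(table(cl))
    x <- cluster_mean_features(x, cl)
    y <- cluster_mean_features(y, cl)
  }
  KX <- .build_kernel(x, kernel_x, bandwidth_x)
  KY <- .build_kernel(y, kernel_y, bandwidth_y)

  if (statistic == "hsic_new") {
    cluster_sizes <- as.vector(table(cl))
    A <- double_center(collapse_kernel(KX, cl))
    B <- double_center(collapse_kernel(KY, cl))
    norm_factor <- 1
  } else {
    A <- double_center(KX)
    B <- double_center(KY)
    norm_factor <- nrow(A)^2   # hsic / hsic_mean carry the 1/n^2 factor
  }
  n_units <- nrow(A)
  t_obs <- sum(A * B)
  stat_value <- t_obs / norm_factor

  if (method == "auto") {
    method <- if (n_units > auto_threshold) "pearson3" else "permutation"
  }
  moments <- NULL; n_permutations <- NULL
  if (method == "pearson3") {
    if (n_units < 4L) {
      stop("Pearson type III needs at least 4 exchangeable units; ",
           "use method = \"permutation\"", call. = FALSE)
    }
    moments <- permutation_moments(A, B)
    p_value <- pearson3_pvalue(t_obs, moments)
  } else {
    perm <- permutation_pvalue(A, B, n_perms = n_perms, seed = seed)
    p_value <- perm$p_value
    n_permutations <- perm$n_permutations
  }

  structure(list(
    statistic = stats::setNames(stat_value, statistic),
    p.value = p_value,
    method = method,
    statistic_name = statistic,
    n_units = n_units,
    n_samples = if (statistic == "hsic_mean") sum(cluster_sizes) else nrow(x),
    cluster_sizes = cluster_sizes,
    n_permutations = n_permutations,
    moments = moments,
    kernel_x = list(name = kernel_x, bandwidth = attr(KX, "bandwidth")),
    kernel_y = list(name = kernel_y, bandwidth = attr(KY, "bandwidth")),
    seed = seed,
    data.name = paste(deparse1(cl_match$x), "and", deparse1(cl_match$y)),
    call = cl_match
  ), class = "hsic_test")
}

#' @export
print.hsic_test <- function(x, digits = 4L, ...) {
  label <- switch(x$statistic_name,
                  hsic = "HSIC independence test",
                  hsic_new = "Clustered HSIC independence test",
                  hsic_mean = "Cluster-mean HSIC independence test")
  cat("\n\t", label, "\n\n", sep = "")
  cat("data:  ", x$data.name, "\n", sep = "")
  cat(names(x$statistic), " = ", format(x$statistic, digits = digits),
      ", units = ", x$n_units,
      if (!is.null(x$cluster_sizes))
        paste0(" clusters (N = ", x$n_samples, ")") else " samples",
      ", p-value = ", format.pval(x$p.value, digits = digits), "\n", sep = "")
  cat("method: ",
      switch(x$method,
             permutation = paste0("permutation (", x$n_permutations,
                                  " permutations)"),
             pearson3 = "Pearson type III moment approximation"),
      "\n", sep = "")
  cat("kernels: x = ", x$kernel_x$name,
      if (!is.null(x$kernel_x$bandwidth))
        sprintf(" (bandwidth %.4g)", x$kernel_x$bandwidth),
      ", y = ", x$kernel_y$name,
      if (!is.null(x$kernel_y$bandwidth))
        sprintf(" (bandwidth %.4g)", x$kernel_y$bandwidth),
      "\n\n", sep = "")
  invisible(x)
}

#' @export
summary.hsic_test <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$moments)) {
    cat("Exact permutation moments:\n")
    cat(sprintf("  mean %.6g, variance %.6g, skewness %.6g\n\n",
                object$moments$mu, object$moments$sigma2,
                object$moments$gamma))
  }
  invisible(object)
}
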