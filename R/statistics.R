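# The HSIC family of test statistics. All of them reduce to the trace of a
# product of two doubly centered kernel matrices; the trace is computed as
# an elementwise-product sum, sum(A * B), which is algebraically identical
# to trace(A %*% B) for symmetric A, B but O(n^2) instead of O(n^3).

.check_pair <- function(KX, KY) {
  KX <- unclass(as.matrix(KX)); KY <- unclass(as.matrix(KY))
  if (nrow(KX) != ncol(KX) || nrow(KY) != ncol(KY)) {
    stop("kernel matrices must be square", call. = FALSE)
  }
  if (nrow(KX) != nrow(KY)) {
    stop("kernel matrices have different sizes (", nrow(KX), " vs ",
         nrow(KY), ")", call. = FALSE)
  }
  list(KX = KX, KY = KY)
}

#' Empirical HSIC statistic
#'
#' The Hilbert-Schmidt independence criterion estimated from two sample
#' kernel matrices: \eqn{\mathrm{tr}(\tilde K_X \tilde K_Y)/N^2} with
#' \eqn{\tilde K = H K H} the doubly centered kernels. Nonnegative whenever
#' both kernels are PSD.
#'
#' @param KX,KY N x N kernel matrices on the same samples.
#' @return Scalar statistic with attributes \code{name} ("hsic") and
#'   \code{n_units} (N).
#' @export
hsic_statistic <- function(KX, KY) {
  k <- .check_pair(KX, KY)
  n <- nrow(k$KX)
  v <- sum(double_center(k$KX) * double_center(k$KY)) / n^2
  structure(v, name = "hsic", n_units = n)
}

#' Clustered HSIC statistic
#'
#' The clustered-data statistic
#' \eqn{\mathrm{tr}(\tilde K_X^{cl} \tilde K_Y^{cl})} computed on
#' cluster-wise averaged kernel matrices (see \code{\link{collapse_kernel}}),
#' centered by \eqn{H_m}. Note the deliberate absence of a \eqn{1/m^2}
#' factor: inference is permutation-based, so the scale of the statistic is
#' immaterial, and the reported value follows the statistic's definition.
#' With singleton clusters it equals \eqn{N^2} times the plain HSIC.
#'
#' @param KXcl,KYcl m x m cluster-wise kernel matrices.
#' @return Scalar statistic with attributes \code{name} ("hsic_new") and
#'   \code{n_units} (m).
#' @export
hsic_new_statistic <- function(KXcl, KYcl) {
  k <- .check_pair(KXcl, KYcl)
  m <- nrow(k$KX)
  v <- sum(double_center(k$KX) * double_center(k$KY))
  structure(v, name = "hsic_new", n_units = m)
}

#' Cluster-mean HSIC baseline statistic
#'
#' Averages the observations of each cluster feature-wise, rebuilds kernels
#' on the m collapsed rows (the median-heuristic bandwidth is recomputed on
#' the collapsed data) and evaluates the plain HSIC there. This is the
#' "average first, test second" baseline that the clustered statistic is
#' compared against in power studies.
#'
#' @param x,y sample matrices (N rows each).
#' @param clusters cluster labels, length N.
#' @param kernel_x,kernel_y kernel names, \code{"gaussian"} or
#'   \code{"braycurtis"}.
#' @param bandwidth_x,bandwidth_y optional Gaussian bandwidth overrides.
#' @return Scalar statistic with attributes \code{name} ("hsic_mean") and
#'   \code{n_units} (m).
#' @export
hsic_mean_statistic <- function(x, y, clusters,
                                kernel_x = "gaussian", kernel_y = "gaussian",
                                bandwidth_x = NULL, bandwidth_y = NULL) {
  xm <- cluster_mean_features(x, clusters)
  ym <- cluster_mean_features(y, clusters)
  KX <- .build_kernel(xm, kernel_x, bandwidth_x)
  KY <- .build_kernel(ym, kernel_y, bandwidth_y)
  v <- hsic_statistic(KX, KY)
  structure(as.numeric(v), name = "hsic_mean", n_units = nrow(xm))
}
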