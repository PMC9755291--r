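# Cluster handling: block-averaging an N x N sample kernel down to an
# m x m cluster-wise kernel, and cluster-level feature averaging.

#' Normalize a cluster assignment
#'
#' Converts a vector of cluster labels (one per sample) into a factor whose
#' levels follow first appearance. Used internally by every cluster-aware
#' operation so that the cluster order of all outputs is the order in which
#' clusters are first seen.
#'
#' @param labels vector (character, factor or numeric) of length N.
#' @return Factor of length N, levels in order of first appearance.
#' @export
cluster_assignment <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (anyNA(labels)) stop("cluster labels contain NA", call. = FALSE)
  factor(labels, levels = unique(labels))
}

.check_clusters <- function(clusters, n) {
  cl <- cluster_assignment(clusters)
  if (length(cl) != n) {
    stop("cluster assignment has ", length(cl), " labels but the data has ",
         n, " samples", call. = FALSE)
  }
  if (any(tabulate(cl) == 0L)) stop("empty cluster", call. = FALSE)
  cl
}

#' Collapse a sample kernel to a cluster-wise kernel
#'
#' Entry \eqn{(a,b)} of the result is the arithmetic mean of the
#' \eqn{l_a \times l_b} block of \code{K} formed by the samples of clusters
#' \eqn{a} and \eqn{b}. Diagonal blocks average all \eqn{l_a^2} entries,
#' including the kernel's own diagonal: the collapse is then
#' \eqn{M^t K M} with a column-stochastic averaging matrix \eqn{M}, which
#' guarantees that positive semi-definiteness of \code{K} carries over
#' exactly to the collapsed matrix.
#'
#' @param K sample-level kernel matrix (N x N).
#' @param clusters cluster labels, length N.
#' @return m x m symmetric PSD matrix; rows/columns ordered by first
#'   appearance of each cluster; attribute \code{source_kernel} records the
#'   kernel name of \code{K} if present.
#' @export
collapse_kernel <- function(K, clusters) {
  src <- attr(K, "kernel")
  K <- unclass(as.matrix(K))
  n <- nrow(K)
  if (ncol(K) != n) stop("'K' must be square", call. = FALSE)
  cl <- .check_clusters(clusters, n)
  m <- nlevels(cl)
  M <- matrix(0, n, m)
  M[cbind(seq_len(n), as.integer(cl))] <- 1
  M <- sweep(M, 2L, colSums(M), "/")
  out <- crossprod(M, K %*% M)
  out <- (out + t(out)) / 2
  dimnames(out) <- list(levels(cl), levels(cl))
  structure(out, source_kernel = src)
}

#' Per-cluster feature means
#'
#' Row \eqn{a} of the result is the mean over the samples of cluster
#' \eqn{a}, feature by feature. This is the data reduction behind the
#' cluster-mean baseline statistic (\code{\link{hsic_mean_statistic}}).
#'
#' @param x numeric matrix (samples x features).
#' @param clusters cluster labels, length \code{nrow(x)}.
#' @return m x d matrix, rows ordered by first appearance of each cluster.
#' @export
cluster_mean_features <- function(x, clusters) {
  x <- .as_sample_matrix(x)
  cl <- .check_clusters(clusters, nrow(x))
  out <- rowsum(x, cl) / as.vector(table(cl))
  out[levels(cl), , drop = FALSE]
}
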