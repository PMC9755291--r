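# Exact moments of the permutation null distribution of the trace statistic
# T(pi) = sum_{ij} A_ij B_{pi(i)pi(j)} for symmetric, doubly centered A, B.
#
# The mean, variance and skewness are exact functionals of the two centered
# matrices, obtained by averaging over all k! permutations analytically.
# The closed forms below were derived by Moebius inversion over the lattice
# of index-equality patterns (every expectation of a product of B-entries
# under a random permutation depends only on which indices coincide) and
# reduce, for doubly centered matrices, to eight elementary functionals of
# each matrix. They are exact for k >= 6; for k in {4, 5} some patterns
# involve more distinct indices than there are samples and the per-monomial
# forms acquire removable singularities, so those two sizes are evaluated by
# direct enumeration of the k! <= 120 permutations, which is equally exact.

# The eight elementary functionals of a symmetric matrix used by the
# closed-form moments.
.kernel_functionals <- function(A) {
  dg <- diag(A)
  A2 <- A %*% A
  list(
    T  = sum(dg),            # trace
    T2 = sum(A * A),         # trace(A^2) = squared Frobenius norm
    S2 = sum(dg^2),
    S3 = sum(dg^3),
    T3 = sum(A2 * A),        # trace(A^3)
    U  = sum(A^3),           # elementwise cube sum
    R  = sum(dg * diag(A2)),
    Bt = as.numeric(crossprod(dg, A %*% dg))
  )
}

# All permutations of 1..k as a k! x k integer matrix (k small).
.all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 0L
  for (pos in seq_len(k)) {
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      v <- sub[r, ]
      out[row, ] <- append(v, k, after = pos - 1L)
    }
  }
  out
}

.perm_var_closed <- function(n, fA, fB) {
  (n*(n + 1)/((n - 3)*(n - 2)*(n - 1))) * fA[["S2"]] * fB[["S2"]] +
      (-1/((n - 3)*(n - 2))) * fA[["S2"]] * fB[["T"]] * fB[["T"]] +
      (-2/((n - 3)*(n - 2))) * fA[["S2"]] * fB[["T2"]] +
      (-1/((n - 3)*(n - 2))) * fA[["T"]] * fA[["T"]] * fB[["S2"]] +
      ((n^2 - 2*n - 1)/(n*(n - 3)*(n - 2)*(n - 1)^2)) * fA[["T"]] * fA[["T"]] * fB[["T"]] * fB[["T"]] +
      (2/(n*(n - 3)*(n - 2)*(n - 1))) * fA[["T"]] * fA[["T"]] * fB[["T2"]] +
      (-2/((n - 3)*(n - 2))) * fA[["T2"]] * fB[["S2"]] +
      (2/(n*(n - 3)*(n - 2)*(n - 1))) * fA[["T2"]] * fB[["T"]] * fB[["T"]] +
      (2/(n*(n - 3))) * fA[["T2"]] * fB[["T2"]]
}

.perm_m3_closed <- function(n, fA, fB) {
  (6*(n^3 - 6*n^2 + 9*n + 12)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 1))) * fA[["Bt"]] * fB[["Bt"]] +
      (24*(n^3 - 2*n^2 - 3*n + 12)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["Bt"]] * fB[["R"]] +
      (6*(2*n^3 - 7*n^2 - 3*n + 12)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["Bt"]] * fB[["S2"]] * fB[["T"]] +
      (-6*(n^2 - n + 4)/((n - 5)*(n - 4)*(n - 3)*(n - 2))) * fA[["Bt"]] * fB[["S3"]] +
      (-6/(n*(n - 5)*(n - 3)*(n - 2))) * fA[["Bt"]] * fB[["T"]] * fB[["T"]] * fB[["T"]] +
      (-24/(n*(n - 5)*(n - 4)*(n - 1))) * fA[["Bt"]] * fB[["T"]] * fB[["T2"]] +
      (-24*(n^2 - 5*n + 8)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["Bt"]] * fB[["T3"]] +
      (24*(n^2 - n - 4)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["Bt"]] * fB[["U"]] +
      (24*(n^3 - 2*n^2 - 3*n + 12)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["R"]] * fB[["Bt"]] +
      (12*(n + 4)*(n^2 - 3*n + 6)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 1))) * fA[["R"]] * fB[["R"]] +
      (12*(n^3 - 2*n^2 + 9*n - 12)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["R"]] * fB[["S2"]] * fB[["T"]] +
      (-12*(n - 1)*(n + 4)/((n - 5)*(n - 4)*(n - 3)*(n - 2))) * fA[["R"]] * fB[["S3"]] +
      (-24/(n*(n - 5)*(n - 4)*(n - 3)*(n - 1))) * fA[["R"]] * fB[["T"]] * fB[["T"]] * fB[["T"]] +
      (-12*(n^2 - 5*n + 12)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 1))) * fA[["R"]] * fB[["T"]] * fB[["T2"]] +
      (-24*(n^2 - 5*n + 8)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 1))) * fA[["R"]] * fB[["T3"]] +
      (24*(n^2 - n - 4)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 1))) * fA[["R"]] * fB[["U"]] +
      (6*(2*n^3 - 7*n^2 - 3*n + 12)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["S2"]] * fA[["T"]] * fB[["Bt"]] +
      (12*(n^3 - 2*n^2 + 9*n - 12)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["S2"]] * fA[["T"]] * fB[["R"]] +
      (9*(n^4 - 3*n^3 - 3*n^2 - 7*n + 4)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1)^2)) * fA[["S2"]] * fA[["T"]] * fB[["S2"]] * fB[["T"]] +
      (-3*(n - 1)*(n + 4)/((n - 5)*(n - 4)*(n - 3)*(n - 2))) * fA[["S2"]] * fA[["T"]] * fB[["S3"]] +
      (-6*(n^2 - 4*n - 2)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["S2"]] * fA[["T"]] * fB[["T"]] * fB[["T"]] * fB[["T"]] +
      (-12*(n^2 - 2*n - 6)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["S2"]] * fA[["T"]] * fB[["T"]] * fB[["T2"]] +
      (-48/(n*(n - 5)*(n - 4)*(n - 3)*(n - 1))) * fA[["S2"]] * fA[["T"]] * fB[["T3"]] +
      (12*(n^2 - n + 4)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["S2"]] * fA[["T"]] * fB[["U"]] +
      (-6*(n^2 - n + 4)/((n - 5)*(n - 4)*(n - 3)*(n - 2))) * fA[["S3"]] * fB[["Bt"]] +
      (-12*(n - 1)*(n + 4)/((n - 5)*(n - 4)*(n - 3)*(n - 2))) * fA[["S3"]] * fB[["R"]] +
      (-3*(n - 1)*(n + 4)/((n - 5)*(n - 4)*(n - 3)*(n - 2))) * fA[["S3"]] * fB[["S2"]] * fB[["T"]] +
      (n*(n + 1)*(n^2 + 15*n - 4)/((n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["S3"]] * fB[["S3"]] +
      (2/((n - 5)*(n - 4)*(n - 3))) * fA[["S3"]] * fB[["T"]] * fB[["T"]] * fB[["T"]] +
      (12/((n - 5)*(n - 4)*(n - 3))) * fA[["S3"]] * fB[["T"]] * fB[["T2"]] +
      (16/((n - 5)*(n - 4)*(n - 3))) * fA[["S3"]] * fB[["T3"]] +
      (-4*(n^2 - n + 4)/((n - 5)*(n - 4)*(n - 3)*(n - 2))) * fA[["S3"]] * fB[["U"]] +
      (-6/(n*(n - 5)*(n - 3)*(n - 2))) * fA[["T"]] * fA[["T"]] * fA[["T"]] * fB[["Bt"]] +
      (-24/(n*(n - 5)*(n - 4)*(n - 3)*(n - 1))) * fA[["T"]] * fA[["T"]] * fA[["T"]] * fB[["R"]] +
      (-6*(n^2 - 4*n - 2)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["T"]] * fA[["T"]] * fA[["T"]] * fB[["S2"]] * fB[["T"]] +
      (2/((n - 5)*(n - 4)*(n - 3))) * fA[["T"]] * fA[["T"]] * fA[["T"]] * fB[["S3"]] +
      (2*(2*n^3 - 13*n^2 + 12*n + 23)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1)^3)) * fA[["T"]] * fA[["T"]] * fA[["T"]] * fB[["T"]] * fB[["T"]] * fB[["T"]] +
      (24/(n*(n - 5)*(n - 3)*(n - 2)*(n - 1)^2)) * fA[["T"]] * fA[["T"]] * fA[["T"]] * fB[["T"]] * fB[["T2"]] +
      (8/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["T"]] * fA[["T"]] * fA[["T"]] * fB[["T3"]] +
      (-16/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["T"]] * fA[["T"]] * fA[["T"]] * fB[["U"]] +
      (-24/(n*(n - 5)*(n - 4)*(n - 1))) * fA[["T"]] * fA[["T2"]] * fB[["Bt"]] +
      (-12*(n^2 - 5*n + 12)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 1))) * fA[["T"]] * fA[["T2"]] * fB[["R"]] +
      (-12*(n^2 - 2*n - 6)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["T"]] * fA[["T2"]] * fB[["S2"]] * fB[["T"]] +
      (12/((n - 5)*(n - 4)*(n - 3))) * fA[["T"]] * fA[["T2"]] * fB[["S3"]] +
      (24/(n*(n - 5)*(n - 3)*(n - 2)*(n - 1)^2)) * fA[["T"]] * fA[["T2"]] * fB[["T"]] * fB[["T"]] * fB[["T"]] +
      (12*(n^2 - 7*n + 13)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["T"]] * fA[["T2"]] * fB[["T"]] * fB[["T2"]] +
      (24/(n*(n - 5)*(n - 4)*(n - 2)*(n - 1))) * fA[["T"]] * fA[["T2"]] * fB[["T3"]] +
      (-12*(n^2 - 5*n + 8)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["T"]] * fA[["T2"]] * fB[["U"]] +
      (-24*(n^2 - 5*n + 8)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["T3"]] * fB[["Bt"]] +
      (-24*(n^2 - 5*n + 8)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 1))) * fA[["T3"]] * fB[["R"]] +
      (-48/(n*(n - 5)*(n - 4)*(n - 3)*(n - 1))) * fA[["T3"]] * fB[["S2"]] * fB[["T"]] +
      (16/((n - 5)*(n - 4)*(n - 3))) * fA[["T3"]] * fB[["S3"]] +
      (8/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["T3"]] * fB[["T"]] * fB[["T"]] * fB[["T"]] +
      (24/(n*(n - 5)*(n - 4)*(n - 2)*(n - 1))) * fA[["T3"]] * fB[["T"]] * fB[["T2"]] +
      (8*(n^3 - 9*n^2 + 26*n - 22)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["T3"]] * fB[["T3"]] +
      (-8*(3*n^2 - 15*n + 16)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["T3"]] * fB[["U"]] +
      (24*(n^2 - n - 4)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["U"]] * fB[["Bt"]] +
      (24*(n^2 - n - 4)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 1))) * fA[["U"]] * fB[["R"]] +
      (12*(n^2 - n + 4)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["U"]] * fB[["S2"]] * fB[["T"]] +
      (-4*(n^2 - n + 4)/((n - 5)*(n - 4)*(n - 3)*(n - 2))) * fA[["U"]] * fB[["S3"]] +
      (-16/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["U"]] * fB[["T"]] * fB[["T"]] * fB[["T"]] +
      (-12*(n^2 - 5*n + 8)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["U"]] * fB[["T"]] * fB[["T2"]] +
      (-8*(3*n^2 - 15*n + 16)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["U"]] * fB[["T3"]] +
      (4*(n^4 - 8*n^3 + 19*n^2 - 4*n - 16)/(n*(n - 5)*(n - 4)*(n - 3)*(n - 2)*(n - 1))) * fA[["U"]] * fB[["U"]]
}

#' Exact permutation moments of the trace statistic
#'
#' Mean, variance and skewness of
#' \eqn{T(\pi) = \sum_{ij} A_{ij} B_{\pi(i)\pi(j)}} under the uniform
#' distribution on all \eqn{k!} permutations, where \code{A} and \code{B}
#' are symmetric doubly centered matrices (typically centered kernel
#' matrices). The mean has the classical form
#' \eqn{\mu = \mathrm{tr}(A)\,\mathrm{tr}(B)/(k-1)}; variance and skewness
#' are closed-form polynomials in elementary trace/diagonal functionals of
#' the two matrices. These are exact functionals, not Monte Carlo estimates.
#'
#' @param A,B symmetric doubly centered matrices of equal size
#'   \eqn{k \ge 4}.
#' @return Object of class \code{"permutation_moments"}: list with
#'   \code{mu}, \code{sigma2}, \code{gamma} (skewness; \code{NA} when the
#'   distribution is degenerate) and \code{degenerate}.
#' @export
permutation_moments <- function(A, B) {
  A <- unclass(as.matrix(A)); B <- unclass(as.matrix(B))
  k <- nrow(A)
  if (ncol(A) != k || nrow(B) != k || ncol(B) != k) {
    stop("'A' and 'B' must be square matrices of the same size",
         call. = FALSE)
  }
  if (k < 4L) {
    stop("permutation moments need k >= 4 (third-moment expressions ",
         "degenerate below that)", call. = FALSE)
  }
  sc <- max(abs(A), abs(B), 1)
  if (max(abs(rowSums(A)), abs(rowSums(B))) > 1e-8 * sc * k) {
    stop("'A' and 'B' must be doubly centered (use double_center())",
         call. = FALSE)
  }
  if (k < 6L) {
    pm <- .all_permutations(k)
    tv <- apply(pm, 1L, function(p) sum(A * B[p, p]))
    mu <- mean(tv)
    sigma2 <- mean((tv - mu)^2)
    m3 <- mean((tv - mu)^3)
  } else {
    fA <- .kernel_functionals(A)
    fB <- .kernel_functionals(B)
    mu <- fA$T * fB$T / (k - 1)
    sigma2 <- .perm_var_closed(k, fA, fB)
    m3 <- .perm_m3_closed(k, fA, fB)
  }
  # natural scale of the variance is ||A||_F^2 ||B||_F^2 / k^2
  vscale <- sum(A * A) * sum(B * B) / k^2
  degenerate <- !(sigma2 > 1e-14 * max(vscale, .Machine$double.xmin))
  gamma <- if (degenerate) NA_real_ else m3 / sigma2^1.5
  structure(list(mu = mu, sigma2 = max(sigma2, 0), gamma = gamma,
                 degenerate = degenerate),
            class = "permutation_moments")
}

#' @export
print.permutation_moments <- function(x, ...) {
  cat("Permutation moments of the trace statistic\n")
  cat(sprintf("  mean     %.6g\n", x$mu))
  cat(sprintf("  variance %.6g\n", x$sigma2))
  cat(sprintf("  skewness %.6g%s\n",
              if (is.na(x$gamma)) NA else x$gamma,
              if (x$degenerate) "  (degenerate)" else ""))
  invisible(x)
}
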