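# Symmetric eigen machinery shared by the estimator and the bootstrap
# transform. Positive definiteness is judged relative to the largest
# eigenvalue: smallest/largest > pd_tol.

pd_tol <- 1e-10

sym_eigen <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix")
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop(what, " must be symmetric")
  eigen((m + t(m)) / 2, symmetric = TRUE)
}

assert_pd <- function(e, what = "matrix") {
  lo <- min(e$values)
  hi <- max(e$values)
  if (lo <= pd_tol * max(hi, 1))
    stop(what, " is not positive-definite (smallest eigenvalue ",
         format(lo, digits = 4), ")")
  e
}

#' Symmetric (spectral) matrix square root and inverse square root
#'
#' For a symmetric positive-definite matrix M with eigendecomposition
#' \eqn{M = V D V'}, \code{matrix_sqrt} returns \eqn{V D^{1/2} V'} and
#' \code{matrix_inv_sqrt} returns \eqn{V D^{-1/2} V'}, the unique symmetric
#' positive-definite roots. The inverse root R satisfies R M R = I. These
#' symmetric roots (never triangular factors) are used in the maxvar
#' eigenproblem and in the Bollen-Stine data transformation so that results
#' are reproducible independent of factorization order.
#'
#' @param m symmetric positive-definite matrix.
#' @return a symmetric matrix of the same dimension.
#' @examples
#' matrix_inv_sqrt(diag(c(4, 9)))
#' @export
matrix_inv_sqrt <- function(m) {
  e <- assert_pd(sym_eigen(m))
  r <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  (r + t(r)) / 2
}

# hot-path variant: input known symmetric, PD still verified
inv_sqrt_fast <- function(m, what = "matrix") {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) <= pd_tol * max(max(e$values), 1))
    stop(what, " is not positive-definite (smallest eigenvalue ",
         format(min(e$values), digits = 4), ")")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' @rdname matrix_inv_sqrt
#' @export
matrix_sqrt <- function(m) {
  e <- assert_pd(sym_eigen(m))
  r <- e$vectors %*% (t(e$vectors) * sqrt(e$values))
  (r + t(r)) / 2
}
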