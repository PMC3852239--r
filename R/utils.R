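`%||%` <- function(a, b) if (is.null(a)) b else a

#' Null space of a matrix by singular value decomposition
#'
#' Columns of the returned matrix span \{x : A x = 0\}.  Singular values below
#' `tol * max(singular value)` are treated as zero, which keeps the computation
#' robust for rank-deficient stoichiometric matrices.
#'
#' @param A numeric matrix (may have zero rows).
#' @param tol relative singular-value threshold.
#' @return matrix with `ncol(A)` rows; zero columns if the null space is trivial.
#' @export
null_space <- function(A, tol = 1e-10) {
  n <- ncol(A)
  if (is.null(n)) stop("A must be a matrix")
  if (nrow(A) == 0L || all(A == 0)) return(diag(1, n))
  sv <- svd(A, nu = 0, nv = n)
  d <- sv$d
  rank <- sum(d > tol * max(d))
  if (rank >= n) return(matrix(0, n, 0))
  sv$v[, (rank + 1L):n, drop = FALSE]
}

matrix_rank <- function(A, tol = 1e-10) {
  if (nrow(A) == 0L || ncol(A) == 0L) return(0L)
  d <- svd(A, nu = 0, nv = 0)$d
  if (max(d) == 0) return(0L)
  sum(d > tol * max(d))
}

## left null space: rows a with a' A = 0 (conservation relations)
left_null_space <- function(A, tol = 1e-10) t(null_space(t(A), tol))

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
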