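#' Jacobi-preconditioned conjugate gradient solver
#'
#' Solves the symmetric positive-definite sparse system \code{A x = b} with
#' conjugate gradients, preconditioned by the diagonal of \code{A}.  Used by
#' the semi-implicit free-surface solver, where the system is SPD by
#' construction.
#'
#' @param A sparse symmetric positive-definite matrix (a \pkg{Matrix} object).
#' @param b right-hand side vector.
#' @param x0 initial guess (defaults to \code{b}).
#' @param tol relative residual tolerance \eqn{\|Ax-b\|/\|b\|}.
#' @param maxiter iteration cap.
#' @return list with \code{x}, \code{iterations}, \code{residual}.
#' @keywords internal
pcg_solve <- function(A, b, x0 = NULL, tol = 1e-12, maxiter = 1000L) {
  n <- length(b)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) {
    return(list(x = numeric(n), iterations = 0L, residual = 0))
  }
  x <- if (is.null(x0)) numeric(n) else x0
  d <- Matrix::diag(A)
  if (any(d <= 0)) stop("pcg_solve: non-positive diagonal; system not SPD")
  r <- b - as.numeric(A %*% x)
  z <- r / d
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxiter)) {
    res <- sqrt(sum(r * r)) / bnorm
    if (res <= tol) {
      return(list(x = x, iterations = it - 1L, residual = res))
    }
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  res <- sqrt(sum(r * r)) / bnorm
  if (res > tol) {
    stop(sprintf(
      "pcg_solve: no convergence in %d iterations (relative residual %.3e)",
      maxiter, res
    ))
  }
  list(x = x, iterations = maxiter, residual = res)
}

# Thomas algorithm for a tridiagonal system; lower/diag/upper are the three
# bands (lower[1] and upper[n] are ignored).  Stable for the diagonally
# dominant M-matrices arising from implicit vertical diffusion/advection.
solve_tridiag <- function(lower, diag_, upper, rhs) {
  n <- length(rhs)
  if (n == 1L) return(rhs / diag_)
  cp <- numeric(n)
  dp <- numeric(n)
  cp[1] <- upper[1] / diag_[1]
  dp[1] <- rhs[1] / diag_[1]
  for (i in 2:n) {
    m <- diag_[i] - lower[i] * cp[i - 1]
    cp[i] <- if (i < n) upper[i] / m else 0
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Adams-Bashforth 2 combination; first step (prev = NULL) is forward Euler.
ab2_combine <- function(current, prev) {
  if (is.null(prev)) current else 1.5 * current - 0.5 * prev
}
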