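# Internal numerical helpers. All dense linear algebra goes through Cholesky
# factorizations; densities and responsibilities are handled in log space.

# Symmetrize a nearly-symmetric matrix.
symm <- function(A) (A + t(A)) / 2

# Cholesky with escalating diagonal jitter. `what` names the matrix in the
# error message when even the largest jitter fails.
chol_jitter <- function(A, what = "matrix", max_tries = 6L) {
  A <- symm(A)
  U <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(U)) return(U)
  scale <- mean(abs(diag(A)))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  jit <- 1e-10 * scale
  for (k in seq_len(max_tries)) {
    U <- tryCatch(chol(A + diag(jit, nrow(A))), error = function(e) NULL)
    if (!is.null(U)) return(U)
    jit <- jit * 100
  }
  stop(what, " is not positive definite (Cholesky failed after jitter)",
       call. = FALSE)
}

# log |A| from its upper Cholesky factor
logdet_from_chol <- function(U) 2 * sum(log(diag(U)))

# Row-wise log-sum-exp of a matrix; never returns NaN for finite input.
logsumexp_rows <- function(L) {
  m <- apply(L, 1L, max)
  m + log(rowSums(exp(L - m)))
}

# Quadratic forms q_n = x_n' A x_n for rows x_n of X, with A = U'U (U = chol(A)).
quad_rows_chol <- function(X, U) {
  Z <- X %*% t(U)
  rowSums(Z * Z)
}

# Quadratic forms q_n = x_n' C^{-1} x_n given U = chol(C).
quad_rows_inv_chol <- function(X, U) {
  Z <- backsolve(U, t(X), transpose = TRUE)
  colSums(Z * Z)
}

# Draw n rows from N(mu, Sigma); Sigma may be exactly zero (degenerate).
rmvnorm_rows <- function(n, mu, Sigma) {
  d <- length(mu)
  if (all(Sigma == 0)) {
    return(matrix(mu, n, d, byrow = TRUE))
  }
  U <- chol_jitter(Sigma, "covariance")
  Z <- matrix(rnorm(n * d), n, d) %*% U
  sweep(Z, 2L, mu, "+")
}

# Multivariate digamma-style sum used by E[ln|Lambda|] of a Wishart.
mvdigamma_half <- function(nu, d) sum(digamma((nu + 1 - seq_len(d)) / 2))

# log normalizing constant ln B(B, nu) of a Wishart W(Lambda | B, nu),
# parameterized so that E[Lambda] = nu * B. Takes ln|B| precomputed.
wishart_lnB <- function(logdetB, nu, d) {
  -(nu / 2) * logdetB - (nu * d / 2) * log(2) -
    (d * (d - 1) / 4) * log(pi) -
    sum(lgamma((nu + 1 - seq_len(d)) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_matrix <- function(x, what = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x))
    stop("`", what, "` must be a numeric matrix", call. = FALSE)
  x
}
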