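# Independent oracles used across the test files. These deliberately avoid
# the package's internal code paths: plain solve()/determinant() linear
# algebra, direct formula transcriptions, and Monte Carlo samplers.

# --- single-component Bayesian linear regression with ARD -------------------
# One-expert variational inference written from scratch: Gaussian-Wishart
# posterior for the input cluster, matrix-Normal-Wishart for the regression,
# Gamma ARD precisions, and the evidence lower bound. Fixed point comparable
# with moe_fit(..., M_init = 1).
blr_ard_oracle <- function(X, Y, beta0 = 0.01, nu0 = ncol(X),
                           lambda0 = ncol(Y), c0 = 0.01, d0 = 1e-4,
                           max_iter = 1000L, tol = 0) {
  N <- nrow(X); dx <- ncol(X); q <- ncol(Y); p <- dx + 1L
  B0 <- diag(dx); Q0 <- diag(q)
  Xt <- cbind(X, 1)
  m0 <- colMeans(X)

  # gate posterior (closed form, responsibilities all one)
  beta <- beta0 + N
  m <- (beta0 * m0 + colSums(X)) / beta
  nu <- nu0 + N
  Binv <- solve(B0) + t(X) %*% X + beta0 * tcrossprod(m0) -
    beta * tcrossprod(m)
  B <- solve(Binv)

  lambda <- lambda0 + N
  ups <- rep(c0 / d0, p)
  cpar <- c0 + q / 2
  for (it in seq_len(max_iter)) {
    C <- t(Xt) %*% Xt + diag(ups, p)
    L <- solve(C)
    W <- L %*% t(Xt) %*% Y
    Qinv <- solve(Q0) + t(Y) %*% Y - t(W) %*% C %*% W
    Q <- solve((Qinv + t(Qinv)) / 2)
    xi <- q * diag(L) + lambda * rowSums((W %*% Q) * W)
    dpar <- d0 + xi / 2
    ups_new <- cpar / dpar
    delta <- max(abs(ups_new - ups) / pmax(abs(ups), 1e-12))
    ups <- ups_new
    if (tol > 0 && delta < tol) break
  }

  ldet <- function(A) determinant(A, logarithm = TRUE)$modulus[1]
  mvdig <- function(a, d) sum(digamma((a + 1 - seq_len(d)) / 2))
  lnBw <- function(S_logdet, dof, d)
    -(dof / 2) * S_logdet - (dof * d / 2) * log(2) -
      (d * (d - 1) / 4) * log(base::pi) -
      sum(lgamma((dof + 1 - seq_len(d)) / 2))

  ElnLam <- mvdig(nu, dx) + dx * log(2) + ldet(B)
  ElnChi <- mvdig(lambda, q) + q * log(2) + ldet(Q)

  # expected data log-densities
  Xc <- sweep(X, 2, m)
  quadx <- rowSums((Xc %*% B) * Xc)
  Ex <- sum(0.5 * ElnLam - dx / 2 * log(2 * base::pi) -
              0.5 * (nu * quadx + dx / beta))
  Eres <- Y - Xt %*% W
  quady <- rowSums((Eres %*% Q) * Eres)
  quadL <- rowSums((Xt %*% L) * Xt)
  Ey <- sum(0.5 * ElnChi - q / 2 * log(2 * base::pi) -
              0.5 * (lambda * quady + q * quadL))

  dm <- m - m0
  gate_kl <- 0.5 * dx * (log(beta0 / beta) - beta0 / beta + 1) -
    0.5 * beta0 * nu * drop(t(dm) %*% B %*% dm) +
    lnBw(ldet(B0), nu0, dx) - lnBw(ldet(B), nu, dx) +
    0.5 * (nu0 - nu) * ElnLam -
    0.5 * nu * sum(diag(solve(B0) %*% B)) + 0.5 * nu * dx

  Elna <- digamma(cpar) - log(dpar)
  wQw <- rowSums((W %*% Q) * W)
  W_kl <- 0.5 * q * (sum(Elna) + ldet(L)) -
    0.5 * (q * sum(ups * diag(L)) + lambda * sum(ups * wQw)) + 0.5 * p * q

  chi_kl <- lnBw(ldet(Q0), lambda0, q) - lnBw(ldet(Q), lambda, q) +
    0.5 * (lambda0 - lambda) * ElnChi -
    0.5 * lambda * sum(diag(solve(Q0) %*% Q)) + 0.5 * lambda * q

  ard_kl <- sum(c0 * log(d0) - lgamma(c0) + lgamma(cpar) -
                  cpar * log(dpar) + (c0 - cpar) * Elna -
                  d0 * cpar / dpar + cpar)

  list(W = W, L = L, lambda = lambda, Q = Q,
       bound = Ex + Ey + gate_kl + W_kl + chi_kl + ard_kl)
}

# --- expert matching --------------------------------------------------------
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

# Best assignment of fitted experts to ground-truth experts by total
# Frobenius distance between weight matrices (exhaustive, small M).
match_experts <- function(fit_W, true_W) {
  M <- length(true_W)
  best <- Inf; bestp <- NULL
  for (p in all_perms(seq_len(M))) {
    err <- sum(vapply(seq_len(M), function(i)
      norm(fit_W[[p[i]]] - true_W[[i]], "F")^2, numeric(1)))
    if (err < best) { best <- err; bestp <- p }
  }
  bestp
}

# --- Monte Carlo sampler from a matrix-Normal-Wishart posterior -------------
# Draws (W, chi) ~ MN(W | What, L, chi^-1) W(chi | Q, lambda) and then
# y ~ N(W'[x 1], chi^-1). Marginalizing W given chi, the draw reduces to
# y = W_hat'[x 1] + sqrt(1 + xt' L xt) * chol(chi^-1) z. Vectorized for
# d_y = 2 (analytic 2x2 inverse and Cholesky). Returns n draws (n x 2).
mc_predictive_draws <- function(What, L, lambda, Q, x, n = 1e5) {
  stopifnot(ncol(What) == 2L)
  xt <- c(x, 1)
  m <- drop(crossprod(What, xt))
  cfac <- 1 + drop(t(xt) %*% L %*% xt)
  chis <- stats::rWishart(n, df = lambda, Sigma = Q)
  a <- chis[1, 1, ]; b <- chis[1, 2, ]; d <- chis[2, 2, ]
  det <- a * d - b * b
  s11 <- d / det; s12 <- -b / det; s22 <- a / det   # chi^{-1}
  l11 <- sqrt(s11); l21 <- s12 / l11; l22 <- sqrt(s22 - l21^2)
  z1 <- rnorm(n); z2 <- rnorm(n)
  cbind(m[1] + sqrt(cfac) * l11 * z1,
        m[2] + sqrt(cfac) * (l21 * z1 + l22 * z2))
}

# Monte Carlo draws of the per-row quadratic w_j chi w_j' under
# (W, chi) ~ MN(W | What, L, chi^-1) W(chi | Q, lambda): W = What + A Z B'
# with A A' = L and B B' = chi^{-1}. Returns an n x p matrix of draws.
mc_row_chi_quad <- function(What, L, lambda, Q, n = 1e5) {
  p <- nrow(What); q <- ncol(What)
  AL <- t(chol(L))
  chis <- stats::rWishart(n, df = lambda, Sigma = Q)
  out <- matrix(0, n, p)
  for (k in seq_len(n)) {
    Sigma <- solve(chis[, , k])
    Bc <- t(chol((Sigma + t(Sigma)) / 2))
    W <- What + AL %*% matrix(rnorm(p * q), p, q) %*% t(Bc)
    out[k, ] <- rowSums((W %*% chis[, , k]) * W)
  }
  out
}

# small standard fixture: 3 well-separated experts in 4-D with 2 force DoF
fixture_gt <- function(seed = 1, M = 3, d_x = 4, d_y = 2, separation = 8,
                       noise = 0.1) {
  make_ground_truth(M, d_x = d_x, d_y = d_y, separation = separation,
                    noise_scale = noise, seed = seed)
}
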