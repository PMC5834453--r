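# Variational updates: closed-form identities, limiting cases, independent
# oracles, and the coordinate-ascent structure of the algorithm.

make_small_problem <- function(seed = 1, M = 2, n = 60) {
  gt <- make_ground_truth(M, d_x = 3, d_y = 2, separation = 6,
                          noise_scale = 0.2, seed = seed)
  ses <- sample_session(gt, n_per_block = n, n_repetitions = 1,
                        rest_fraction = 0, seed = seed + 50)
  list(gt = gt, X = ses$X, Y = ses$Y, z = ses$z)
}

test_that("initialization is normalized, deterministic, prior-centered", {
  p <- make_small_problem()
  hy <- moe_hyper(3, 2, M_init = 4)
  st <- init_state(p$X, p$Y, hy, seed = 3)
  expect_equal(rowSums(st$r), rep(1, nrow(p$X)))
  expect_true(all(st$r >= 0 & st$r <= 1))
  expect_equal(st$Upsilon, matrix(0.01 / 1e-4, 4, 4))
  expect_equal(st$pi, rep(0.25, 4))
  expect_equal(dim(st$hyper$m0), c(4L, 3L))
  expect_identical(st, init_state(p$X, p$Y, hy, seed = 3))

  st1 <- init_state(p$X, p$Y, moe_hyper(3, 2, M_init = 1), seed = 3)
  expect_equal(st1$r, matrix(1, nrow(p$X), 1))
  expect_error(init_state(p$X[1:2, ], p$Y[1:2, ],
                          moe_hyper(3, 2, M_init = 5), 1), "at least")
})

test_that("gate posteriors: prior for empty experts, data-dominated limits", {
  p <- make_small_problem()
  hy <- moe_hyper(3, 2, M_init = 2)
  hy$m0 <- matrix(0, 2, 3)
  r <- cbind(rep(1, nrow(p$X)), 0)    # expert 2 gets nothing
  g <- vbm_gates(p$X, r, hy)
  expect_equal(g$m[2, ], hy$m0[2, ])
  expect_equal(g$beta[2], hy$beta0)
  expect_equal(g$nu[2], hy$nu0)
  expect_equal(g$B[[2]], hy$B0)
  # beta_i >= beta0, nu_i >= nu0, B SPD: Cholesky succeeded inside
  expect_true(all(g$beta >= hy$beta0) && all(g$nu >= hy$nu0))

  # beta0 -> 0, single expert: posterior mean -> sample mean
  hy0 <- moe_hyper(3, 2, M_init = 1, beta0 = 1e-12)
  hy0$m0 <- matrix(50, 1, 3)
  g0 <- vbm_gates(p$X, matrix(1, nrow(p$X), 1), hy0)
  expect_equal(g0$m[1, ], colMeans(p$X), tolerance = 1e-9)

  # precision mean E[Lambda] = nu B approaches the inverse sample covariance
  set.seed(9)
  Sig <- matrix(c(0.04, 0.01, 0.01, 0.03), 2)
  Xs <- matrix(rnorm(20000), 10000) %*% chol(Sig)
  hyc <- moe_hyper(2, 1, M_init = 1)
  hyc$m0 <- matrix(0, 1, 2)
  gc <- vbm_gates(Xs, matrix(1, 10000, 1), hyc)
  ELam <- gc$nu[1] * gc$B[[1]]
  expect_equal(ELam, solve(cov(Xs)), tolerance = 0.05)
})

test_that("expert posteriors: prior under zero responsibility, OLS limit", {
  p <- make_small_problem()
  N <- nrow(p$X)
  hy <- moe_hyper(3, 2, M_init = 2)
  hy$m0 <- matrix(0, 2, 3)
  Ups <- matrix(100, 2, 4)
  r <- cbind(rep(1, N), 0)
  e <- vbm_experts(p$X, p$Y, r, Ups, hy)
  expect_equal(e$W[[2]], matrix(0, 4, 2))
  expect_equal(e$L[[2]], diag(1 / 100, 4))
  expect_equal(e$Q[[2]], hy$Q0)
  expect_equal(e$lambda, hy$lambda0 + c(N, 0))

  # noiseless single expert with vanishing ARD precision: W -> OLS
  set.seed(10)
  X <- matrix(rnorm(300), 100, 3)
  Wtrue <- matrix(rnorm(8), 4, 2)
  Y <- cbind(X, 1) %*% Wtrue
  eo <- vbm_experts(X, Y, matrix(1, 100, 1), matrix(1e-12, 1, 4),
                    moe_hyper(3, 2, M_init = 1))
  Wols <- solve(crossprod(cbind(X, 1)), crossprod(cbind(X, 1), Y))
  expect_equal(eo$W[[1]], Wols, tolerance = 1e-8)
  expect_equal(eo$W[[1]], Wtrue, tolerance = 1e-6)
})

test_that("ARD posterior constants, suppression mechanism, MC oracle", {
  # c_i = c0 + d_y/2: with 6 DoF and c0 = 0.01 this is 3.01
  p <- make_small_problem()
  hy6 <- moe_hyper(3, 6, M_init = 1)
  e6 <- vbm_experts(p$X, cbind(p$Y, p$Y, p$Y), matrix(1, nrow(p$X), 1),
                    matrix(1, 1, 4), hy6)
  a6 <- vbm_ard(e6, hy6)
  expect_equal(a6$c, 3.01)

  # an input with zero weight and vanishing posterior variance is driven to
  # the prior rate d0, i.e. a huge precision expectation
  e_null <- e6
  e_null$W[[1]][2, ] <- 0
  e_null$L[[1]][2, 2] <- 0
  a_null <- vbm_ard(e_null, hy6)
  expect_equal(a_null$d[1, 2], hy6$d0)
  expect_equal(a_null$Upsilon[1, 2], 3.01 / 1e-4)

  # xi_ij equals E_q[w_j chi w_j'] under the matrix-Normal-Wishart posterior
  hy <- moe_hyper(3, 2, M_init = 1)
  e <- vbm_experts(p$X, p$Y, matrix(1, nrow(p$X), 1), matrix(1, 1, 4), hy)
  a <- vbm_ard(e, hy)
  xi <- 2 * (a$d[1, ] - hy$d0)
  set.seed(11)
  draws <- mc_row_chi_quad(e$W[[1]], e$L[[1]], e$lambda[1], e$Q[[1]],
                           n = 1e5)
  mc_mean <- colMeans(draws)
  mc_se <- apply(draws, 2, sd) / sqrt(nrow(draws))
  expect_true(all(abs(mc_mean - xi) < 3 * mc_se))
})

test_that("responsibilities: degenerate cases and the direct-formula oracle", {
  p <- make_small_problem()
  N <- nrow(p$X)
  hy1 <- moe_hyper(3, 2, M_init = 1)
  st1 <- init_state(p$X, p$Y, hy1, 1)
  g1 <- vbm_gates(p$X, st1$r, st1$hyper)
  e1 <- vbm_experts(p$X, p$Y, st1$r, st1$Upsilon, st1$hyper)
  expect_equal(vbe_step(p$X, p$Y, g1, e1, 1), matrix(1, N, 1))

  # identical posteriors with equal mixing: r = 0.5 by symmetry
  hy2 <- moe_hyper(3, 2, M_init = 2)
  hy2$m0 <- matrix(1, 2, 3)
  r_half <- matrix(0.5, N, 2)
  g2 <- vbm_gates(p$X, r_half, hy2)
  e2 <- vbm_experts(p$X, p$Y, r_half, matrix(1, 2, 4), hy2)
  r_out <- vbe_step(p$X, p$Y, g2, e2, c(0.5, 0.5))
  expect_equal(r_out, matrix(0.5, N, 2))

  # well-separated two-expert model: the true-label responsibilities are
  # recovered and match a from-scratch evaluation of the update formula
  hy <- moe_hyper(3, 2, M_init = 2)
  hy$m0 <- p$gt$mu_true
  r_true <- cbind(as.numeric(p$z == 1), as.numeric(p$z == 2))
  g <- vbm_gates(p$X, r_true, hy)
  e <- vbm_experts(p$X, p$Y, r_true, matrix(1, 2, 4), hy)
  pi_hat <- update_mixing(r_true)
  r_new <- vbe_step(p$X, p$Y, g, e, pi_hat)
  # query at expert 1's gate mean
  r_at_m1 <- vbe_step(matrix(g$m[1, ], 1), matrix(e$W[[1]][4, ] +
                        g$m[1, ] %*% e$W[[1]][1:3, ], 1), g, e, pi_hat)
  expect_gt(r_at_m1[1, 1], 0.99)

  # direct scalar oracle of the update equations on a few rows
  oracle_log_gamma <- function(x, y, i) {
    dx <- 3; q <- 2
    ElnLam <- sum(digamma((g$nu[i] + 1 - 1:dx) / 2)) + dx * log(2) +
      determinant(g$B[[i]], logarithm = TRUE)$modulus[1]
    ElnChi <- sum(digamma((e$lambda[i] + 1 - 1:q) / 2)) + q * log(2) +
      determinant(e$Q[[i]], logarithm = TRUE)$modulus[1]
    varpi <- g$nu[i] * drop(t(x - g$m[i, ]) %*% g$B[[i]] %*% (x - g$m[i, ])) +
      dx / g$beta[i]
    xt <- c(x, 1)
    res <- y - drop(t(e$W[[i]]) %*% xt)
    xi <- e$lambda[i] * drop(t(res) %*% e$Q[[i]] %*% res) +
      q * drop(t(xt) %*% e$L[[i]] %*% xt)
    log(pi_hat[i]) + 0.5 * (ElnLam + ElnChi - varpi - xi)
  }
  for (n in c(1, 17, 60)) {
    lg <- c(oracle_log_gamma(p$X[n, ], p$Y[n, ], 1),
            oracle_log_gamma(p$X[n, ], p$Y[n, ], 2))
    expect_equal(r_new[n, ], exp(lg) / sum(exp(lg)), tolerance = 1e-10)
  }

  # extreme separation: normalization survives underflow without NaN
  far <- matrix(c(1e3, 1e3, 1e3), 1)
  r_far <- vbe_step(far, matrix(0, 1, 2), g, e, pi_hat)
  expect_false(any(is.nan(r_far)))
  expect_equal(sum(r_far), 1)
})

test_that("mixing update and pruning behave as specified", {
  r <- matrix(1 / 3, 9, 3)
  expect_equal(update_mixing(r), rep(1 / 3, 3))
  r2 <- cbind(rep(1, 4), 0)
  expect_equal(update_mixing(r2), c(1, 0))
  set.seed(12)
  rr <- matrix(runif(50), 10)
  rr <- rr / rowSums(rr)
  expect_equal(sum(update_mixing(rr)), 1, tolerance = 1e-12)

  state <- list(r = cbind(0.5, 0.5, 0)[rep(1, 10), ],
                pi = c(0.5, 0.5, 0),
                Upsilon = matrix(1, 3, 2),
                hyper = list(m0 = matrix(1:3, 3, 1)))
  pruned <- prune_experts(state, threshold = 0.01)
  expect_equal(pruned$pi, c(0.5, 0.5))
  expect_equal(ncol(pruned$r), 2L)
  expect_equal(rowSums(pruned$r), rep(1, 10))
  # no pi below threshold: identity
  same <- prune_experts(list(r = matrix(0.5, 5, 2), pi = c(0.5, 0.5),
                             Upsilon = matrix(1, 2, 2),
                             hyper = list(m0 = matrix(1:2, 2, 1))), 0.01)
  expect_equal(same$pi, c(0.5, 0.5))
  expect_warning(
    prune_experts(list(r = matrix(0.5, 5, 2), pi = c(2e-9, 1e-9),
                       Upsilon = matrix(1, 2, 2),
                       hyper = list(m0 = matrix(1:2, 2, 1))), 0.5),
    "keeping largest")
})

test_that("every update is a coordinate-ascent step on the same bound", {
  p <- make_small_problem(seed = 21, M = 3, n = 50)
  hy <- moe_hyper(3, 2, M_init = 4)
  st <- init_state(p$X, p$Y, hy, seed = 5)
  r <- st$r; Ups <- st$Upsilon; pi_m <- st$pi; hy <- st$hyper
  gates <- vbm_gates(p$X, r, hy)
  experts <- vbm_experts(p$X, p$Y, r, Ups, hy)
  ard <- vbm_ard(experts, hy); Ups <- ard$Upsilon
  r <- vbe_step(p$X, p$Y, gates, experts, pi_m)
  lb <- function() moe_lower_bound(p$X, p$Y, r, gates, experts, ard, pi_m, hy)
  for (k in 1:12) {
    b <- lb()
    pi_m <- update_mixing(r)
    expect_gte(lb(), b - 1e-8 * abs(b)); b <- lb()
    gates <- vbm_gates(p$X, r, hy)
    expect_gte(lb(), b - 1e-8 * abs(b)); b <- lb()
    experts <- vbm_experts(p$X, p$Y, r, Ups, hy)
    expect_gte(lb(), b - 1e-8 * abs(b)); b <- lb()
    ard <- vbm_ard(experts, hy); Ups <- ard$Upsilon
    expect_gte(lb(), b - 1e-8 * abs(b)); b <- lb()
    r <- vbe_step(p$X, p$Y, gates, experts, pi_m)
    expect_gte(lb(), b - 1e-8 * abs(b))
  }
})

test_that("converged bound is a local optimum of the variational parameters", {
  p <- make_small_problem(seed = 31, M = 2, n = 80)
  fit <- moe_fit(p$X, p$Y, M_init = 2, n_restarts = 1, seed = 4,
                 max_iter = 500, tol = 1e-12)
  b_opt <- moe_lower_bound(p$X, p$Y, fit$r, fit$gates, fit$experts,
                           fit$ard, fit$pi, fit$hyper)
  for (eps in c(1e-3, -1e-3)) {
    pert <- fit$experts
    pert$W[[1]][2, 1] <- pert$W[[1]][2, 1] + eps
    b1 <- moe_lower_bound(p$X, p$Y, fit$r, fit$gates, pert, fit$ard,
                          fit$pi, fit$hyper)
    expect_lte(b1, b_opt + 1e-7 * abs(b_opt))
    gpert <- fit$gates
    gpert$m[1, 1] <- gpert$m[1, 1] + eps
    b2 <- moe_lower_bound(p$X, p$Y, fit$r, gpert, fit$experts, fit$ard,
                          fit$pi, fit$hyper)
    expect_lte(b2, b_opt + 1e-7 * abs(b_opt))
  }
})

test_that("fits are reproducible and symmetric under expert relabeling", {
  p <- make_small_problem(seed = 41, M = 2, n = 70)
  f1 <- moe_fit(p$X, p$Y, M_init = 3, n_restarts = 1, seed = 8)
  f2 <- moe_fit(p$X, p$Y, M_init = 3, n_restarts = 1, seed = 8)
  expect_identical(f1$lower_bound_trace, f2$lower_bound_trace)
  expect_identical(f1$experts$W, f2$experts$W)
  expect_equal(sum(f1$pi), 1, tolerance = 1e-10)
  expect_equal(rowSums(f1$r), rep(1, nrow(p$X)), tolerance = 1e-10)

  # permuting the initialization permutes the solution
  hy <- moe_hyper(3, 2, M_init = 2)
  st <- init_state(p$X, p$Y, hy, seed = 9)
  run_from <- function(r0, m0) {
    hyp <- st$hyper; hyp$m0 <- m0
    r <- r0; Ups <- matrix(hy$c0 / hy$d0, 2, 4); pi_m <- c(0.5, 0.5)
    for (k in 1:20) {
      pi_m <- update_mixing(r)
      gates <- vbm_gates(p$X, r, hyp)
      experts <- vbm_experts(p$X, p$Y, r, Ups, hyp)
      ard <- vbm_ard(experts, hyp); Ups <- ard$Upsilon
      r <- vbe_step(p$X, p$Y, gates, experts, pi_m)
    }
    list(r = r, pi = pi_m)
  }
  a <- run_from(st$r, st$hyper$m0)
  b <- run_from(st$r[, 2:1], st$hyper$m0[2:1, ])
  expect_equal(a$r, b$r[, 2:1], tolerance = 1e-9)
})
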