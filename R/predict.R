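# Posterior predictive distribution with winner-takes-all gating.
#
# The gate of each expert is evaluated at the MAP estimates of its
# Gaussian-Wishart posterior (mean m_i, precision set to the Wishart
# posterior mean nu_i B_i, which is always defined); the winning expert's
# matrix-Normal-Wishart posterior yields a multivariate Student-t predictive.

#' Gate probabilities at new inputs
#'
#' Normalized-Gaussian gate values `g_i(x) \propto pi_i N(x | m_i,
#' (nu_i B_i)^{-1})`, computed in log space with a log-sum-exp guard so rows
#' never underflow.
#'
#' @param model a fitted [moe_fit()] object.
#' @param X matrix of query inputs (rows), or a single input vector.
#' @return N x M matrix of gate probabilities; rows sum to 1.
#' @export
gate_probabilities <- function(model, X) {
  stopifnot(inherits(model, "vbmoe"))
  X <- if (is.vector(X)) matrix(X, nrow = 1L) else as_matrix(X, "X")
  if (ncol(X) != model$d_x) stop("query dimension != d_x")
  M <- model$M
  lg <- matrix(0, nrow(X), M)
  for (i in seq_len(M)) {
    # MAP precision = Wishart posterior mean nu_i B_i
    Xc <- sweep(X, 2L, model$gates$m[i, ])
    qf <- model$gates$nu[i] * quad_rows_chol(Xc, model$gates$cholB[[i]])
    logdet <- model$d_x * log(model$gates$nu[i]) + model$gates$logdetB[i]
    lg[, i] <- log(model$pi[i]) + 0.5 * logdet - 0.5 * qf
  }
  exp(lg - logsumexp_rows(lg))
}

#' Classify inputs by the dominant gate
#'
#' Movement classification as a by-product of the mixture: each query is
#' assigned to the expert with the largest gate probability (ties broken by
#' the lowest expert index).
#'
#' @inheritParams gate_probabilities
#' @return integer vector of winning expert indices.
#' @export
classify <- function(model, X) {
  g <- gate_probabilities(model, X)
  max.col(g, ties.method = "first")
}

#' Posterior predictive distribution at one query point
#'
#' The winning expert's predictive is a multivariate Student-t with mean
#' `[x 1] W_i`, degrees of freedom `kappa_i = lambda_i - d_y + 1` and
#' covariance `Q_i^{-1} (1 + [x 1] L_i [x 1]') / (kappa_i - 2)` (defined for
#' `kappa_i > 2`). The `(1 + x L x')` factor inflates uncertainty away from
#' the training data.
#'
#' @param model a fitted [moe_fit()] object.
#' @param x a single d_x query vector.
#' @return an object of class `moe_prediction`: `winner`, `mean`, `dof`,
#'   `scale` (the Student-t scale matrix), `covariance` (or `NA` with a flag
#'   if `dof <= 2`), and `gate_probs`.
#' @export
predictive <- function(model, x) {
  stopifnot(inherits(model, "vbmoe"))
  x <- as.numeric(x)
  if (length(x) != model$d_x) stop("query dimension != d_x")
  g <- gate_probabilities(model, x)[1L, ]
  w <- which.max(g)
  xt <- c(x, 1)
  mean_y <- drop(crossprod(model$experts$W[[w]], xt))
  cfac <- 1 + drop(quad_rows_inv_chol(matrix(xt, 1L), model$experts$cholC[[w]]))
  kap <- model$experts$lambda[w] - model$d_y + 1
  Qinv <- chol2inv(chol_jitter(model$experts$Q[[w]], "Q"))
  scale <- Qinv * cfac / kap          # Student-t scale matrix
  cov_ok <- kap > 2
  structure(list(
    winner = w, mean = mean_y, dof = kap, scale = symm(scale),
    covariance = if (cov_ok) symm(Qinv * cfac / (kap - 2)) else NA,
    covariance_defined = cov_ok,
    gate_probs = g), class = "moe_prediction")
}

#' Confidence intervals of a predictive distribution
#'
#' Per-DoF marginal Student-t quantile intervals centered at the predictive
#' mean.
#'
#' @param pred a `moe_prediction` from [predictive()].
#' @param level interval mass, in (0, 1); 0.99 by default.
#' @return matrix with columns `lower`, `upper`, one row per force DoF.
#' @export
confidence_interval <- function(pred, level = 0.99) {
  stopifnot(inherits(pred, "moe_prediction"))
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  half <- qt((1 + level) / 2, df = pred$dof) * sqrt(diag(pred$scale))
  cbind(lower = pred$mean - half, upper = pred$mean + half)
}

#' Vectorized prediction over a test session
#'
#' Row-wise hard-gated predictive means, Student-t interval half-widths and
#' winning experts. Deterministic (no sampling involved).
#'
#' @param model a fitted [moe_fit()] object.
#' @param X N x d_x query matrix.
#' @param level confidence level for the per-DoF intervals.
#' @return list with `mean` (N x d_y), `winner` (N), `dof` (N), `lower` and
#'   `upper` (N x d_y interval bounds).
#' @export
predict_sequence <- function(model, X, level = 0.99) {
  stopifnot(inherits(model, "vbmoe"))
  X <- if (is.vector(X)) matrix(X, nrow = 1L) else as_matrix(X, "X")
  winners <- classify(model, X)
  n <- nrow(X); q <- model$d_y
  mu <- matrix(0, n, q); lo <- matrix(0, n, q); hi <- matrix(0, n, q)
  dof <- numeric(n)
  Xt <- cbind(X, 1)
  for (i in sort(unique(winners))) {
    idx <- which(winners == i)
    Xi <- Xt[idx, , drop = FALSE]
    mu[idx, ] <- Xi %*% model$experts$W[[i]]
    kap <- model$experts$lambda[i] - q + 1
    dof[idx] <- kap
    cfac <- 1 + quad_rows_inv_chol(Xi, model$experts$cholC[[i]])
    Qinv <- chol2inv(chol_jitter(model$experts$Q[[i]], "Q"))
    half <- sqrt(outer(cfac / kap, diag(Qinv))) * qt((1 + level) / 2, kap)
    lo[idx, ] <- mu[idx, , drop = FALSE] - half
    hi[idx, ] <- mu[idx, , drop = FALSE] + half
  }
  list(mean = mu, winner = winners, dof = dof, lower = lo, upper = hi,
       level = level)
}

#' Predict method for fitted mixture-of-experts models
#'
#' @param object a `vbmoe` model.
#' @param newdata feature matrix of query rows.
#' @param level confidence level for prediction intervals.
#' @param ... ignored.
#' @return see [predict_sequence()].
#' @export
predict.vbmoe <- function(object, newdata, level = 0.99, ...) {
  predict_sequence(object, newdata, level = level)
}
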