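# Regression-based global sensitivity analysis for correlated inputs, with
# Iman-Conover rank-correlated Latin hypercube sampling. Used to rank sEMG
# electrodes (individually or grouped by location) by their contribution to
# the force-output variance.

#' Rank-correlated Latin hypercube sample (Iman-Conover)
#'
#' Draws one Latin-hypercube stratified sample per column from the given
#' marginals, then rearranges each column (Iman-Conover rank shuffle on van
#' der Waerden scores) so the realized Spearman correlation approximates
#' `rank_corr`. The marginal values are untouched by the shuffle: each
#' column still occupies all `n_lhs` equiprobable strata exactly once.
#'
#' @param marginals either a numeric matrix whose columns define empirical
#'   marginals (sampled by quantile interpolation), or a list of quantile
#'   functions taking probabilities in (0, 1).
#' @param rank_corr target Spearman correlation matrix (symmetric, unit
#'   diagonal, positive definite). Identity by default.
#' @param n_lhs number of samples.
#' @param seed integer seed.
#' @return an `n_lhs x d` sample matrix.
#' @export
iman_conover_lhs <- function(marginals, rank_corr = NULL, n_lhs = 1000L,
                             seed = 1L) {
  qfuns <- marginal_quantiles(marginals)
  d <- length(qfuns)
  if (is.null(rank_corr)) rank_corr <- diag(d)
  if (!isTRUE(all.equal(rank_corr, t(rank_corr))) ||
      any(abs(diag(rank_corr) - 1) > 1e-8))
    stop("`rank_corr` must be symmetric with unit diagonal")
  # Spearman target -> Pearson correlation of the normal scores
  Cp <- 2 * sin(pi * rank_corr / 6)
  diag(Cp) <- 1
  if (min(eigen(Cp, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
    stop("`rank_corr` is not positive definite; repair it to the nearest ",
         "positive-definite correlation matrix first", call. = FALSE)
  Uc <- chol(Cp)

  set.seed(as.integer(seed))
  U <- lhs::randomLHS(n_lhs, d)
  Xs <- vapply(seq_len(d), function(j) qfuns[[j]](U[, j]), numeric(n_lhs))

  # independent van der Waerden score columns, then induce the target
  # correlation and rearrange each sample column to match the score ranks
  s <- qnorm(seq_len(n_lhs) / (n_lhs + 1))
  R <- vapply(seq_len(d), function(j) s[sample.int(n_lhs)], numeric(n_lhs))
  Rstar <- R %*% solve(chol(cor(R))) %*% Uc
  out <- vapply(seq_len(d), function(j) {
    sort(Xs[, j])[rank(Rstar[, j], ties.method = "first")]
  }, numeric(n_lhs))
  colnames(out) <- if (is.matrix(marginals)) colnames(marginals) else NULL
  out
}

marginal_quantiles <- function(marginals) {
  if (is.matrix(marginals) || is.data.frame(marginals)) {
    marginals <- as_matrix(marginals, "marginals")
    lapply(seq_len(ncol(marginals)), function(j) {
      col <- marginals[, j]
      function(p) quantile(col, probs = p, names = FALSE, type = 7L)
    })
  } else if (is.list(marginals) && all(vapply(marginals, is.function,
                                              logical(1)))) {
    marginals
  } else stop("`marginals` must be a matrix or a list of quantile functions")
}

#' Total output variance
#'
#' Population variance `mean((y - mean(y))^2)` per output column, the
#' denominator of the sensitivity indices.
#'
#' @param y_samples vector or matrix of model outputs.
#' @export
total_variance <- function(y_samples) {
  y <- as_matrix(y_samples, "y_samples")
  if (nrow(y) < 2L) stop("need at least two samples")
  colMeans(sweep(y, 2L, colMeans(y))^2)
}

#' First-order sensitivity indices for correlated inputs
#'
#' Regression-based variance decomposition: the contribution `V_j` of input
#' `j` (variance of the fitted values of a regression of the output on `x_j`
#' alone) splits into an uncorrelated part `VU_j` (the same regression on
#' the residual of `x_j` after regressing it on all other inputs) and a
#' correlated part `VC_j = V_j - VU_j`. Reported as variance shares
#' `S_j = V_j / V`, `SU_j`, `SC_j` with `S_j = SU_j + SC_j` by construction.
#' A spurious input — one that matters only through its correlation with
#' informative inputs — shows `SU_j` near zero with `SC_j` near `S_j`.
#'
#' Inputs are sampled by [iman_conover_lhs()] so that both the marginals and
#' the rank-correlation structure of the training features are respected.
#'
#' @param model_predict function mapping an `n x d_x` sample matrix to an
#'   output vector or `n x d_y` matrix (e.g. the model's predictive mean).
#' @param marginals,rank_corr passed to [iman_conover_lhs()]; when
#'   `marginals` is the training feature matrix and `rank_corr` is `NULL`,
#'   the target is the training features' Spearman matrix.
#' @param groups optional named list partitioning `1..d_x` (e.g. from
#'   [electrode_groups()]); indices are then computed per group, regressing
#'   on the group's columns jointly.
#' @param n_lhs Latin hypercube sample count.
#' @param seed integer seed.
#' @return a data.frame of class `moe_sensitivity` with columns `input` (or
#'   group name), `dof`, `S`, `SU`, `SC` and the total variance `V`.
#' @export
sensitivity_indices <- function(model_predict, marginals, rank_corr = NULL,
                                groups = NULL, n_lhs = 2000L, seed = 1L) {
  if ((is.matrix(marginals) || is.data.frame(marginals)) &&
      is.null(rank_corr)) {
    rank_corr <- cor(as_matrix(marginals), method = "spearman")
  }
  X <- iman_conover_lhs(marginals, rank_corr, n_lhs = n_lhs, seed = seed)
  d <- ncol(X)
  Yh <- model_predict(X)
  Yh <- as_matrix(Yh, "model output")
  if (nrow(Yh) != n_lhs) stop("`model_predict` must return one row per sample")
  V <- total_variance(Yh)

  if (is.null(groups)) {
    groups <- as.list(seq_len(d))
    names(groups) <- colnames(X) %||% paste0("x", seq_len(d))
  } else {
    validate_groups(groups, d)
  }

  fitted_var <- function(Z, y) {
    f <- lm.fit(cbind(1, Z), y)
    if (f$rank < ncol(Z) + 1L) stop("singular regression design in SA")
    mean((f$fitted.values - mean(f$fitted.values))^2)
  }

  rows <- list(); k <- 0L
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    XG <- X[, idx, drop = FALSE]
    rest <- X[, setdiff(seq_len(d), idx), drop = FALSE]
    # residualize the group columns on all remaining inputs
    ZG <- if (ncol(rest) == 0L) XG else {
      fr <- lm.fit(cbind(1, rest), XG)
      as_matrix(fr$residuals, "residuals")
    }
    for (dof in seq_len(ncol(Yh))) {
      y <- Yh[, dof]
      Vj <- fitted_var(XG, y)
      VUj <- fitted_var(ZG, y)
      k <- k + 1L
      rows[[k]] <- data.frame(input = gname, dof = dof,
                              S = Vj / V[dof], SU = VUj / V[dof],
                              SC = (Vj - VUj) / V[dof], V = V[dof],
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_lhs") <- n_lhs
  class(out) <- c("moe_sensitivity", "data.frame")
  out
}

validate_groups <- function(groups, d) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("`groups` must be a named list")
  all_idx <- unlist(groups)
  if (any(duplicated(all_idx))) stop("groups must not overlap")
  if (!setequal(all_idx, seq_len(d)))
    stop("groups must partition the ", d, " input channels")
  invisible(TRUE)
}

#' Default electrode grouping by anatomical location
#'
#' For the standard 12-electrode layout: eight electrodes equally spaced
#' around the forearm, one each on the finger extensor and flexor muscles,
#' and one each on the biceps and triceps.
#'
#' @param n_channels number of sEMG channels; must be at least 12 for the
#'   default layout.
#' @return named list of channel index vectors, suitable for
#'   [sensitivity_indices()].
#' @export
electrode_groups <- function(n_channels = 12L) {
  if (n_channels < 12L)
    stop("the default layout needs 12 channels; got ", n_channels)
  list(forearm = 1:8, extensor_flexor = 9:10, upper_arm = 11:12)
}
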