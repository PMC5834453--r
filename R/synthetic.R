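#' Generate a ground-truth mixture-of-experts model
#'
#' Draws a random but reproducible generative mixture of linear experts with
#' Gaussian gate clusters, mirroring the complete-data likelihood of the
#' fitted model: per-movement Gaussian clusters in feature space and
#' per-movement linear feature-to-force maps with Gaussian noise. Used as the
#' reference truth for simulation studies and parameter-recovery tests.
#'
#' Cluster means are drawn uniformly from a positive box (so that they can
#' double as non-negative sEMG envelope amplitudes in [sample_raw_semg()]),
#' rejection-sampled until every pairwise Euclidean distance is at least
#' `separation`; the box grows geometrically if the constraint is tight. The
#' lower corner of the box keeps every cluster at least `separation` away from
#' the origin, where the rest cluster sits.
#'
#' @param M_true number of experts (movements), a positive integer.
#' @param d_x input (sEMG channel/feature) dimension. Default 12 channels.
#' @param d_y output (force DoF) dimension. Default 6 DoF.
#' @param separation minimum pairwise Euclidean distance between cluster
#'   means, in feature units (within-cluster SDs are approximately 1).
#' @param noise_scale SD scale of the expert observation noise; expert noise
#'   covariances have diagonal approximately `noise_scale^2`.
#' @param seed integer seed; the same seed reproduces the same truth.
#' @param pi_true mixing weights (non-negative, summing to 1). Default
#'   uniform, matching a protocol where each movement occurs equally often.
#'
#' @return An object of class `moe_ground_truth`: a list with `M_true`,
#'   `d_x`, `d_y`, `mu_true` (M x d_x means), `Lambda_inv_true` (list of
#'   cluster covariances), `W_true` (list of (d_x+1) x d_y weight matrices,
#'   bias in the last row), `chi_inv_true` (list of noise covariances),
#'   `pi_true`, `separation`, `noise_scale`.
#' @export
#' @examples
#' gt <- make_ground_truth(M_true = 3, d_x = 4, d_y = 2, separation = 8,
#'                         noise_scale = 0.1, seed = 1)
#' min(dist(gt$mu_true)) >= 8
make_ground_truth <- function(M_true, d_x = 12L, d_y = 6L, separation = 8,
                              noise_scale = 0.1, seed = 1L,
                              pi_true = NULL) {
  if (length(M_true) != 1L || M_true < 1 || M_true != round(M_true))
    stop("`M_true` must be a positive integer")
  if (d_x < 1 || d_y < 1) stop("`d_x` and `d_y` must be positive integers")
  if (separation <= 0) stop("`separation` must be > 0")
  if (noise_scale < 0) stop("`noise_scale` must be >= 0")
  M_true <- as.integer(M_true)
  if (is.null(pi_true)) pi_true <- rep(1 / M_true, M_true)
  if (length(pi_true) != M_true || any(pi_true < 0))
    stop("`pi_true` must be a length-M vector of non-negative weights")
  pi_true <- pi_true / sum(pi_true)

  set.seed(as.integer(seed))
  lo <- max(0.5, separation / sqrt(d_x))
  mu <- .sample_separated_means(M_true, d_x, separation, lo)

  Lambda_inv <- vector("list", M_true)
  W <- vector("list", M_true)
  chi_inv <- vector("list", M_true)
  for (i in seq_len(M_true)) {
    A <- matrix(rnorm(d_x * d_x), d_x, d_x)
    Lambda_inv[[i]] <- symm(0.5 * diag(d_x) + 0.5 * crossprod(A) / d_x)
    G <- matrix(rnorm(d_y * d_y), d_y, d_y)
    chi_inv[[i]] <- noise_scale^2 *
      symm(0.6 * diag(d_y) + 0.4 * crossprod(G) / d_y)
    W[[i]] <- matrix(rnorm((d_x + 1) * d_y), d_x + 1, d_y)
  }

  structure(
    list(M_true = M_true, d_x = as.integer(d_x), d_y = as.integer(d_y),
         mu_true = mu, Lambda_inv_true = Lambda_inv, W_true = W,
         chi_inv_true = chi_inv, pi_true = pi_true,
         separation = separation, noise_scale = noise_scale),
    class = "moe_ground_truth")
}

# Rejection sampler for cluster means with a minimum pairwise distance.
.sample_separated_means <- function(M, d, sep, lo) {
  side <- max(sep, 1)
  tries <- 0L
  repeat {
    mu <- matrix(runif(M * d, lo, lo + side), M, d)
    if (M == 1L || min(dist(mu)) >= sep) return(mu)
    tries <- tries + 1L
    if (tries %% 20L == 0L) side <- side * 1.3
  }
}

#' Sample a feature-space session from a ground-truth model
#'
#' Emulates the block structure of a force-protocol recording directly in
#' feature space: contiguous movement blocks separated by rest blocks,
#' organized into repetitions. Each non-rest block is drawn from one expert
#' (`x ~ N(mu_i, Lambda_inv_i)`, `y = W_i'[x; 1] + noise`); rest blocks come
#' from a dedicated near-zero-force expert at the origin (label `M_true + 1`,
#' movement id 0), matching protocols that enforce a rest period between each
#' movement and each repetition.
#'
#' @param gt a `moe_ground_truth` from [make_ground_truth()].
#' @param n_per_block samples per movement block (>= 1).
#' @param n_repetitions number of repetitions of the movement schedule.
#' @param rest_fraction length of each rest block relative to `n_per_block`;
#'   0 produces no rest rows.
#' @param seed integer seed.
#' @param schedule `"protocol"` cycles every movement once per repetition (as
#'   in a force-pattern protocol); `"iid"` draws each block's movement from
#'   `pi_true`, so empirical mixing proportions converge to `pi_true`.
#'
#' @return An object of class `moe_session`: list with `X` (N x d_x), `Y`
#'   (N x d_y), `z` (true expert label; rest rows get `M_true + 1`),
#'   `movement` (0 = rest) and `repetition`.
#' @export
sample_session <- function(gt, n_per_block = 200L, n_repetitions = 6L,
                           rest_fraction = 0.5, seed = 1L,
                           schedule = c("protocol", "iid")) {
  stopifnot(inherits(gt, "moe_ground_truth"))
  if (n_per_block < 1) stop("`n_per_block` must be >= 1")
  if (n_repetitions < 1) stop("`n_repetitions` must be >= 1")
  if (rest_fraction < 0) stop("`rest_fraction` must be >= 0")
  schedule <- match.arg(schedule)
  set.seed(as.integer(seed))

  M <- gt$M_true
  n_rest <- as.integer(round(n_per_block * rest_fraction))
  rest_y_sd <- sqrt(mean(diag(gt$chi_inv_true[[1L]])))

  Xs <- list(); Ys <- list(); zs <- list(); mov <- list(); rep_id <- list()
  blk <- 0L
  for (r in seq_len(n_repetitions)) {
    order_r <- if (schedule == "protocol") seq_len(M)
               else sample.int(M, M, replace = TRUE, prob = gt$pi_true)
    for (i in order_r) {
      if (n_rest > 0L) {
        blk <- blk + 1L
        Xs[[blk]] <- matrix(rnorm(n_rest * gt$d_x, sd = 0.2), n_rest, gt$d_x)
        Ys[[blk]] <- matrix(rnorm(n_rest * gt$d_y, sd = rest_y_sd),
                            n_rest, gt$d_y)
        zs[[blk]] <- rep(M + 1L, n_rest)
        mov[[blk]] <- rep(0L, n_rest)
        rep_id[[blk]] <- rep(r, n_rest)
      }
      blk <- blk + 1L
      Xb <- rmvnorm_rows(n_per_block, gt$mu_true[i, ], gt$Lambda_inv_true[[i]])
      Yb <- cbind(Xb, 1) %*% gt$W_true[[i]] +
        rmvnorm_rows(n_per_block, rep(0, gt$d_y), gt$chi_inv_true[[i]])
      Xs[[blk]] <- Xb; Ys[[blk]] <- Yb
      zs[[blk]] <- rep(i, n_per_block)
      mov[[blk]] <- rep(i, n_per_block)
      rep_id[[blk]] <- rep(r, n_per_block)
    }
  }

  structure(
    list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys),
         z = unlist(zs), movement = unlist(mov),
         repetition = unlist(rep_id)),
    class = "moe_session")
}

#' Simulate a raw multichannel sEMG recording with synchronized forces
#'
#' Generates an amplitude-modulated Gaussian-noise carrier per channel whose
#' per-window RMS/MAV envelope tracks the active movement's cluster mean, so
#' that windowed feature extraction approximately recovers the feature-space
#' cluster structure of `gt`. The protocol alternates rest and movement
#' blocks with raised-cosine amplitude ramps, repeated `n_repetitions` times;
#' the force signal scales with the envelope and is zero at rest. No
#' physiological motor-unit model is claimed: the carrier is white noise.
#'
#' Defaults mirror a force-pattern acquisition: 2 kHz sampling, 5 s movement
#' plateaus with 3 s rests, six repetitions.
#'
#' @param gt a `moe_ground_truth`; its cluster means (positive by
#'   construction) are used as per-channel target envelope amplitudes.
#' @param fs sampling rate in Hz.
#' @param block_ms movement block duration (ms), including the two ramps.
#' @param rest_ms rest duration between blocks (ms).
#' @param ramp_ms rise/fall time of the amplitude envelope (ms).
#' @param n_repetitions repetitions of the full movement schedule.
#' @param amp_base baseline (rest) envelope amplitude.
#' @param seed integer seed.
#'
#' @return An object of class `semg_session`: list with `emg` (T x d_x),
#'   `force` (T x d_y), `stimulus` (movement id per sample, 0 = rest),
#'   `repetition` and `fs`.
#' @export
sample_raw_semg <- function(gt, fs = 2000, block_ms = 5000, rest_ms = 3000,
                            ramp_ms = 500, n_repetitions = 6L,
                            amp_base = 0.05, seed = 1L) {
  stopifnot(inherits(gt, "moe_ground_truth"))
  if (fs <= 0) stop("`fs` must be > 0")
  if (block_ms <= 0 || rest_ms < 0) stop("invalid block/rest durations")
  set.seed(as.integer(seed))

  M <- gt$M_true; d_x <- gt$d_x; d_y <- gt$d_y
  nb <- as.integer(round(block_ms * fs / 1000))
  nr <- as.integer(round(rest_ms * fs / 1000))
  nramp <- min(as.integer(round(ramp_ms * fs / 1000)), nb %/% 2L)
  amp <- pmax(gt$mu_true, amp_base)           # M x d_x target amplitudes
  F_target <- t(vapply(seq_len(M), function(i)
    drop(crossprod(gt$W_true[[i]], c(amp[i, ], 1))), numeric(d_y)))

  # raised-cosine activation profile for one movement block
  s_up <- (1 - cos(pi * seq_len(nramp) / nramp)) / 2
  s_blk <- c(s_up, rep(1, nb - 2L * nramp), rev(s_up))

  noise_sd <- sqrt(pmax(vapply(gt$chi_inv_true, function(S) mean(diag(S)),
                               numeric(1)), 0))

  segs_env <- list(); segs_force <- list(); segs_stim <- list()
  segs_rep <- list(); k <- 0L
  for (r in seq_len(n_repetitions)) {
    for (i in seq_len(M)) {
      if (nr > 0L) {
        k <- k + 1L
        segs_env[[k]] <- matrix(amp_base, nr, d_x)
        segs_force[[k]] <- matrix(rnorm(nr * d_y, sd = noise_sd[i]), nr, d_y)
        segs_stim[[k]] <- rep(0L, nr)
        segs_rep[[k]] <- rep(r, nr)
      }
      k <- k + 1L
      env <- matrix(amp_base, nb, d_x) +
        outer(s_blk, amp[i, ] - amp_base)
      frc <- outer(s_blk, F_target[i, ]) +
        matrix(rnorm(nb * d_y, sd = noise_sd[i]), nb, d_y)
      segs_env[[k]] <- env
      segs_force[[k]] <- frc
      segs_stim[[k]] <- rep(i, nb)
      segs_rep[[k]] <- rep(r, nb)
    }
  }

  env <- do.call(rbind, segs_env)
  emg <- env * matrix(rnorm(length(env)), nrow(env), ncol(env))
  structure(
    list(emg = emg, force = do.call(rbind, segs_force),
         stimulus = unlist(segs_stim), repetition = unlist(segs_rep),
         fs = fs),
    class = "semg_session")
}
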