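# Windowed time-domain sEMG feature extraction, zero-phase low-pass envelope
# features, repetition splitting, subsampling and standardization.

#' Segment a signal into overlapping sliding windows
#'
#' Window `k` (1-based) covers samples `(k-1)*increment + 1` to
#' `(k-1)*increment + window_len`; there are
#' `floor((T - window_len)/increment) + 1` windows. Each window is annotated
#' with the index of its last sample (`attr(-, "end")`), the causal
#' convention used to attach labels to windows.
#'
#' @param x numeric vector of length `T >= window_len`.
#' @param window_len window length in samples (>= 1).
#' @param increment hop between successive windows, `1 <= increment <=
#'   window_len` for overlapping coverage.
#' @return a `n_windows x window_len` matrix, one window per row, with
#'   attribute `end` giving each window's last sample index.
#' @export
#' @examples
#' nrow(sliding_windows(rnorm(2000), 800, 20)) # 61
sliding_windows <- function(x, window_len, increment) {
  if (window_len < 1) stop("`window_len` must be >= 1")
  if (increment < 1 || increment > window_len)
    stop("`increment` must be in [1, window_len]")
  n <- length(x)
  if (n < window_len)
    stop("signal length (", n, ") is shorter than the window (",
         window_len, ")")
  ends <- seq.int(window_len, n, by = increment)
  idx <- outer(ends - window_len, seq_len(window_len), "+")
  W <- matrix(x[idx], length(ends), window_len)
  attr(W, "end") <- ends
  W
}

.check_window <- function(w, min_len = 1L, op = "feature") {
  if (is.matrix(w)) {
    if (ncol(w) < min_len)
      stop(op, " requires windows of length >= ", min_len)
  } else if (length(w) < min_len) {
    stop(op, " requires a window of length >= ", min_len)
  }
  invisible(TRUE)
}

#' Time-domain sEMG features: MAV, WL, RMS
#'
#' Per-window summaries of a (rectified) sEMG window: mean absolute value
#' `mean(|x|)`, waveform length `sum(|diff(x)|)` and root mean square
#' `sqrt(mean(x^2))`. All are non-negative and scale-equivariant:
#' `f(c*x) = |c| * f(x)`.
#'
#' @param w a numeric window (vector), or a matrix of windows, one per row,
#'   as returned by [sliding_windows()].
#' @return a scalar, or one value per window row.
#' @export
#' @examples
#' mav(c(1, -1, 2, -2)) # 1.5
#' wl(c(0, 1, 3))       # 3
#' rms(c(3, -4))        # sqrt(12.5)
mav <- function(w) {
  .check_window(w, 1L, "mav")
  if (is.matrix(w)) rowMeans(abs(w)) else mean(abs(w))
}

#' @rdname mav
#' @export
wl <- function(w) {
  .check_window(w, 2L, "wl")
  if (is.matrix(w)) rowSums(abs(w[, -1L, drop = FALSE] -
                                  w[, -ncol(w), drop = FALSE]))
  else sum(abs(diff(w)))
}

#' @rdname mav
#' @export
rms <- function(w) {
  .check_window(w, 1L, "rms")
  if (is.matrix(w)) sqrt(rowMeans(w * w)) else sqrt(mean(w * w))
}

# O(T) windowed features via cumulative sums; agrees with applying
# mav/wl/rms to sliding_windows() rows (tested), but avoids materializing
# windows for long recordings.
window_feature_series <- function(x, window_len, increment,
                                  fe = c("mav", "wl", "rms")) {
  fe <- match.arg(fe)
  n <- length(x)
  if (n < window_len) stop("signal shorter than the window")
  ends <- seq.int(window_len, n, by = increment)
  starts <- ends - window_len + 1L
  f <- switch(fe,
    mav = {
      cs <- c(0, cumsum(abs(x)))
      (cs[ends + 1L] - cs[starts]) / window_len
    },
    rms = {
      cs <- c(0, cumsum(x * x))
      sqrt((cs[ends + 1L] - cs[starts]) / window_len)
    },
    wl = {
      cd <- c(0, cumsum(abs(diff(x))))
      cd[ends] - cd[starts]
    })
  attr(f, "end") <- ends
  f
}

#' Low-pass envelope features (FILT)
#'
#' Full-wave rectifies the signal, applies a zero-phase low-pass Butterworth
#' filter (forward-backward pass), and keeps every `subsample`-th sample
#' starting from the first. The forward and backward passes are initialized
#' at the filter's steady state for the first/last sample value, so a
#' constant input is reproduced exactly (unit DC gain) with no edge
#' transient. Training and test series should be filtered separately.
#'
#' @param x numeric signal (one channel).
#' @param fs sampling rate (Hz); must exceed `2 * cutoff`.
#' @param cutoff low-pass cutoff frequency in Hz.
#' @param order Butterworth filter order.
#' @param subsample keep every `subsample`-th filtered sample (starting at
#'   the first sample).
#' @return the subsampled envelope, with attribute `end` giving the retained
#'   sample indices.
#' @export
filt_features <- function(x, fs, cutoff = 2, order = 2L, subsample = 200L) {
  if (fs <= 2 * cutoff) stop("`fs` must exceed 2 * cutoff")
  if (subsample < 1) stop("`subsample` must be >= 1")
  if (length(x) < 3L * order + 1L)
    stop("signal shorter than the filter warm-up (", 3L * order + 1L,
         " samples)")
  bf <- signal::butter(order, 2 * cutoff / fs, type = "low")
  y <- filtfilt_ss(bf$b, bf$a, abs(x))
  idx <- seq.int(1L, length(y), by = subsample)
  out <- y[idx]
  attr(out, "end") <- idx
  out
}

# One IIR pass y = filter(b, a, x) with the recursion initialized at the
# steady state for a constant input `x0` (removes start-up transients; a
# constant signal maps to itself times the DC gain, exactly).
iir_pass_ss <- function(b, a, x, x0 = x[1L]) {
  b <- b / a[1L]; a <- a / a[1L]
  nb <- length(b)
  xp <- c(rep(x0, nb - 1L), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1L)
  v <- as.numeric(v)[nb:length(xp)]
  if (length(a) > 1L) {
    y0 <- x0 * sum(b) / sum(a)
    y <- stats::filter(v, -a[-1L], method = "recursive",
                       init = rep(y0, length(a) - 1L))
    as.numeric(y)
  } else v
}

# Zero-phase (forward-backward) filtering with steady-state initialization.
filtfilt_ss <- function(b, a, x) {
  y <- iir_pass_ss(b, a, x)
  rev(iir_pass_ss(b, a, rev(y)))
}

#' Construct a feature dataset
#'
#' Bundles a feature matrix `X`, force matrix `Y` and per-row movement and
#' repetition labels; the container used throughout model fitting and
#' evaluation.
#'
#' @param X N x d_x numeric feature matrix.
#' @param Y N x d_y numeric force matrix.
#' @param movement integer movement ids (0 = rest).
#' @param repetition integer repetition ids.
#' @return an object of class `feature_dataset`.
#' @export
feature_dataset <- function(X, Y, movement = rep(0L, nrow(X)),
                            repetition = rep(1L, nrow(X))) {
  X <- as_matrix(X, "X"); Y <- as_matrix(Y, "Y")
  if (nrow(X) != nrow(Y) || nrow(X) != length(movement) ||
      nrow(X) != length(repetition))
    stop("X, Y, movement and repetition must have the same number of rows")
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("X and Y must be finite")
  structure(list(X = X, Y = Y, movement = as.integer(movement),
                 repetition = as.integer(repetition)),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat("<feature_dataset> ", nrow(x$X), " rows, ", ncol(x$X), " features, ",
      ncol(x$Y), " force DoF, movements {",
      paste(sort(unique(x$movement)), collapse = ","), "}\n", sep = "")
  invisible(x)
}

ds_rows <- function(ds, idx) {
  feature_dataset(ds$X[idx, , drop = FALSE], ds$Y[idx, , drop = FALSE],
                  ds$movement[idx], ds$repetition[idx])
}

#' Split a feature dataset by repetition id
#'
#' Rows whose repetition id is in `test_reps` form the test set; the rest
#' train. The default follows the protocol of holding out the second and
#' fifth repetition of each movement.
#'
#' @param ds a [feature_dataset()].
#' @param test_reps repetition ids assigned to the test set.
#' @return `list(train = , test = )` of feature datasets (a side may be
#'   empty, with a warning).
#' @export
split_by_repetition <- function(ds, test_reps = c(2L, 5L)) {
  stopifnot(inherits(ds, "feature_dataset"))
  test <- ds$repetition %in% test_reps
  if (!any(test)) warning("test split is empty")
  if (all(test)) warning("train split is empty")
  list(train = ds_rows(ds, which(!test)), test = ds_rows(ds, which(test)))
}

#' Subsample dataset rows at regular intervals
#'
#' Keeps rows 1, 1+factor, 1+2*factor, ... (labels in lockstep with X and Y),
#' the usual computational-feasibility thinning of the training set.
#'
#' @param ds a [feature_dataset()].
#' @param factor keep every `factor`-th row (>= 1).
#' @export
subsample_rows <- function(ds, factor = 10L) {
  stopifnot(inherits(ds, "feature_dataset"))
  if (factor < 1) stop("`factor` must be >= 1")
  ds_rows(ds, seq.int(1L, nrow(ds$X), by = as.integer(factor)))
}

#' Standardize features using training-set statistics only
#'
#' Learns per-column mean and SD on the training features and applies the
#' same affine transform to both sets, so that each training column has mean
#' 0 and SD 1 while the test set is transformed but generally not centered.
#'
#' @param train,test [feature_dataset()]s; `test` may be `NULL`.
#' @return `list(train, test, standardizer)` where `standardizer` holds the
#'   training column means and SDs.
#' @export
standardize <- function(train, test = NULL) {
  stopifnot(inherits(train, "feature_dataset"))
  st <- fit_standardizer(train$X)
  train$X <- apply_standardizer(train$X, st)
  if (!is.null(test)) {
    stopifnot(inherits(test, "feature_dataset"))
    test$X <- apply_standardizer(test$X, st)
  }
  list(train = train, test = test, standardizer = st)
}

#' @rdname standardize
#' @param X a numeric matrix whose columns are to be standardized.
#' @export
fit_standardizer <- function(X) {
  X <- as_matrix(X, "X")
  mu <- colMeans(X)
  s <- apply(X, 2L, sd)
  bad <- which(!is.finite(s) | s == 0)
  if (length(bad))
    stop("zero-SD training column(s): ", paste(bad, collapse = ", "))
  structure(list(mean = mu, sd = s), class = "standardizer")
}

#' @rdname standardize
#' @param st a standardizer from [fit_standardizer()].
#' @export
apply_standardizer <- function(X, st) {
  X <- as_matrix(X, "X")
  sweep(sweep(X, 2L, st$mean, "-"), 2L, st$sd, "/")
}

#' @rdname standardize
#' @export
invert_standardizer <- function(X, st) {
  X <- as_matrix(X, "X")
  sweep(sweep(X, 2L, st$sd, "*"), 2L, st$mean, "+")
}
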