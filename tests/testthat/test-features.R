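# Feature extraction, windowing, splitting, subsampling, standardization.

test_that("window count and coverage match the enumeration oracle", {
  W <- sliding_windows(seq_len(2000), 800, 20)
  expect_equal(nrow(W), 61L)
  expect_equal(nrow(sliding_windows(1:800, 800, 20)), 1L)
  # non-overlapping tiling when the increment equals the window
  expect_equal(nrow(sliding_windows(1:60, 20, 20)), 3L)
  # window k covers [k*inc, k*inc + len) 0-based, labelled by its last sample
  expect_equal(W[2, ], 21:820)
  expect_equal(attr(W, "end"), seq(800, 2000, by = 20))
  expect_error(sliding_windows(1:10, 20, 5), "shorter")

  # enumeration oracle over a grid of (T, len, inc)
  for (len in c(1, 3, 7, 20)) {
    for (inc in unique(pmin(c(1, 2, len), len))) {
      for (n in c(len, len + 1, 4 * len + 3, 100)) {
        starts <- 0L; k <- 0L
        while (k * inc + len <= n) k <- k + 1L   # brute-force count
        expect_equal(nrow(sliding_windows(seq_len(n), len, inc)), k,
                     info = sprintf("T=%d len=%d inc=%d", n, len, inc))
      }
    }
  }
})

test_that("MAV, WL, RMS match hand computations and are scale-equivariant", {
  expect_equal(mav(c(1, -1, 2, -2)), 1.5)
  expect_equal(mav(rep(0, 5)), 0)
  expect_equal(mav(rep(-3.2, 4)), 3.2)
  expect_equal(wl(c(0, 1, 3)), 3)
  expect_equal(wl(rep(2, 10)), 0)
  expect_equal(wl(c(0, 1, 0, 1)), 3)
  expect_equal(rms(c(3, -4)), sqrt(12.5))
  expect_equal(rms(rep(0, 3)), 0)
  expect_equal(rms(rep(-2.5, 8)), 2.5)
  expect_error(wl(1), ">= 2")

  set.seed(4)
  x <- rnorm(50)
  for (f in list(mav, wl, rms)) {
    expect_true(f(x) >= 0)
    expect_equal(f(-3 * x), 3 * f(x))
  }

  # matrix form agrees with per-row application
  W <- sliding_windows(rnorm(200), 16, 4)
  expect_equal(mav(W), apply(W, 1, mav))
  expect_equal(wl(W), apply(W, 1, wl))
  expect_equal(rms(W), apply(W, 1, rms))
})

test_that("cumulative-sum window features agree with the windowed oracle", {
  set.seed(5)
  x <- rnorm(500)
  W <- sliding_windows(x, 32, 8)
  for (fe in c("mav", "wl", "rms")) {
    fast <- vbmoe:::window_feature_series(x, 32, 8, fe)
    slow <- get(fe)(W)
    expect_equal(as.numeric(fast), as.numeric(slow), tolerance = 1e-12)
    expect_equal(attr(fast, "end"), attr(W, "end"))
  }
})

test_that("FILT has unit DC gain, smooths a rectified tone, zeroes zeros", {
  const <- rep(0.7, 3000)
  f <- filt_features(const, fs = 2000)
  expect_equal(as.numeric(f), rep(0.7, length(f)), tolerance = 1e-6)

  expect_equal(as.numeric(filt_features(rep(0, 2000), fs = 2000)),
               rep(0, 10))

  # rectified 50 Hz tone: the envelope is its long-run mean 2A/pi with
  # small ripple once past the filter settling region
  t <- seq(0, 4, by = 1 / 2000)[-1]
  x <- 1.5 * sin(2 * base::pi * 50 * t)
  y <- filt_features(x, fs = 2000, subsample = 1)
  mid <- y[2000:6000]
  expect_equal(mean(mid), 2 * 1.5 / base::pi, tolerance = 0.01)
  expect_true(max(abs(mid - 2 * 1.5 / base::pi)) / (2 * 1.5 / base::pi)
              < 0.05)

  # subsampling starts at the first sample
  y200 <- filt_features(x, fs = 2000, subsample = 200)
  expect_equal(attr(y200, "end"), seq(1, length(x), by = 200))
  expect_error(filt_features(rnorm(5), fs = 2000), "warm-up")
  expect_error(filt_features(rnorm(100), fs = 3), "exceed")
})

test_that("repetition split is disjoint, exhaustive and defaults to {2,5}", {
  set.seed(6)
  ds <- feature_dataset(matrix(rnorm(60), 30), matrix(rnorm(30), 30),
                        movement = rep(1:5, each = 6),
                        repetition = rep(1:6, 5))
  sp <- split_by_repetition(ds)
  expect_setequal(unique(sp$train$repetition), c(1, 3, 4, 6))
  expect_setequal(unique(sp$test$repetition), c(2, 5))
  expect_equal(nrow(sp$train$X) + nrow(sp$test$X), 30L)
  expect_warning(split_by_repetition(ds, integer(0)), "empty")
})

test_that("row subsampling keeps regular rows with labels in lockstep", {
  ds <- feature_dataset(matrix(seq_len(3000), ncol = 1),
                        matrix(seq_len(3000), ncol = 1),
                        movement = seq_len(3000) %% 7,
                        repetition = rep(1L, 3000))
  expect_equal(subsample_rows(ds, 1), ds)
  sub <- subsample_rows(ds, 10)
  expect_equal(nrow(sub$X), 300L)
  expect_equal(sub$X[, 1], seq(1, 3000, by = 10))
  expect_equal(sub$movement, (seq(1, 3000, by = 10)) %% 7)
})

test_that("standardization uses training statistics only and inverts", {
  tr <- feature_dataset(matrix(c(0, 2, 0, 4), 2), matrix(rnorm(2), 2))
  te <- feature_dataset(matrix(c(5, 7, 2, 2.5), 2), matrix(rnorm(2), 2))
  out <- standardize(tr, te)
  expect_equal(out$train$X[, 1], c(-1, 1) / sqrt(2))
  expect_equal(colMeans(out$train$X), c(0, 0), tolerance = 1e-9)
  expect_equal(apply(out$train$X, 2, sd), c(1, 1), tolerance = 1e-9)
  expect_false(all(abs(colMeans(out$test$X)) < 1e-9))
  back <- invert_standardizer(out$test$X, out$standardizer)
  expect_equal(back, te$X, tolerance = 1e-12)

  bad <- feature_dataset(matrix(c(1, 1, 0, 4), 2), matrix(rnorm(2), 2))
  expect_error(standardize(bad), "zero-SD.*1")
})
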