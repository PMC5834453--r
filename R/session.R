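# Session containers and the preprocessing pipeline from raw recordings to
# standardized train/test feature datasets.

#' Build or validate an sEMG session
#'
#' A session bundles the raw multichannel sEMG, the synchronized force
#' signals, per-sample movement ids (`stimulus`, 0 = rest) and repetition
#' ids, plus the sampling rate. Accepts a plain list in the NinaPro dialect
#' (fields `emg`, `force`, `stimulus` or `restimulus`, `repetition` or
#' `rerepetition`), so data exported from that database maps directly.
#'
#' @param x a list with fields `emg` (T x channels), `force` (T x DoF),
#'   `stimulus`/`restimulus` and `repetition`/`rerepetition`.
#' @param fs sampling rate in Hz (required if absent from `x`).
#' @return an object of class `semg_session`.
#' @export
as_session <- function(x, fs = x$fs) {
  if (inherits(x, "semg_session")) return(x)
  stim <- x$stimulus %||% x$restimulus
  reps <- x$repetition %||% x$rerepetition
  if (is.null(x$emg)) stop("session is missing the `emg` field")
  if (is.null(x$force)) stop("session is missing the `force` field")
  if (is.null(stim)) stop("session is missing `stimulus`/`restimulus`")
  if (is.null(reps)) stop("session is missing `repetition`/`rerepetition`")
  if (is.null(fs) || fs <= 0) stop("`fs` must be a positive sampling rate")
  emg <- as_matrix(x$emg, "emg"); force <- as_matrix(x$force, "force")
  n <- nrow(emg)
  lens <- c(force = nrow(force), stimulus = length(stim),
            repetition = length(reps))
  short <- names(lens)[lens != n]
  if (length(short))
    stop("field(s) ", paste(short, collapse = ", "),
         " do not match emg length ", n)
  structure(list(emg = emg, force = force, stimulus = as.integer(stim),
                 repetition = as.integer(reps), fs = fs),
            class = "semg_session")
}

#' Read/write a session as delimited text
#'
#' One row per sample: channels, forces, movement (stimulus) and repetition,
#' with a header naming the columns and a leading `# fs=<Hz>` comment line
#' carrying the sampling rate. The round trip is lossless.
#'
#' @param path file path.
#' @param dialect input layout; `"tsv"` is the delimited-text layout written
#'   by `write_session()`. NinaPro-dialect structures (in-memory lists) are
#'   handled by [as_session()].
#' @return `read_session()` returns a `semg_session`;
#'   `write_session()` returns `path` invisibly.
#' @export
read_session <- function(path, dialect = c("tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  fs <- if (grepl("^#\\s*fs=", first))
    as.numeric(sub("^#\\s*fs=", "", first)) else NA_real_
  if (!is.finite(fs)) stop("missing `# fs=` header line in ", path)
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  emg_cols <- grep("^emg_", names(d))
  force_cols <- grep("^force_", names(d))
  if (!length(emg_cols) || !length(force_cols) ||
      !all(c("stimulus", "repetition") %in% names(d)))
    stop("session file lacks emg_*/force_*/stimulus/repetition columns")
  as_session(list(emg = as.matrix(d[emg_cols]),
                  force = as.matrix(d[force_cols]),
                  stimulus = d$stimulus, repetition = d$repetition), fs = fs)
}

#' @rdname read_session
#' @param session a `semg_session`.
#' @export
write_session <- function(session, path) {
  session <- as_session(session)
  d <- data.frame(session$emg, session$force,
                  stimulus = session$stimulus,
                  repetition = session$repetition)
  names(d) <- c(paste0("emg_", seq_len(ncol(session$emg))),
                paste0("force_", seq_len(ncol(session$force))),
                "stimulus", "repetition")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", session$fs), con)
  write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract windowed features from a session
#'
#' Applies one of the time-domain feature extractions (MAV, WL, RMS) over
#' sliding windows, or the FILT low-pass envelope, to every sEMG channel.
#' Each feature row is labelled with the force, movement and repetition of
#' the window's *last* sample (causal convention). For `fe = "filt"` no
#' windowing is used; the rectified, zero-phase-filtered signal is subsampled
#' at regular intervals instead.
#'
#' @param session a `semg_session`.
#' @param fe feature extraction: `"mav"`, `"wl"`, `"rms"` or `"filt"`.
#' @param window_len,increment window length and hop in samples (defaults:
#'   400 ms windows, 10 ms increments at 2 kHz).
#' @param filt_cutoff,filt_order,filt_subsample FILT parameters: cutoff (Hz),
#'   Butterworth order, and subsampling interval in samples.
#' @return a [feature_dataset()].
#' @export
extract_features <- function(session, fe = c("rms", "mav", "wl", "filt"),
                             window_len = 800L, increment = 20L,
                             filt_cutoff = 2, filt_order = 2L,
                             filt_subsample = 200L) {
  session <- as_session(session)
  fe <- match.arg(fe)
  E <- session$emg
  if (fe == "filt") {
    cols <- lapply(seq_len(ncol(E)), function(j)
      filt_features(E[, j], fs = session$fs, cutoff = filt_cutoff,
                    order = filt_order, subsample = filt_subsample))
    idx <- attr(cols[[1L]], "end")
    X <- do.call(cbind, lapply(cols, as.numeric))
  } else {
    cols <- lapply(seq_len(ncol(E)), function(j)
      window_feature_series(E[, j], window_len, increment, fe))
    idx <- attr(cols[[1L]], "end")
    X <- do.call(cbind, lapply(cols, as.numeric))
  }
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  feature_dataset(X, session$force[idx, , drop = FALSE],
                  session$stimulus[idx], session$repetition[idx])
}

session_rows <- function(session, idx) {
  as_session(list(emg = session$emg[idx, , drop = FALSE],
                  force = session$force[idx, , drop = FALSE],
                  stimulus = session$stimulus[idx],
                  repetition = session$repetition[idx]), fs = session$fs)
}

#' Full preprocessing pipeline: raw session to standardized feature sets
#'
#' Reproduces the preprocessing protocol end to end: (1) split raw samples
#' into train/test by repetition id; (2) standardize the raw sEMG and force
#' channels with training-set statistics; (3) extract windowed features
#' separately on each side (so no window straddles the train/test boundary);
#' (4) standardize the extracted features, again with training statistics
#' only; (5) thin the training rows at regular intervals.
#'
#' @inheritParams extract_features
#' @param test_reps repetition ids held out for testing.
#' @param subsample training-row thinning factor (1 = keep everything).
#' @param standardize_raw standardize raw channels before feature extraction.
#' @param ... passed on to [extract_features()].
#' @return list with `train` and `test` feature datasets, the raw and
#'   feature `standardizer`s, and the feature type.
#' @export
prepare_dataset <- function(session, fe = "rms", test_reps = c(2L, 5L),
                            subsample = 10L, standardize_raw = TRUE, ...) {
  session <- as_session(session)
  is_test <- session$repetition %in% test_reps
  train_raw <- session_rows(session, which(!is_test))
  test_raw <- session_rows(session, which(is_test))

  raw_st <- NULL
  if (standardize_raw) {
    raw_st <- list(emg = fit_standardizer(train_raw$emg),
                   force = fit_standardizer(train_raw$force))
    for (s in c("train_raw", "test_raw")) {
      ss <- get(s)
      if (nrow(ss$emg) == 0L) next
      ss$emg <- apply_standardizer(ss$emg, raw_st$emg)
      ss$force <- apply_standardizer(ss$force, raw_st$force)
      assign(s, ss)
    }
  }

  train <- extract_features(train_raw, fe = fe, ...)
  test <- if (nrow(test_raw$emg) > 0L) extract_features(test_raw, fe = fe, ...)
          else NULL
  std <- standardize(train, test)
  train <- subsample_rows(std$train, subsample)
  list(train = train, test = std$test,
       raw_standardizer = raw_st, feature_standardizer = std$standardizer,
       fe = fe)
}

#' Read/write feature datasets as delimited text
#'
#' Tab-separated with a header naming feature columns (`x1..`), force DoF
#' (`y1..`), movement and repetition.
#'
#' @param ds a [feature_dataset()].
#' @param path file path.
#' @export
write_features <- function(ds, path) {
  stopifnot(inherits(ds, "feature_dataset"))
  d <- data.frame(ds$X, ds$Y, movement = ds$movement,
                  repetition = ds$repetition)
  names(d) <- c(paste0("x", seq_len(ncol(ds$X))),
                paste0("y", seq_len(ncol(ds$Y))), "movement", "repetition")
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.table(path, header = TRUE, sep = "\t")
  xc <- grep("^x[0-9]+$", names(d)); yc <- grep("^y[0-9]+$", names(d))
  if (!length(xc) || !length(yc))
    stop("feature file lacks x*/y* columns")
  feature_dataset(as.matrix(d[xc]), as.matrix(d[yc]),
                  d$movement, d$repetition)
}
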