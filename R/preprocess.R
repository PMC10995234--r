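#' Preprocessing configuration
#'
#' Parameters of the preprocessing stage: band-pass edges and order of the
#' Butterworth filter, sliding-window geometry, and the per-subject
#' train fraction of the record split.
#'
#' @param low_hz,high_hz Band edges in Hz. The 0.5 Hz high-pass edge
#'   removes DC offset and postural drift; the 15 Hz low-pass edge removes
#'   content above the band where cough transients concentrate.
#' @param filter_order Order of the one-pass Butterworth prototype; the
#'   filter is applied forward and backward (zero phase), doubling the
#'   effective order.
#' @param window_s Window length in seconds.
#' @param step_s Window slide in seconds.
#' @param train_fraction Fraction of each subject's records, per class,
#'   assigned to the training set.
#' @return An object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(low_hz = 0.5, high_hz = 15.0,
                              filter_order = 4L, window_s = 2.0,
                              step_s = 0.2, train_fraction = 0.8) {
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (!(step_s > 0 && step_s <= window_s)) {
    stop("need 0 < step_s <= window_s", call. = FALSE)
  }
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 filter_order = as.integer(filter_order),
                 window_s = window_s, step_s = step_s,
                 train_fraction = train_fraction),
            class = "preprocess_config")
}

#' Accelerometer vector magnitude
#'
#' Per-sample Euclidean norm sqrt(x^2 + y^2 + z^2) of the three axes,
#' summarizing overall motion independent of sensor orientation.
#'
#' @param rec A [recording()].
#' @return Numeric vector of the same length as the axis vectors.
#' @export
compute_magnitude <- function(rec) {
  sqrt(rec$ax^2 + rec$ay^2 + rec$az^2)
}

# Butterworth band-pass design; returns normalized (b, a) of equal length.
butter_coefs <- function(fs, cfg) {
  nyq <- fs / 2
  if (cfg$high_hz >= nyq) {
    stop("high_hz must be below the Nyquist frequency ", nyq, " Hz",
         call. = FALSE)
  }
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$low_hz, cfg$high_hz) / nyq, type = "pass")
  n <- max(length(bf$b), length(bf$a))
  b <- c(bf$b, numeric(n - length(bf$b)))
  a <- c(bf$a, numeric(n - length(bf$a)))
  b <- b / a[1]
  a <- a / a[1]
  list(b = b, a = a)
}

# Steady-state initial filter state (direct form II transposed) for a unit
# step, so that filtering a constant yields its steady-state response from
# the first sample.
lfilter_zi <- function(b, a) {
  n <- length(a)
  companion <- rbind(-a[-1], cbind(diag(n - 2), 0))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(companion), B)
}

# Zero-phase filtering with odd extension at both ends and steady-state
# initial conditions, so edge transients are suppressed and a constant
# input maps to (numerically) zero for a band-pass design.
filtfilt_zi <- function(b, a, x) {
  n <- length(a)
  pad <- 3L * (n - 1L)
  if (length(x) <= pad) {
    stop("signal too short to filter: need more than ", pad, " samples",
         call. = FALSE)
  }
  nx <- length(x)
  ext <- c(2 * x[1] - x[(pad + 1):2],
           x,
           2 * x[nx] - x[(nx - 1):(nx - pad)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + nx)]
}

#' Band-pass filter a channel
#'
#' Zero-phase (forward-backward) application of the Butterworth band-pass
#' filter defined by `cfg`. Output length equals input length; the DC
#' component and out-of-band frequencies are removed without phase
#' distortion.
#'
#' @param channel Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param cfg A [preprocess_config()].
#' @return Filtered numeric vector.
#' @export
bandpass <- function(channel, fs, cfg = preprocess_config()) {
  co <- butter_coefs(fs, cfg)
  filtfilt_zi(co$b, co$a, channel)
}

#' Split records into training and testing sets
#'
#' Within each (subject, class) stratum, records are shuffled with the
#' given seed and the first `round(train_fraction * n)` go to training,
#' the rest to testing. The split is a partition of all record ids and is
#' balanced between cough and non-cough within each subject whenever the
#' stratum counts are equal.
#'
#' @param manifest A [cohort_manifest()].
#' @param cfg A [preprocess_config()].
#' @param seed Integer seed controlling the within-stratum shuffle.
#' @return A list with character vectors `train` and `test`.
#' @export
split_records <- function(manifest, cfg = preprocess_config(), seed = 1L) {
  strata <- split(manifest$record_id,
                  list(manifest$subject_id, manifest$label), drop = TRUE)
  if (any(vapply(strata, length, integer(1)) == 0L)) {
    stop("every subject needs records in both classes", call. = FALSE)
  }
  set.seed(seed)
  train <- character(0)
  for (ids in strata[order(names(strata))]) {
    ids <- sample(ids)
    n_train <- round(cfg$train_fraction * length(ids))
    train <- c(train, ids[seq_len(n_train)])
  }
  list(train = sort(train),
       test = sort(setdiff(manifest$record_id, train)))
}

window_samples <- function(fs, cfg) round(cfg$window_s * fs)
step_samples <- function(fs, cfg) max(1L, floor(cfg$step_s * fs))

#' Segment a recording into sliding windows
#'
#' Cuts the four channels (three axes plus magnitude) into fixed-length
#' windows of `round(window_s * fs)` samples advanced by
#' `floor(step_s * fs)` samples. Only fully contained windows are emitted.
#' At the default 2 s / 200 ms geometry and 62.5 Hz this yields 42 windows
#' from a 10 s recording (125-sample windows, 12-sample step).
#'
#' @param rec A [recording()] whose axis vectors are the (possibly
#'   filtered) channel signals.
#' @param magnitude The (possibly filtered) magnitude channel, same length
#'   as the axes.
#' @param cfg A [preprocess_config()].
#' @return A list of uncentered `"signal_window"` objects, each holding
#'   the four channels `accX`, `accY`, `accZ`, `Mag` plus provenance.
#' @export
segment <- function(rec, magnitude, cfg = preprocess_config()) {
  n <- length(rec$ax)
  if (length(magnitude) != n) {
    stop("magnitude length must match the recording", call. = FALSE)
  }
  w <- window_samples(rec$fs, cfg)
  s <- step_samples(rec$fs, cfg)
  if (n < w) {
    stop("record '", rec$record_id, "' shorter than one window",
         call. = FALSE)
  }
  starts <- seq.int(1L, n - w + 1L, by = s)
  lapply(seq_along(starts), function(k) {
    idx <- starts[k]:(starts[k] + w - 1L)
    structure(
      list(window_id = sprintf("%s_w%02d", rec$record_id, k),
           record_id = rec$record_id, subject_id = rec$subject_id,
           label = rec$label,
           channels = list(accX = rec$ax[idx], accY = rec$ay[idx],
                           accZ = rec$az[idx], Mag = magnitude[idx]),
           centered = FALSE),
      class = "signal_window")
  })
}

#' Center a window
#'
#' Subtracts each channel's own mean so that amplitude features measure
#' deviation from the window's operating point rather than posture offset.
#' Idempotent.
#'
#' @param window A `"signal_window"`.
#' @return The window with zero-mean channels and `centered = TRUE`.
#' @export
center <- function(window) {
  window$channels <- lapply(window$channels, function(ch) ch - mean(ch))
  window$centered <- TRUE
  window
}

#' Run the full preprocessing stage on a cohort
#'
#' Pipeline order: magnitude computation on the raw axes, zero-phase
#' band-pass filtering of all four channel vectors, record-level
#' train/test split, sliding-window segmentation, and per-window
#' centering.
#'
#' @param manifest A [cohort_manifest()].
#' @param recordings List of [recording()] objects matching the manifest.
#' @param cfg A [preprocess_config()].
#' @param seed Integer seed for the record split.
#' @return A list with `train_windows`, `test_windows` (lists of centered
#'   windows), the record `split`, and a `counts` list.
#' @export
preprocess_cohort <- function(manifest, recordings,
                              cfg = preprocess_config(), seed = 1L) {
  fs <- unique(vapply(recordings, `[[`, numeric(1), "fs"))
  if (length(fs) != 1L) stop("recordings disagree on fs", call. = FALSE)
  split <- split_records(manifest, cfg, seed)
  co <- butter_coefs(fs, cfg)
  windows <- lapply(recordings, function(rec) {
    mag <- compute_magnitude(rec)
    fr <- rec
    fr$ax <- filtfilt_zi(co$b, co$a, rec$ax)
    fr$ay <- filtfilt_zi(co$b, co$a, rec$ay)
    fr$az <- filtfilt_zi(co$b, co$a, rec$az)
    fmag <- filtfilt_zi(co$b, co$a, mag)
    lapply(segment(fr, fmag, cfg), center)
  })
  windows <- unlist(windows, recursive = FALSE)
  rid <- vapply(windows, `[[`, character(1), "record_id")
  train <- windows[rid %in% split$train]
  test <- windows[rid %in% split$test]
  list(train_windows = train, test_windows = test, split = split,
       counts = list(n_records = length(recordings),
                     n_train_records = length(split$train),
                     n_test_records = length(split$test),
                     n_train_windows = length(train),
                     n_test_windows = length(test)))
}
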