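#' Synthetic cohort configuration
#'
#' Parameters of the synthetic accelerometry generator. The defaults
#' emulate the structure of a five-subject seated-recording cohort:
#' 180 ten-second recordings at 62.5 Hz, 90 cough and 90 non-cough, with
#' four subjects contributing 20 + 20 records and one contributing
#' 10 + 10.
#'
#' Cough records are baseline sensor noise plus a train of three-phase
#' bursts (a quiet inspiratory ramp, a brief near-zero compression
#' pause, then a high-amplitude damped expulsive transient) covering
#' the whole record — emulating continuous repeated coughing — with
#' onsets jittered so the train is non-periodic.
#' The expulsive transient is a Hann-windowed damped sinusoid whose
#' frequency lies inside the analysis pass band; its gain is largest on
#' the z axis (forward chest motion) and smallest on x. Non-cough records
#' are baseline noise plus a slow postural drift below the pass band and,
#' in a fraction of records, a low-amplitude "talking" tremor. Every
#' record of a subject is scaled by a per-subject gain.
#'
#' Amplitudes are in arbitrary consistent acceleration units (think g).
#'
#' @param n_subjects Number of subjects.
#' @param records_per_subject List with one `c(n_cough, n_noncough)` pair
#'   per subject.
#' @param record_duration_s Duration of each recording in seconds.
#' @param fs Sampling rate in Hz.
#' @param bursts_per_record Integer range `c(min, max)` of coughs per
#'   cough record.
#' @param burst_duration_s Duration of the expulsive transient.
#' @param burst_peak_amp Peak amplitude of the expulsive transient on the
#'   z axis before jitter and subject gain.
#' @param burst_freq_hz Range of the damped oscillation frequency (Hz).
#' @param burst_amp_jitter Lognormal sd of per-burst amplitude jitter.
#' @param axis_gains Relative burst gain on the x, y, z axes.
#' @param ramp_duration_s,ramp_amp Duration of the inspiratory ramp
#'   preceding each burst, and its peak amplitude as a fraction of the
#'   realized burst amplitude.
#' @param compression_s Duration of the near-zero compression pause.
#' @param noise_sd Baseline white-noise sd on each axis.
#' @param drift_amp,drift_freq_hz Amplitude and frequency range of the
#'   slow postural drift (below the analysis pass band).
#' @param tremor_amp,tremor_freq_hz,tremor_prob Amplitude, frequency
#'   range and per-record probability of the talking tremor in non-cough
#'   records.
#' @param subject_gain_sd Lognormal sd of the per-subject gain.
#' @param seed Integer seed; the full cohort is deterministic given it.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 5L,
                       records_per_subject = c(rep(list(c(20L, 20L)), 4),
                                               list(c(10L, 10L))),
                       record_duration_s = 10, fs = 62.5,
                       bursts_per_record = c(6L, 9L),
                       burst_duration_s = 0.35, burst_peak_amp = 0.8,
                       burst_freq_hz = c(8, 14), burst_amp_jitter = 0.25,
                       axis_gains = c(x = 0.35, y = 0.6, z = 1.0),
                       ramp_duration_s = 0.4, ramp_amp = 0.0625,
                       compression_s = 0.1,
                       noise_sd = 0.02,
                       drift_amp = 0.05, drift_freq_hz = c(0.1, 0.4),
                       tremor_amp = 0.004, tremor_freq_hz = c(4, 8),
                       tremor_prob = 0.5,
                       subject_gain_sd = 0.15, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              records_per_subject = records_per_subject,
              record_duration_s = record_duration_s, fs = fs,
              bursts_per_record = as.integer(bursts_per_record),
              burst_duration_s = burst_duration_s,
              burst_peak_amp = burst_peak_amp,
              burst_freq_hz = burst_freq_hz,
              burst_amp_jitter = burst_amp_jitter,
              axis_gains = axis_gains,
              ramp_duration_s = ramp_duration_s, ramp_amp = ramp_amp,
              compression_s = compression_s,
              noise_sd = noise_sd, drift_amp = drift_amp,
              drift_freq_hz = drift_freq_hz, tremor_amp = tremor_amp,
              tremor_freq_hz = tremor_freq_hz, tremor_prob = tremor_prob,
              subject_gain_sd = subject_gain_sd, seed = as.integer(seed))
  pos <- c("record_duration_s", "fs", "burst_duration_s",
           "burst_peak_amp", "noise_sd")
  for (p in pos) {
    if (cfg[[p]] <= 0) stop(p, " must be > 0", call. = FALSE)
  }
  if (length(records_per_subject) != n_subjects) {
    stop("records_per_subject must have one entry per subject",
         call. = FALSE)
  }
  if (cfg$record_duration_s * cfg$fs < 2 * cfg$fs) {
    stop("records must be at least one analysis window long",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Deterministic sub-seed for record counter k (kept below 2^31).
substream_seed <- function(seed, k) {
  (as.numeric(seed) * 10007 + k * 7919) %% 2147483647
}

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))

# One three-phase cough burst added in place to a 3 x n signal matrix.
add_burst <- function(sig, at, cfg, fs) {
  n <- ncol(sig)
  n_ramp <- round(cfg$ramp_duration_s * fs)
  n_comp <- round(cfg$compression_s * fs)
  n_exp <- round(cfg$burst_duration_s * fs)
  amp <- cfg$burst_peak_amp *
    exp(rnorm(1, 0, cfg$burst_amp_jitter)) * sample(c(-1, 1), 1)
  f0 <- runif(1, cfg$burst_freq_hz[1], cfg$burst_freq_hz[2])
  gains <- cfg$axis_gains[c("x", "y", "z")]
  # inspiratory ramp: low-amplitude noise swelling linearly
  i0 <- at
  i1 <- min(n, at + n_ramp - 1L)
  if (i1 >= i0) {
    k <- i1 - i0 + 1L
    ramp <- seq(0, 1, length.out = k) * cfg$ramp_amp * abs(amp)
    for (ax in 1:3) {
      sig[ax, i0:i1] <- sig[ax, i0:i1] + gains[ax] * ramp * rnorm(k)
    }
  }
  # compression pause: nothing added (near-zero motion)
  # expulsive transient: Hann-windowed damped sinusoid
  e0 <- at + n_ramp + n_comp
  e1 <- min(n, e0 + n_exp - 1L)
  if (e1 >= e0 && e0 <= n) {
    k <- e1 - e0 + 1L
    tt <- (seq_len(k) - 1) / fs
    phase <- runif(1, 0, 2 * pi)
    wave <- hann(k) * exp(-tt / (cfg$burst_duration_s / 3)) *
      sin(2 * pi * f0 * tt + phase)
    for (ax in 1:3) {
      sig[ax, e0:e1] <- sig[ax, e0:e1] + amp * gains[ax] * wave
    }
  }
  sig
}

simulate_record <- function(record_id, subject_id, label, gain, cfg,
                            counter) {
  set.seed(substream_seed(cfg$seed, counter))
  fs <- cfg$fs
  n <- round(cfg$record_duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  sig <- matrix(rnorm(3 * n, 0, cfg$noise_sd), nrow = 3)
  # slow postural drift, below the analysis pass band, on all axes
  for (ax in 1:3) {
    f <- runif(1, cfg$drift_freq_hz[1], cfg$drift_freq_hz[2])
    sig[ax, ] <- sig[ax, ] +
      cfg$drift_amp * runif(1, 0.3, 1) * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
  }
  if (label == "cough") {
    n_burst <- sample(seq(cfg$bursts_per_record[1],
                          cfg$bursts_per_record[2]), 1)
    span <- round((cfg$ramp_duration_s + cfg$compression_s +
                     cfg$burst_duration_s) * fs)
    # cough onsets cover the whole record (continuous repeated
    # coughing) but are jittered within equal slots so the burst train
    # stays non-periodic
    slot <- max(1L, (n - span) %/% n_burst)
    starts <- (seq_len(n_burst) - 1L) * slot +
      sample.int(slot, n_burst, replace = TRUE)
    for (at in starts) sig <- add_burst(sig, at, cfg, fs)
  } else if (runif(1) < cfg$tremor_prob) {
    # talking tremor: low-amplitude oscillation inside the pass band
    f <- runif(1, cfg$tremor_freq_hz[1], cfg$tremor_freq_hz[2])
    on <- runif(2)
    on <- round(sort(on * n))
    if (diff(on) > fs) {
      idx <- (on[1] + 1):on[2]
      sig[2, idx] <- sig[2, idx] +
        cfg$tremor_amp * sin(2 * pi * f * tt[idx] + runif(1, 0, 2 * pi))
      sig[3, idx] <- sig[3, idx] +
        0.7 * cfg$tremor_amp * sin(2 * pi * f * tt[idx] + runif(1, 0, 2 * pi))
    }
  }
  sig <- sig * gain
  recording(record_id, subject_id, label, fs,
            ax = sig[1, ], ay = sig[2, ], az = sig[3, ])
}

#' Simulate a synthetic accelerometry cohort
#'
#' Generates the full cohort described by a [sim_config()]:
#' per-subject record counts, cough records with repeated non-periodic
#' burst transients and non-cough records with rest/talking motion, all
#' scaled by per-subject gains. Each record is drawn from its own RNG
#' substream derived from the global seed and a record counter, so the
#' cohort is bit-reproducible and records are independent of generation
#' order.
#'
#' @param cfg A [sim_config()].
#' @return A list with `manifest` (a [cohort_manifest()]) and
#'   `recordings` (list of [recording()] objects).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gains <- exp(rnorm(cfg$n_subjects, 0, cfg$subject_gain_sd))
  counter <- 0L
  recordings <- list()
  rows <- list()
  for (s in seq_len(cfg$n_subjects)) {
    subject_id <- sprintf("S%d", s)
    counts <- cfg$records_per_subject[[s]]
    for (cls in 1:2) {
      label <- c("cough", "non_cough")[cls]
      for (i in seq_len(counts[cls])) {
        counter <- counter + 1L
        record_id <- sprintf("%s_%s_%02d", subject_id,
                             ifelse(label == "cough", "c", "n"), i)
        rec <- simulate_record(record_id, subject_id, label, gains[s],
                               cfg, counter)
        recordings[[counter]] <- rec
        rows[[counter]] <- data.frame(record_id = record_id,
                                      subject_id = subject_id,
                                      label = label,
                                      stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- cohort_manifest(do.call(rbind, rows), cfg$fs)
  list(manifest = manifest, recordings = recordings)
}

#' Simulate a labelled feature table directly
#'
#' A direct fixture for the ranking and evaluation stages: `n_windows`
#' rows over the 43 registry features with balanced labels.
#' `n_informative` randomly chosen features are drawn from class-shifted
#' unit Gaussians (cough mean `+effect_size/2`, non-cough
#' `-effect_size/2`); the rest are pure N(0, 1) noise. Rows are assigned
#' to subjects round-robin so subject-aware protocols can run on the
#' fixture.
#'
#' @param n_windows Number of rows (made even).
#' @param n_informative Number of class-informative features (0..43).
#' @param seed Integer seed.
#' @param effect_size Class mean separation of informative features, in
#'   within-class sd units.
#' @param n_subjects Number of subjects to cycle rows over.
#' @return A [feature_table()] with attribute `"informative_features"`
#'   naming the informative columns.
#' @export
simulate_feature_table <- function(n_windows, n_informative, seed = 1L,
                                   effect_size = 2, n_subjects = 5L) {
  fn <- feature_names()
  if (n_informative < 0 || n_informative > length(fn)) {
    stop("n_informative must be in 0..", length(fn), call. = FALSE)
  }
  n_windows <- 2L * (as.integer(n_windows) %/% 2L)
  if (n_windows < 2L) stop("n_windows must be >= 2", call. = FALSE)
  set.seed(seed)
  informative <- sort(sample(fn, n_informative))
  label <- rep(c("cough", "non_cough"), each = n_windows / 2)
  y <- ifelse(label == "cough", 0.5, -0.5) * effect_size
  mat <- matrix(rnorm(n_windows * length(fn)), nrow = n_windows,
                dimnames = list(NULL, fn))
  for (f in informative) mat[, f] <- mat[, f] + y
  subject <- sprintf("S%d", (seq_len(n_windows) - 1L) %% n_subjects + 1L)
  df <- data.frame(window_id = sprintf("w%05d", seq_len(n_windows)),
                   record_id = sprintf("r%05d",
                                       (seq_len(n_windows) - 1L) %/% 10L),
                   subject_id = subject, label = label,
                   stringsAsFactors = FALSE)
  out <- feature_table(cbind(df, as.data.frame(mat)))
  attr(out, "informative_features") <- informative
  out
}
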