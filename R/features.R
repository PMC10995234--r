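#' Per-window statistics
#'
#' The scalar statistics computed on each channel of a centered window.
#' All moment-based statistics use population (biased) denominators so
#' that on a centered window the RMS equals the standard deviation and
#' the variance equals RMS squared, exactly.
#'
#' @param channel Numeric sample vector (one window of one channel).
#' @return A scalar.
#' @name window_statistics
NULL

#' @rdname window_statistics
#' @export
feat_min <- function(channel) min(channel)

#' @rdname window_statistics
#' @export
feat_max <- function(channel) max(channel)

#' @rdname window_statistics
#' @export
feat_diff <- function(channel) max(channel) - min(channel)

#' @rdname window_statistics
#' @export
feat_rms <- function(channel) sqrt(mean(channel^2))

#' @rdname window_statistics
#' @export
feat_var <- function(channel) mean((channel - mean(channel))^2)

#' @rdname window_statistics
#' @details `feat_iqr` uses the linear-interpolation percentile convention
#'   (R quantile type 7): the difference between the 75th and 25th
#'   percentiles.
#' @export
feat_iqr <- function(channel) {
  q <- quantile(channel, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

#' @rdname window_statistics
#' @details `feat_mad` is the unscaled median absolute deviation:
#'   median(|x - median(x)|).
#' @export
feat_mad <- function(channel) median(abs(channel - median(channel)))

#' @rdname window_statistics
#' @details `feat_skewness` is the biased moment skewness m3 / m2^(3/2);
#'   0 for a constant channel.
#' @export
feat_skewness <- function(channel) {
  m <- mean(channel)
  m2 <- mean((channel - m)^2)
  if (m2 == 0) return(0)
  mean((channel - m)^3) / m2^1.5
}

#' @rdname window_statistics
#' @details `feat_kurtosis` is the Fisher (excess) kurtosis
#'   m4 / m2^2 - 3 in biased moment form, so a Gaussian scores ~0;
#'   0 for a constant channel.
#' @export
feat_kurtosis <- function(channel) {
  m <- mean(channel)
  m2 <- mean((channel - m)^2)
  if (m2 == 0) return(0)
  mean((channel - m)^4) / m2^2 - 3
}

#' Mean approximate entropy of a channel
#'
#' Approximate entropy (ApEn) measures signal regularity by comparing
#' counts of similar templates of consecutive samples at adjacent
#' embedding dimensions; higher values indicate a less predictable
#' signal. This implementation computes ApEn for embedding dimensions
#' 0..`m` with tolerance `r = r_coeff * sd(channel)` (population sd),
#' Chebyshev distance and self-matches included, and returns the
#' arithmetic mean of the per-dimension estimates. The dimension-0
#' estimate uses the convention phi_0 = 0 (length-0 templates always
#' match), so ApEn(0) = -phi_1.
#'
#' A zero-variance channel has no structure to measure (and an undefined
#' tolerance); it returns 0.
#'
#' @param channel Numeric sample vector with more than `m + 1` samples.
#' @param m Maximum embedding dimension (default 2).
#' @param r_coeff Tolerance as a multiple of the channel's standard
#'   deviation (default 0.2).
#' @return Mean ApEn over dimensions 0..m (nonnegative).
#' @export
feat_entropy <- function(channel, m = 2L, r_coeff = 0.2) {
  if (length(channel) <= m + 1L) {
    stop("channel too short for embedding dimension ", m, call. = FALSE)
  }
  s <- sqrt(feat_var(channel))
  if (s == 0) return(0)
  phi <- apen_phi(channel, m + 1L, r_coeff * s)
  # ApEn(k) = phi_k - phi_{k+1}, with phi_0 = 0
  apen <- c(0, phi[seq_len(m)]) - phi
  mean(apen)
}

#' @rdname window_statistics
#' @param channel_a,channel_b Two channels of equal length.
#' @details `feat_corr` is the Pearson correlation between two channels;
#'   0 if either channel has zero variance.
#' @export
feat_corr <- function(channel_a, channel_b) {
  if (feat_var(channel_a) == 0 || feat_var(channel_b) == 0) return(0)
  cor(channel_a, channel_b)
}

#' Extract the 43 time-domain features from centered windows
#'
#' Computes, for each window, ten statistics (Min, Max, Diff, RMS,
#' Skewness, Kurtosis, IQR, Var, Ent, MAD) on each of the four channels
#' plus the three inter-axis Pearson correlations, in registry order
#' ([feature_names()]).
#'
#' @param windows List of centered `"signal_window"` objects.
#' @param apen_m,apen_r Approximate-entropy parameters passed to
#'   [feat_entropy()].
#' @return A [feature_table()] with one row per window.
#' @export
extract_features <- function(windows, apen_m = 2L, apen_r = 0.2) {
  if (length(windows) && !all(vapply(windows, `[[`, logical(1),
                                     "centered"))) {
    stop("windows must be centered before feature extraction",
         call. = FALSE)
  }
  fn <- feature_names()
  chans <- c("X" = "accX", "Y" = "accY", "Z" = "accZ", "Mag" = "Mag")
  rows <- lapply(windows, function(w) {
    ch <- w$channels
    vals <- numeric(length(fn))
    names(vals) <- fn
    for (suffix in names(chans)) {
      x <- ch[[chans[[suffix]]]]
      vals[paste0("Min_", suffix)] <- feat_min(x)
      vals[paste0("Max_", suffix)] <- feat_max(x)
      vals[paste0("Diff_", suffix)] <- feat_diff(x)
      vals[paste0("RMS_", suffix)] <- feat_rms(x)
      vals[paste0("Skewness_", suffix)] <- feat_skewness(x)
      vals[paste0("Kurtosis_", suffix)] <- feat_kurtosis(x)
      vals[paste0("IQR_", suffix)] <- feat_iqr(x)
      vals[paste0("Var_", suffix)] <- feat_var(x)
      vals[paste0("Ent_", suffix)] <- feat_entropy(x, apen_m, apen_r)
      vals[paste0("MAD_", suffix)] <- feat_mad(x)
    }
    vals["Corr_xy"] <- feat_corr(ch$accX, ch$accY)
    vals["Corr_yz"] <- feat_corr(ch$accY, ch$accZ)
    vals["Corr_xz"] <- feat_corr(ch$accX, ch$accZ)
    vals
  })
  mat <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, length(fn), dimnames = list(NULL, fn))
  meta <- data.frame(
    window_id = vapply(windows, `[[`, character(1), "window_id"),
    record_id = vapply(windows, `[[`, character(1), "record_id"),
    subject_id = vapply(windows, `[[`, character(1), "subject_id"),
    label = vapply(windows, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  if (!length(windows)) {
    meta <- data.frame(window_id = character(0), record_id = character(0),
                       subject_id = character(0), label = character(0))
  }
  feature_table(cbind(meta, as.data.frame(mat)))
}
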