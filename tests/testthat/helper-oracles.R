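# Independent brute-force oracles used to cross-check the implementation.

# Approximate entropy by direct template counting: builds every embedded
# template explicitly and counts Chebyshev-neighbourhoods, one dimension
# at a time.
oracle_apen_mean <- function(x, m = 2L, r_coeff = 0.2) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) return(0)
  r <- r_coeff * s
  phi <- function(k) {
    n <- length(x)
    nt <- n - k + 1
    tmpl <- matrix(vapply(seq_len(nt), function(i) x[i:(i + k - 1)],
                          numeric(k)), nrow = k)
    mean(vapply(seq_len(nt), function(i) {
      d <- apply(abs(tmpl - tmpl[, i]), 2, max)
      log(mean(d <= r))
    }, numeric(1)))
  }
  phis <- vapply(seq_len(m + 1L), phi, numeric(1))
  apen <- c(0, phis[seq_len(m)]) - phis
  mean(apen)
}

# Population central moment.
oracle_moment <- function(x, p) mean((x - mean(x))^p)

oracle_skewness <- function(x) {
  oracle_moment(x, 3) / oracle_moment(x, 2)^1.5
}

oracle_kurtosis <- function(x) {
  oracle_moment(x, 4) / oracle_moment(x, 2)^2 - 3
}

# IQR via explicit linear interpolation between order statistics
# (quantile type 7): q(p) = x_(j) + g * (x_(j+1) - x_(j)) with
# h = (n - 1) p + 1.
oracle_iqr <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  q <- function(p) {
    h <- (n - 1) * p + 1
    j <- floor(h)
    g <- h - j
    if (j >= n) xs[n] else xs[j] + g * (xs[j + 1] - xs[j])
  }
  q(0.75) - q(0.25)
}

oracle_mad <- function(x) {
  dev <- sort(abs(x - median(x)))
  median(dev)
}

# Window-count oracle: enumerate valid start positions.
oracle_window_count <- function(n, w, s) {
  sum(seq(1, max(1, n), by = s) + w - 1 <= n)
}

# Small deterministic test window.
make_window <- function(seed = 1, n = 125, centered = TRUE) {
  set.seed(seed)
  w <- structure(
    list(window_id = "t_w01", record_id = "t", subject_id = "S1",
         label = "cough",
         channels = list(accX = rnorm(n), accY = rnorm(n),
                         accZ = rnorm(n), Mag = abs(rnorm(n)) + 1),
         centered = FALSE),
    class = "signal_window")
  if (centered) center(w) else w
}
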