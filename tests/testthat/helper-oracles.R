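# Independent oracles and fixture builders shared across test files.

# Naive O(N^2) discrete Fourier transform; deliberately slow and independent
# of stats::fft so it can serve as the spectral oracle on short segments.
naive_dft <- function(x) {
  n <- length(x)
  k <- seq_len(n) - 1
  vapply(k, function(kk) {
    sum(complex(modulus = 1, argument = -2 * pi * kk * (seq_len(n) - 1) / n) * x)
  }, complex(1))
}

# One-sided density periodogram built on the naive DFT, mirroring the
# documented normalization contract.
naive_periodogram <- function(x, fs, window = "rectangular", detrend = "none") {
  n <- length(x)
  if (detrend == "mean") x <- x - mean(x)
  w <- if (window == "hann") 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n)) else rep(1, n)
  u <- mean(w^2)
  X <- naive_dft(x * w)[1:(n / 2 + 1)]
  p <- Mod(X)^2 / (fs * u * n)
  p[2:(n / 2)] <- 2 * p[2:(n / 2)]
  p
}

# Deterministic 3-subject x 3-condition x 2-limb toy cohort with integer
# responses; its sums of squares were frozen from an independent
# aov/Error-strata decomposition (see test-cohort-stats.R).
toy_cohort <- function() {
  vals <- c(
    5, 6, 8, 7, 9, 10,
    4, 4, 6, 7, 8, 8,
    6, 5, 7, 9, 11, 10
  )
  d <- tidyr::expand_grid(
    subject_id = c("A", "B", "C"),
    condition = c("rest", "endurance", "sprint"),
    limb = c("left", "right")
  )
  dplyr::mutate(d, band = "2_5", L = vals, F = 3.2)
}

random_recording <- function(n = 64L, fs = 200, ...) {
  accel_recording(rnorm(n), fs = fs, ...)
}
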