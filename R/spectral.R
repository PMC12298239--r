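#' Spectral estimation configuration
#'
#' Settings for the segment-averaged periodogram: the signal is split into
#' `n_segments` contiguous, non-overlapping blocks of `segment_length`
#' samples taken from the start of the recording, each block is mean-detrended
#' (optional), tapered with a raised-cosine (Hann) window, transformed with
#' the FFT, and the density-scaled one-sided periodograms are averaged.
#'
#' Defaults follow the canonical tremor protocol: six 1024-sample segments of
#' a 200 Hz recording, giving a frequency resolution of 200/1024 =
#' 0.1953125 Hz and an analyzed length of 6144 samples (30.72 s).
#'
#' @param segment_length Samples per segment (positive even integer).
#' @param n_segments Number of contiguous segments averaged.
#' @param window `"hann"` (raised cosine) or `"rectangular"`.
#' @param detrend `"mean"` (subtract each segment's mean) or `"none"`.
#' @return A `spectral_config` list.
#' @export
spectral_config <- function(segment_length = 1024L, n_segments = 6L,
                            window = c("hann", "rectangular"),
                            detrend = c("mean", "none")) {
  window <- match.arg(window)
  detrend <- match.arg(detrend)
  segment_length <- as.integer(segment_length)
  n_segments <- as.integer(n_segments)
  if (segment_length < 4L || segment_length %% 2L != 0L) {
    abort("`segment_length` must be an even integer >= 4.")
  }
  if (n_segments < 1L) abort("`n_segments` must be >= 1.")
  structure(
    list(segment_length = segment_length, n_segments = n_segments,
         window = window, detrend = detrend),
    class = "spectral_config"
  )
}

# Periodic Hann (raised-cosine) taper of length n; weights in [0, 1].
hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
}

window_weights <- function(window, n) {
  switch(window,
    hann = hann_window(n),
    rectangular = rep(1, n),
    abort(sprintf("Unknown window %s.", dQuote(window, FALSE)))
  )
}

#' Split a signal into contiguous analysis segments
#'
#' Takes exactly `n_segments` non-overlapping blocks of `segment_length`
#' samples from the start of the signal; surplus trailing samples are
#' discarded.
#'
#' @param samples Numeric vector.
#' @param cfg A [spectral_config()].
#' @return List of `n_segments` numeric vectors of length `segment_length`.
#' @export
segment_signal <- function(samples, cfg = spectral_config()) {
  needed <- cfg$segment_length * cfg$n_segments
  if (length(samples) < needed) {
    abort(sprintf(
      "Insufficient samples for segmentation: %d required (%d segments x %d), %d available.",
      needed, cfg$n_segments, cfg$segment_length, length(samples)
    ))
  }
  lapply(seq_len(cfg$n_segments) - 1L, function(i) {
    samples[(i * cfg$segment_length + 1L):((i + 1L) * cfg$segment_length)]
  })
}

#' One-sided density-scaled periodogram of a single segment
#'
#' After optional mean removal the segment is multiplied by the window and
#' transformed with the FFT. Power at bin k is `2 |X_k|^2 / (fs * U * N)` for
#' interior bins (no doubling at DC and Nyquist), where `U = mean(w^2)`
#' compensates the window's power loss so the Parseval contract
#' `sum(P) * df = variance` holds for any window in expectation (exactly for
#' the rectangular window).
#'
#' @param segment Numeric vector, even length >= 4.
#' @param fs Sampling rate in Hz.
#' @param window `"hann"` or `"rectangular"`.
#' @param detrend `"mean"` or `"none"`.
#' @return Numeric vector of length `length(segment)/2 + 1`, units
#'   (sensor units)^2 / Hz, on the grid `(0:(N/2)) * fs / N`.
#' @export
periodogram <- function(segment, fs, window = "hann", detrend = "mean") {
  n <- length(segment)
  if (n < 4L || n %% 2L != 0L) {
    abort(sprintf("Segment length must be even and >= 4 (got %d).", n))
  }
  if (detrend == "mean") segment <- segment - mean(segment)
  w <- window_weights(window, n)
  u <- mean(w^2)
  x <- fft(segment * w)[1:(n / 2 + 1)]
  p <- Mod(x)^2 / (fs * u * n)
  p[2:(n / 2)] <- 2 * p[2:(n / 2)]  # fold negative frequencies; DC/Nyquist unpaired
  p
}

#' Segment-averaged power spectral density of a recording
#'
#' Estimates the one-sided PSD of an acceleration recording by averaging the
#' per-segment periodograms of [segment_signal()] blocks. With the canonical
#' configuration this is the arithmetic mean of six Hann-windowed 1024-point
#' periodograms of a 200 Hz signal.
#'
#' @param rec An [accel_recording()] (or a bare numeric vector together with
#'   `fs` via `attr`-free fallback is not supported; wrap vectors with
#'   [accel_recording()]).
#' @param cfg A [spectral_config()].
#' @return A `tremor_psd` tibble with columns `freq_hz` and `psd`
#'   ((sensor units)^2/Hz), carrying the sampling rate, configuration,
#'   number of segments used and recording metadata as attributes.
#' @examples
#' rec <- accel_recording(rnorm(6144), fs = 200)
#' psd <- estimate_psd(rec)
#' sum(psd$psd) * (200 / 1024)  # ~ var(rec$samples)
#' @export
estimate_psd <- function(rec, cfg = spectral_config()) {
  validate_recording(rec)
  segs <- segment_signal(rec$samples, cfg)
  per <- vapply(segs, periodogram, numeric(cfg$segment_length / 2 + 1),
                fs = rec$fs, window = cfg$window, detrend = cfg$detrend)
  power <- rowMeans(per)
  out <- tibble::tibble(
    freq_hz = (0:(cfg$segment_length / 2)) * rec$fs / cfg$segment_length,
    psd = power
  )
  structure(out,
            class = c("tremor_psd", class(out)),
            fs = rec$fs,
            config = cfg,
            n_segments_used = cfg$n_segments,
            units = rec$units,
            subject_id = rec$subject_id,
            limb = rec$limb,
            condition = rec$condition)
}

#' Frequency resolution of a PSD estimate
#' @param psd A `tremor_psd`.
#' @return Bin spacing in Hz.
#' @export
psd_resolution <- function(psd) {
  psd$freq_hz[[2]] - psd$freq_hz[[1]]
}

#' Write a PSD estimate to TSV
#'
#' Columns `freq_hz`, `psd`; the spectral configuration is echoed as `#`
#' header comments for provenance.
#'
#' @param psd A `tremor_psd`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psd <- function(psd, path) {
  cfg <- attr(psd, "config")
  hdr <- c(
    sprintf("#fs_hz\t%g", attr(psd, "fs")),
    sprintf("#segment_length\t%d", cfg$segment_length),
    sprintf("#n_segments\t%d", cfg$n_segments),
    sprintf("#window\t%s", cfg$window),
    sprintf("#detrend\t%s", cfg$detrend)
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(hdr, "freq_hz\tpsd",
               sprintf("%.17g\t%.17g", psd$freq_hz, psd$psd)), con)
  invisible(path)
}

#' Plot a PSD estimate
#'
#' Renders the averaged spectrum on a linear or logarithmic power scale,
#' optionally shading the canonical 2-5 Hz and 9-14 Hz tremor bands.
#'
#' @param object A `tremor_psd`.
#' @param log_power Plot `ln(PSD)` instead of PSD?
#' @param bands Optional list of [tremor_band()] objects to shade.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot tremor_psd
#' @export
autoplot.tremor_psd <- function(object, log_power = FALSE,
                                bands = canonical_bands(), ...) {
  df <- tibble::tibble(freq_hz = object$freq_hz, psd = object$psd)
  if (log_power) df <- dplyr::filter(df, .data$psd > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$psd))
  if (!is.null(bands)) {
    shade <- dplyr::bind_rows(lapply(bands, function(b) {
      tibble::tibble(f1 = b$f1, f2 = b$f2, label = b$label)
    }))
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$f1, xmax = .data$f2, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85", alpha = 0.6
    )
  }
  p <- p + ggplot2::geom_line(linewidth = 0.4)
  if (log_power) p <- p + ggplot2::scale_y_log10()
  p + ggplot2::labs(
    x = "Frequency [Hz]",
    y = if (log_power) "PSD [(units)²/Hz, log scale]" else "PSD [(units)²/Hz]",
    title = "Segment-averaged power spectral density"
  ) + ggplot2::theme_minimal()
}
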