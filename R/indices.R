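#' Define a tremor frequency band
#'
#' A band is a closed frequency interval `[f1, f2]` over which the two
#' tremor indices are computed. The canonical lower-limb bands are 2-5 Hz
#' (postural control, slow-twitch drive) and 9-14 Hz (central drive,
#' fast-twitch activation).
#'
#' @param f1,f2 Band edges in Hz, `0 <= f1 < f2`.
#' @param label Band label used in output tables; defaults to `"f1_f2"`.
#' @return A `tremor_band` list.
#' @export
tremor_band <- function(f1, f2, label = sprintf("%g_%g", f1, f2)) {
  if (!is.finite(f1) || !is.finite(f2) || f1 < 0 || f1 >= f2) {
    abort("Band edges must satisfy 0 <= f1 < f2.")
  }
  structure(list(f1 = f1, f2 = f2, label = label), class = "tremor_band")
}

#' Canonical lower-limb tremor bands
#'
#' @return List of two [tremor_band()]s: 2-5 Hz and 9-14 Hz.
#' @export
canonical_bands <- function() {
  list(tremor_band(2, 5, "2_5"), tremor_band(9, 14, "9_14"))
}

#' FFT bins falling inside a band
#'
#' Selects the indices (into the PSD rows) of bins whose center frequency
#' lies in the closed interval `[f1, f2]`, always excluding the DC bin.
#' No interpolation is performed at band edges.
#'
#' @param psd A `tremor_psd` from [estimate_psd()].
#' @param band A [tremor_band()].
#' @return Integer vector of row indices, non-empty.
#' @export
band_bins <- function(psd, band) {
  fs <- attr(psd, "fs")
  if (band$f2 > fs / 2 + 1e-9) {
    abort(sprintf("Band [%g, %g] Hz exceeds the Nyquist frequency %g Hz.",
                  band$f1, band$f2, fs / 2))
  }
  tol <- 1e-9
  idx <- which(psd$freq_hz >= band$f1 - tol & psd$freq_hz <= band$f2 + tol)
  idx <- setdiff(idx, 1L)  # never include DC
  if (length(idx) == 0L) {
    abort(sprintf(
      "No FFT bin center falls inside band [%g, %g] Hz at resolution %g Hz.",
      band$f1, band$f2, psd_resolution(psd)
    ))
  }
  idx
}

#' Band log-amplitude index L(f1, f2)
#'
#' The unweighted arithmetic mean of the natural logarithm of the PSD
#' ordinates over the in-band bins: the discrete realization of
#' `L = (1/(f2 - f1)) * integral of ln PSD(f) df` over the band. L is
#' dimensionless up to an additive constant fixed by the sensor units;
#' scaling the signal by `c` shifts L by `2 ln c`.
#'
#' @param psd A `tremor_psd`.
#' @param band A [tremor_band()].
#' @param floor Optional positive density floor added before taking logs;
#'   by default none, and any non-positive in-band ordinate is an error.
#' @return L, a single numeric value.
#' @export
log_amplitude_index <- function(psd, band, floor = NULL) {
  idx <- band_bins(psd, band)
  p <- psd$psd[idx]
  if (!is.null(floor)) {
    if (floor <= 0) abort("`floor` must be positive.")
    p <- p + floor
  }
  if (any(p <= 0)) {
    abort(sprintf(
      "Log-amplitude undefined: %d non-positive PSD ordinate(s) in band [%g, %g] Hz.",
      sum(p <= 0), band$f1, band$f2
    ))
  }
  mean(log(p))
}

#' Band mean frequency F(f1, f2)
#'
#' The power-weighted mean of the in-band bin frequencies (spectral
#' centroid): the discrete realization of
#' `F = integral f PSD(f) df / integral PSD(f) df` over the band.
#' Always lies between the first and last in-band bin center.
#'
#' @param psd A `tremor_psd`.
#' @param band A [tremor_band()].
#' @return F in Hz.
#' @export
mean_frequency_index <- function(psd, band) {
  idx <- band_bins(psd, band)
  p <- psd$psd[idx]
  total <- sum(p)
  if (total <= 0) {
    abort(sprintf("Degenerate spectrum: zero total power in band [%g, %g] Hz.",
                  band$f1, band$f2))
  }
  sum(psd$freq_hz[idx] * p) / total
}

#' Compute both tremor indices for a recording
#'
#' Estimates the segment-averaged PSD once, then evaluates the log-amplitude
#' index L and mean frequency F for each requested band. Deterministic for a
#' fixed recording.
#'
#' @param rec An [accel_recording()].
#' @param bands List of [tremor_band()]s; default [canonical_bands()].
#' @param cfg A [spectral_config()].
#' @param floor Optional density floor passed to [log_amplitude_index()].
#' @return A tibble with one row per band: subject_id, condition, limb,
#'   band, L, F.
#' @examples
#' rec <- accel_recording(rnorm(6144), fs = 200)
#' compute_indices(rec)
#' @export
compute_indices <- function(rec, bands = canonical_bands(),
                            cfg = spectral_config(), floor = NULL) {
  psd <- estimate_psd(rec, cfg)
  purrr::map_dfr(bands, function(b) {
    tibble::tibble(
      subject_id = rec$subject_id,
      condition = rec$condition,
      limb = rec$limb,
      band = b$label,
      L = log_amplitude_index(psd, b, floor = floor),
      F = mean_frequency_index(psd, b)
    )
  })
}

#' Compute tremor indices for a set of recordings
#'
#' @param recs List of [accel_recording()]s.
#' @inheritParams compute_indices
#' @return A long tibble, one row per recording x band.
#' @export
indices_table <- function(recs, bands = canonical_bands(),
                          cfg = spectral_config(), floor = NULL) {
  purrr::map_dfr(recs, compute_indices, bands = bands, cfg = cfg, floor = floor)
}
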