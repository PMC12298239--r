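#' Construct an acceleration recording
#'
#' An `accel_recording` holds one trial's single-axis (vertical) acceleration
#' trace together with its sampling rate and subject/limb/condition metadata.
#' It is the unit of input to [estimate_psd()] and [compute_indices()].
#'
#' The canonical acquisition for the analysis pipeline is 200 Hz sampling and
#' at least 6144 samples (six contiguous 1024-sample segments, 30.72 s of
#' signal); shorter recordings are valid objects but are rejected by the
#' pipeline unless the spectral configuration is reduced to fit.
#'
#' @param samples Numeric vector of acceleration values (sensor units).
#' @param fs Sampling rate in Hz (positive). Default 200.
#' @param subject_id Subject identifier string.
#' @param limb `"left"` or `"right"`.
#' @param condition `"rest"`, `"endurance"` or `"sprint"`.
#' @param units Opaque unit string carried through unchanged (never
#'   converted); band log-amplitude values are only comparable within one
#'   unit convention.
#' @param trial_duration_s Optional nominal trial duration in seconds.
#' @return An object of class `accel_recording`.
#' @examples
#' rec <- accel_recording(sin(2 * pi * 3 * (0:6143) / 200), fs = 200)
#' rec
#' @export
accel_recording <- function(samples, fs = 200, subject_id = "S01",
                            limb = "left", condition = "rest",
                            units = "m/s^2", trial_duration_s = NULL) {
  rec <- structure(
    list(
      samples = as.numeric(samples),
      fs = as.numeric(fs),
      subject_id = as.character(subject_id),
      limb = as.character(limb),
      condition = as.character(condition),
      units = as.character(units),
      trial_duration_s = if (is.null(trial_duration_s)) NULL else as.numeric(trial_duration_s)
    ),
    class = "accel_recording"
  )
  validate_recording(rec)
}

#' Validate an acceleration recording
#'
#' Checks the structural invariants of an [accel_recording()]: positive
#' sampling rate, at least one finite sample, and limb/condition labels drawn
#' from their closed vocabularies. With `strict = TRUE` the recording must
#' also carry at least `min_samples` samples (default 6144, the pipeline's
#' canonical analyzed length).
#'
#' @param rec An `accel_recording`.
#' @param strict Enforce the pipeline minimum length?
#' @param min_samples Minimum sample count under `strict`.
#' @return `rec`, invisibly unchanged, or an error.
#' @export
validate_recording <- function(rec, strict = FALSE, min_samples = 6144L) {
  if (!inherits(rec, "accel_recording")) {
    abort("`rec` must be an `accel_recording` object.")
  }
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || !is.finite(rec$fs) || rec$fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  if (length(rec$samples) < 1L) {
    abort("Recording must contain at least one sample.")
  }
  if (anyNA(rec$samples) || !all(is.finite(rec$samples))) {
    abort("Recording samples must all be finite.")
  }
  if (!rec$limb %in% .limbs) {
    abort(sprintf("Unknown limb label %s: must be one of %s.",
                  dQuote(rec$limb, FALSE), paste(dQuote(.limbs, FALSE), collapse = ", ")))
  }
  if (!rec$condition %in% .conditions) {
    abort(sprintf("Unknown condition label %s: must be one of %s.",
                  dQuote(rec$condition, FALSE), paste(dQuote(.conditions, FALSE), collapse = ", ")))
  }
  if (strict && length(rec$samples) < min_samples) {
    abort(sprintf(
      "Recording too short for analysis: %d samples present, %d required.",
      length(rec$samples), as.integer(min_samples)
    ))
  }
  invisible(rec)
}

#' @export
print.accel_recording <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf(
    "<accel_recording> subject %s, %s limb, %s\n  %d samples @ %g Hz (%.2f s), units: %s\n",
    x$subject_id, x$limb, x$condition, length(x$samples), x$fs, dur, x$units
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#'
#' @param rec An `accel_recording`.
#' @return Sample count divided by sampling rate, in seconds.
#' @export
recording_duration <- function(rec) {
  validate_recording(rec)
  length(rec$samples) / rec$fs
}

.header_keys <- c("subject_id", "limb", "condition", "fs_hz", "units", "trial_duration_s")

#' Read an acceleration recording from a `.acc.tsv` file
#'
#' The recording format is self-describing UTF-8 text: header lines
#' `#key<TAB>value` for the keys `subject_id`, `limb`, `condition`, `fs_hz`,
#' `units` and optionally `trial_duration_s`, followed by one acceleration
#' value per line. Parsing is locale-independent (decimal point, no
#' thousands separators).
#'
#' @param path Path to the recording file.
#' @param strict Reject recordings shorter than 6144 samples (the pipeline's
#'   canonical analyzed length)?
#' @return A validated [accel_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, strict = FALSE) {
  if (!file.exists(path)) abort(sprintf("Recording file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  is_header <- startsWith(lines, "#")
  n_header <- match(FALSE, is_header, nomatch = length(lines) + 1L) - 1L
  if (n_header == 0L) {
    abort(sprintf("Missing header in %s: expected '#key<TAB>value' lines first.", path))
  }
  hdr <- list()
  for (i in seq_len(n_header)) {
    parts <- strsplit(sub("^#", "", lines[[i]]), "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      abort(sprintf("Garbled header at line %d of %s: %s", i, path, dQuote(lines[[i]], FALSE)))
    }
    if (!parts[[1]] %in% .header_keys) {
      abort(sprintf("Unknown header key %s at line %d of %s.", dQuote(parts[[1]], FALSE), i, path))
    }
    hdr[[parts[[1]]]] <- parts[[2]]
  }
  required <- c("subject_id", "limb", "condition", "fs_hz", "units")
  missing <- setdiff(required, names(hdr))
  if (length(missing) > 0L) {
    abort(sprintf("Missing header key(s) in %s: %s.", path, paste(missing, collapse = ", ")))
  }
  body <- lines[seq.int(n_header + 1L, length.out = length(lines) - n_header)]
  body <- body[nzchar(body)]
  samples <- suppressWarnings(as.numeric(body))
  bad <- which(is.na(samples))
  if (length(bad) > 0L) {
    abort(sprintf("Non-numeric sample %s at line %d of %s.",
                  dQuote(body[[bad[[1]]]], FALSE), n_header + bad[[1]], path))
  }
  fs <- suppressWarnings(as.numeric(hdr$fs_hz))
  if (is.na(fs)) abort(sprintf("Non-numeric fs_hz header in %s.", path))
  dur <- if (is.null(hdr$trial_duration_s)) NULL else suppressWarnings(as.numeric(hdr$trial_duration_s))
  rec <- accel_recording(
    samples = samples, fs = fs,
    subject_id = hdr$subject_id, limb = hdr$limb, condition = hdr$condition,
    units = hdr$units, trial_duration_s = dur
  )
  validate_recording(rec, strict = strict)
  rec
}

#' Write an acceleration recording to a `.acc.tsv` file
#'
#' Samples are serialized with 17 significant digits so a write/read round
#' trip reproduces every sample bit-identically.
#'
#' @param rec A valid [accel_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  hdr <- c(
    sprintf("#subject_id\t%s", rec$subject_id),
    sprintf("#limb\t%s", rec$limb),
    sprintf("#condition\t%s", rec$condition),
    sprintf("#fs_hz\t%s", sprintf("%.17g", rec$fs)),
    sprintf("#units\t%s", rec$units)
  )
  if (!is.null(rec$trial_duration_s)) {
    hdr <- c(hdr, sprintf("#trial_duration_s\t%s", sprintf("%.17g", rec$trial_duration_s)))
  }
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) abort(sprintf("Cannot write to %s: %s", path, conditionMessage(e))))
  on.exit(close(con))
  writeLines(c(hdr, sprintf("%.17g", rec$samples)), con)
  invisible(path)
}

#' Write an index / cohort table to TSV
#'
#' Fixed column order: subject_id, condition, limb, band, L, F.
#'
#' @param table Tibble with at least those columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_table <- function(table, path) {
  cols <- c("subject_id", "condition", "limb", "band", "L", "F")
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0L) {
    abort(sprintf("Index table is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  readr::write_tsv(table[cols], path)
  invisible(path)
}

#' Read an index / cohort table from TSV
#'
#' @param path Path to a TSV written by [write_index_table()].
#' @return Tibble with columns subject_id, condition, limb, band, L, F.
#' @export
read_index_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cols <- c("subject_id", "condition", "limb", "band", "L", "F")
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0L) {
    abort(sprintf("File %s is missing column(s): %s.", path, paste(missing, collapse = ", ")))
  }
  bad_cond <- setdiff(unique(tab$condition), .conditions)
  if (length(bad_cond) > 0L) {
    abort(sprintf("Unknown condition label(s) in %s: %s.", path, paste(bad_cond, collapse = ", ")))
  }
  bad_limb <- setdiff(unique(tab$limb), .limbs)
  if (length(bad_limb) > 0L) {
    abort(sprintf("Unknown limb label(s) in %s: %s.", path, paste(bad_limb, collapse = ", ")))
  }
  tibble::as_tibble(tab[cols])
}
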