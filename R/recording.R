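#' Construct a continuous multi-channel EEG recording
#'
#' The session container: channel-major sample matrix, sampling rate, an
#' event-marker table encoding the five trial phases, and session metadata.
#'
#' @param data Ne x Ntotal numeric matrix, microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_names Ordered channel names; length must equal `nrow(data)`.
#' @param markers data.frame with columns `sample` (0-based sample index),
#'   `code` (integer phase code: 1 fixation, 2 target presentation, 3
#'   preparation, 4 stimulation onset, 5 rest onset) and `payload` (integer;
#'   the target index on code-2 markers, `NA` elsewhere).
#' @param paradigm Paradigm code or `NA`.
#' @param subject_id Subject identifier string.
#' @param frequencies Stimulation frequencies (Hz) indexed by the code-2
#'   marker payloads.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, channel_names, markers = empty_markers(),
                      paradigm = NA_character_, subject_id = "unknown",
                      frequencies = stimulation_frequencies()) {
  rec <- structure(
    list(data = data, fs = fs, channel_names = channel_names,
         markers = markers, paradigm = paradigm, subject_id = subject_id,
         frequencies = as.numeric(frequencies)),
    class = "eeg_recording"
  )
  validate_recording(rec)
}

#' @rdname recording
#' @param rec An `eeg_recording` object to validate.
#' @export
validate_recording <- function(rec) {
  if (!is.matrix(rec$data) || !is.numeric(rec$data)) {
    stop("recording data must be a numeric matrix", call. = FALSE)
  }
  if (nrow(rec$data) != length(rec$channel_names)) {
    stop("channel count mismatch: ", nrow(rec$data), " rows vs ",
         length(rec$channel_names), " channel names", call. = FALSE)
  }
  if (!is.numeric(rec$fs) || rec$fs <= 0) {
    stop("fs must be a positive sampling rate", call. = FALSE)
  }
  m <- rec$markers
  if (!is.data.frame(m) || !all(c("sample", "code", "payload") %in% names(m))) {
    stop("markers must be a data.frame with sample, code, payload",
         call. = FALSE)
  }
  if (nrow(m) > 0) {
    if (any(m$sample < 0) || any(m$sample >= ncol(rec$data))) {
      stop("marker sample indices must lie inside the recording",
           call. = FALSE)
    }
    if (is.unsorted(m$sample)) {
      stop("marker sample indices must be non-decreasing", call. = FALSE)
    }
  }
  rec
}

#' @export
empty_markers <- function() {
  data.frame(sample = integer(0), code = integer(0), payload = integer(0))
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording>", nrow(x$data), "channels x", ncol(x$data),
      "samples @", x$fs, "Hz (", round(ncol(x$data) / x$fs, 2), "s )\n")
  cat("  paradigm:", x$paradigm, "| subject:", x$subject_id, "|",
      nrow(x$markers), "markers\n")
  invisible(x)
}

#' Write a recording to disk (delimited text + JSON sidecar)
#'
#' The container is a pair of plain-text files: `<path>.tsv` holding the
#' sample matrix (samples in rows, one column per channel, full double
#' precision) and `<path>.json` holding sampling rate, channel names, markers
#' and session metadata. The round trip is lossless to the printed precision
#' (15 significant digits).
#'
#' @param rec An `eeg_recording`.
#' @param path Output path stem (no extension).
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: ", dir, call. = FALSE)
  mat <- t(rec$data)
  colnames(mat) <- rec$channel_names
  utils::write.table(format(mat, digits = 15, trim = TRUE, scientific = TRUE),
                     paste0(path, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    format = "ssvepbench-recording", version = 1L,
    fs = rec$fs, channel_names = rec$channel_names,
    paradigm = rec$paradigm, subject_id = rec$subject_id,
    frequencies = rec$frequencies,
    markers = rec$markers
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Path stem as passed to [write_recording()].
#' @return A validated `eeg_recording`.
#' @export
read_recording <- function(path) {
  tsv <- paste0(path, ".tsv")
  js <- paste0(path, ".json")
  if (!file.exists(tsv) || !file.exists(js)) {
    stop("no recording at ", path, " (expected .tsv and .json pair)",
         call. = FALSE)
  }
  sidecar <- tryCatch(jsonlite::read_json(js, simplifyVector = TRUE),
                      error = function(e) {
                        stop("corrupt sidecar ", js, ": ", conditionMessage(e),
                             call. = FALSE)
                      })
  if (!identical(sidecar$format, "ssvepbench-recording")) {
    stop("unknown recording dialect in ", js, call. = FALSE)
  }
  mat <- tryCatch(
    as.matrix(utils::read.table(tsv, header = TRUE, sep = "\t",
                                check.names = FALSE)),
    error = function(e) {
      stop("corrupt data file ", tsv, ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (!is.numeric(mat)) stop("corrupt data file ", tsv, call. = FALSE)
  markers <- sidecar$markers
  if (is.null(markers) || length(markers) == 0 || NROW(markers) == 0) {
    markers <- empty_markers()
  } else {
    markers <- as.data.frame(markers)
    markers$sample <- as.integer(markers$sample)
    markers$code <- as.integer(markers$code)
    markers$payload <- suppressWarnings(as.integer(markers$payload))
  }
  recording(
    data = t(mat), fs = sidecar$fs, channel_names = sidecar$channel_names,
    markers = markers, paradigm = sidecar$paradigm %||% NA_character_,
    subject_id = sidecar$subject_id %||% "unknown",
    frequencies = sidecar$frequencies %||% stimulation_frequencies()
  )
}

#' Band-pass and notch filtering of a recording
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-pass
#' plus a 2nd-order Butterworth band-stop notch per channel. Markers are
#' unchanged.
#'
#' @param rec An `eeg_recording`.
#' @param band Pass-band edges in Hz, default `c(0.5, 60)`.
#' @param notch Notch center frequency in Hz (power-line suppression),
#'   default 60; `NULL` disables the notch. Use 50 in 50-Hz mains regions.
#' @param notch_halfwidth Half-width of the stop band in Hz.
#' @return Filtered `eeg_recording`.
#' @export
preprocess <- function(rec, band = c(0.5, 60), notch = 60,
                       notch_halfwidth = 2) {
  validate_recording(rec)
  nyq <- rec$fs / 2
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq)) {
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  bp <- signal::butter(4, band / nyq, "pass")
  filters <- list(bp)
  if (!is.null(notch)) {
    if (notch - notch_halfwidth <= 0 || notch + notch_halfwidth >= nyq) {
      stop("notch band must lie inside (0, fs/2)", call. = FALSE)
    }
    filters <- c(filters, list(
      signal::butter(2, c(notch - notch_halfwidth,
                          notch + notch_halfwidth) / nyq, "stop")))
  }
  out <- rec
  for (e in seq_len(nrow(rec$data))) {
    x <- rec$data[e, ]
    for (fl in filters) x <- signal::filtfilt(fl, x)
    out$data[e, ] <- x
  }
  out
}

#' One trial's windowed signal epoch
#'
#' @param X Ne x Nt signal matrix.
#' @param fs Sampling rate.
#' @param t0 Epoch start relative to stimulation onset, seconds.
#' @param kind One of `"stimulation"`, `"no_stimulation"`, `"detection"`.
#' @param target_frequency Attended stimulation frequency in Hz.
#' @param paradigm Paradigm code.
#' @param trial_index 1-based trial index within the run.
#' @return Object of class `eeg_epoch`.
#' @export
epoch <- function(X, fs, t0, kind, target_frequency, paradigm = NA,
                  trial_index = NA) {
  kind <- match.arg(kind, c("stimulation", "no_stimulation", "detection"))
  structure(
    list(X = X, fs = fs, t0 = t0, kind = kind,
         target_frequency = target_frequency, paradigm = paradigm,
         trial_index = trial_index),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat("<eeg_epoch>", x$kind, ":", nrow(x$X), "ch x", ncol(x$X), "samples, t0 =",
      x$t0, "s, target", signif(x$target_frequency, 6), "Hz\n")
  invisible(x)
}

#' Cut the per-trial analysis epochs from a recording
#'
#' Three epoch kinds are supported, all anchored on the stimulation-onset
#' marker of each trial: `"stimulation"` covers the 5-s stimulation phase
#' (`t0 = 0`), `"no_stimulation"` the 5 s immediately preceding onset
#' (fixation + target presentation + preparation), and `"detection"` a 6-s
#' window starting 1 s before onset. Sample intervals are half-open
#' `[start, end)` with boundaries at `round(fs * t)`. Trials with a missing
#' phase marker are skipped with a warning.
#'
#' @param rec An `eeg_recording` with phase markers.
#' @param kind Epoch kind (see above).
#' @param stimulation_s Stimulation phase duration in seconds.
#' @param pre_s Pre-onset span (s) covered by `no_stimulation` epochs, and
#'   whose final second precedes `detection` epochs.
#' @return List of `eeg_epoch` objects, one per complete trial.
#' @export
extract_epochs <- function(rec, kind = c("stimulation", "no_stimulation",
                                         "detection"),
                           stimulation_s = 5, pre_s = 5) {
  kind <- match.arg(kind)
  validate_recording(rec)
  m <- rec$markers
  fix_idx <- which(m$code == MARKER_CODES[["fixation"]])
  n_total <- ncol(rec$data)
  epochs <- list()
  skipped <- 0L
  for (i in seq_along(fix_idx)) {
    lo <- fix_idx[i]
    hi <- if (i < length(fix_idx)) fix_idx[i + 1] - 1 else nrow(m)
    trial <- m[lo:hi, , drop = FALSE]
    onset_row <- trial[trial$code == MARKER_CODES[["stimulation"]], ]
    target_row <- trial[trial$code == MARKER_CODES[["target"]], ]
    if (nrow(onset_row) != 1 || nrow(target_row) != 1 ||
        is.na(target_row$payload)) {
      skipped <- skipped + 1L
      next
    }
    onset <- onset_row$sample[1]                   # 0-based
    span <- switch(kind,
      stimulation = c(0, stimulation_s),
      no_stimulation = c(-pre_s, 0),
      detection = c(-1, stimulation_s))
    start <- onset + round(span[1] * rec$fs)       # 0-based, inclusive
    end <- onset + round(span[2] * rec$fs)         # exclusive
    if (start < 0 || end > n_total) {
      skipped <- skipped + 1L
      next
    }
    ti <- target_row$payload[1]
    epochs[[length(epochs) + 1]] <- epoch(
      X = rec$data[, (start + 1):end, drop = FALSE], fs = rec$fs,
      t0 = span[1], kind = kind,
      target_frequency = rec$frequencies[ti + 1],
      paradigm = rec$paradigm, trial_index = i
    )
  }
  if (skipped > 0) {
    warning(skipped, " trial(s) skipped (missing markers or truncated data)",
            call. = FALSE)
  }
  epochs
}
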