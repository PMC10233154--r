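#' Stimulation frequencies realizable on a fixed-refresh display
#'
#' Flicker frequencies on an LCD are constrained to integer divisors of the
#' monitor refresh rate: a square toggled every `d` frames flickers at
#' `refresh_hz / d`. The default divisors reproduce the five-target layout
#' used throughout this package: 240 Hz refresh with divisors 28, 22, 16, 12
#' and 10 gives 8.5714, 10.9091, 15, 20 and 24 Hz.
#'
#' @param refresh_hz Monitor refresh rate in Hz.
#' @param frame_divisors Integer number of frames per flicker period, one per
#'   target.
#' @return Numeric vector of stimulation frequencies in Hz.
#' @examples
#' stimulation_frequencies()
#' @export
stimulation_frequencies <- function(refresh_hz = 240,
                                    frame_divisors = c(28, 22, 16, 12, 10)) {
  stopifnot(refresh_hz > 0, all(frame_divisors >= 1))
  refresh_hz / frame_divisors
}

#' Paradigm codes for the four visual stimulus types
#'
#' On-Off (OO) or Checkerboard (CB) pattern, luminance modulated by a
#' Rectangular (R) or Sinusoidal (S) waveform. For checkerboard stimuli the
#' evoked response appears at the pattern-reversal rate, so the frequencies in
#' a [stimulus_spec()] are always the expected *response* frequencies; only
#' the response amplitude differs between patterns.
#'
#' @export
PARADIGMS <- c("OOR", "OOS", "CBR", "CBS")

#' Specification of a multi-target flicker stimulus
#'
#' @param paradigm One of `"OOR"`, `"OOS"`, `"CBR"`, `"CBS"`.
#' @param frequencies Stimulation frequencies in Hz, one per target; strictly
#'   positive and pairwise distinct.
#' @return An object of class `stimulus_spec` with fields `paradigm`,
#'   `frequencies` and `n_targets`.
#' @examples
#' stimulus_spec("OOS")
#' @export
stimulus_spec <- function(paradigm = "OOR",
                          frequencies = stimulation_frequencies()) {
  paradigm <- match.arg(paradigm, PARADIGMS)
  frequencies <- as.numeric(frequencies)
  if (any(frequencies <= 0)) {
    stop("stimulation frequencies must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(frequencies)) {
    stop("stimulation frequencies must be pairwise distinct", call. = FALSE)
  }
  structure(
    list(paradigm = paradigm, frequencies = frequencies,
         n_targets = length(frequencies)),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("<stimulus_spec> paradigm", x$paradigm, "-", x$n_targets, "targets at",
      paste(signif(x$frequencies, 6), collapse = ", "), "Hz\n")
  invisible(x)
}

#' Trial phase durations
#'
#' A trial runs through five phases: Fixation, Target Presentation,
#' Preparation, Stimulation and Rest. Defaults (2, 2, 1, 5, 5 s) give the
#' standard 15-s trial.
#'
#' @param fixation_s,target_s,preparation_s,stimulation_s,rest_s Phase
#'   durations in seconds, all non-negative.
#' @return An object of class `trial_timing`.
#' @export
trial_timing <- function(fixation_s = 2, target_s = 2, preparation_s = 1,
                         stimulation_s = 5, rest_s = 5) {
  durs <- c(fixation_s = fixation_s, target_s = target_s,
            preparation_s = preparation_s, stimulation_s = stimulation_s,
            rest_s = rest_s)
  if (any(durs < 0)) stop("phase durations must be non-negative", call. = FALSE)
  structure(as.list(durs), class = "trial_timing")
}

#' Total trial duration in seconds
#' @param timing A [trial_timing()] object.
#' @export
trial_duration <- function(timing) {
  timing$fixation_s + timing$target_s + timing$preparation_s +
    timing$stimulation_s + timing$rest_s
}

# phase onset times (s) relative to trial start, in marker emission order
phase_onsets <- function(timing) {
  c(fixation = 0,
    target = timing$fixation_s,
    preparation = timing$fixation_s + timing$target_s,
    stimulation = timing$fixation_s + timing$target_s + timing$preparation_s,
    rest = timing$fixation_s + timing$target_s + timing$preparation_s +
      timing$stimulation_s)
}

# marker code enum shared by the generator and the readers
MARKER_CODES <- c(fixation = 1L, target = 2L, preparation = 3L,
                  stimulation = 4L, rest = 5L)
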