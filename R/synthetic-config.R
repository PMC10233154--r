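#' Default occipital/parieto-occipital channel montage
#' @export
DEFAULT_CHANNELS <- c("PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")

#' Configuration of the synthetic SSVEP session generator
#'
#' Describes the signal model used to emulate a recording session: an evoked
#' harmonic component, present only during visual stimulation, superimposed on
#' background EEG made of pink (1/f^gamma) noise plus a narrow-band alpha
#' component. Channel `e` of the evoked part is
#' `sum_h A[e,h] * gain * sin(2*pi*h*f*t + phi[e,h])`, with harmonics above
#' Nyquist truncated.
#'
#' @param fs Sampling rate in Hz.
#' @param channels Ordered channel names.
#' @param n_harmonics Number of harmonics in the evoked component.
#' @param harmonic_amplitudes Ne x Nh matrix of per-channel, per-harmonic
#'   amplitudes in microvolts. The default decays as `1/h` across harmonics
#'   and weights occipital channels (O1, Oz, O2) above the parieto-occipital
#'   ring, mimicking the usual scalp topography of the response.
#' @param harmonic_phases Ne x Nh matrix of phase offsets in radians
#'   (default 0).
#' @param paradigm_gain Named multiplicative response gain per paradigm.
#'   Checkerboard responses are roughly three times weaker than On-Off ones,
#'   hence the default `OOR = OOS = 1`, `CBR = CBS = 1/3`.
#' @param noise_gamma Spectral exponent of the pink background noise
#'   (`gamma = 1` is classic 1/f EEG background; 0 gives white noise).
#' @param noise_rms Broadband background RMS amplitude per channel, microvolts.
#' @param alpha_amp RMS amplitude (microvolts) of the additive 8-13 Hz alpha
#'   band component.
#' @param alpha_band Alpha component band edges in Hz.
#' @param target_snr_db Wide-band SNR (dB) that unit-gain (On-Off)
#'   stimulation segments should approximately attain; the evoked amplitude
#'   scale is calibrated per trial against the realized background power.
#'   `NULL` disables calibration and uses `harmonic_amplitudes` verbatim.
#' @param seed Master RNG seed; identical configuration and seed give
#'   byte-identical sessions. Per-trial sub-seeds are derived
#'   deterministically from it.
#' @return An object of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' dim(cfg$harmonic_amplitudes)
#' @export
synthetic_config <- function(fs = 256,
                             channels = DEFAULT_CHANNELS,
                             n_harmonics = 4,
                             harmonic_amplitudes = NULL,
                             harmonic_phases = NULL,
                             paradigm_gain = c(OOR = 1, OOS = 1,
                                               CBR = 1 / 3, CBS = 1 / 3),
                             noise_gamma = 1,
                             noise_rms = 10,
                             alpha_amp = 2,
                             alpha_band = c(8, 13),
                             target_snr_db = 0,
                             seed = 1L) {
  ne <- length(channels)
  nh <- as.integer(n_harmonics)
  stopifnot(fs > 0, ne >= 1, nh >= 1, noise_rms >= 0, alpha_amp >= 0)
  if (is.null(harmonic_amplitudes)) {
    # occipital row strongest, 1/h harmonic decay
    w <- ifelse(channels %in% c("O1", "O2"), 0.9,
                ifelse(channels == "Oz", 1.0,
                       ifelse(channels == "POz", 0.7, 0.6)))
    harmonic_amplitudes <- outer(w, 1 / seq_len(nh))
  }
  harmonic_amplitudes <- as.matrix(harmonic_amplitudes)
  if (!all(dim(harmonic_amplitudes) == c(ne, nh))) {
    stop("harmonic_amplitudes must be a ", ne, " x ", nh, " matrix",
         call. = FALSE)
  }
  if (any(harmonic_amplitudes < 0)) {
    stop("harmonic amplitudes must be non-negative", call. = FALSE)
  }
  if (is.null(harmonic_phases)) {
    harmonic_phases <- matrix(0, ne, nh)
  }
  harmonic_phases <- as.matrix(harmonic_phases)
  if (!all(dim(harmonic_phases) == c(ne, nh))) {
    stop("harmonic_phases must be a ", ne, " x ", nh, " matrix", call. = FALSE)
  }
  if (!all(PARADIGMS %in% names(paradigm_gain))) {
    stop("paradigm_gain must name all of ", paste(PARADIGMS, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(fs = fs, channels = channels, n_harmonics = nh,
         harmonic_amplitudes = harmonic_amplitudes,
         harmonic_phases = harmonic_phases,
         paradigm_gain = paradigm_gain[PARADIGMS],
         noise_gamma = noise_gamma, noise_rms = noise_rms,
         alpha_amp = alpha_amp, alpha_band = alpha_band,
         target_snr_db = target_snr_db,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>", length(x$channels), "channels @", x$fs, "Hz,",
      x$n_harmonics, "harmonics\n")
  cat("  noise: pink gamma =", x$noise_gamma, ", rms =", x$noise_rms,
      "uV + alpha", x$alpha_amp, "uV\n")
  cat("  target SNR:",
      if (is.null(x$target_snr_db)) "uncalibrated" else
        paste(x$target_snr_db, "dB"),
      "| seed:", x$seed, "\n")
  invisible(x)
}
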