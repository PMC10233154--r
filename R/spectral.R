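#' Segment-averaged power spectral density of an epoch
#'
#' Per channel, averages one-sided periodograms over non-overlapping 2-s
#' Hanning-tapered segments (Bartlett/Welch with zero overlap); any trailing
#' remainder shorter than one segment is discarded. The taper is
#' power-normalized (density divided by `sum(w^2)`), so the integral of the
#' density over the full one-sided grid recovers the signal variance
#' (Parseval). At the default `fs = 256` and 2-s segments the native grid
#' step is exactly 0.5 Hz, matching the 2-50 Hz reporting grid with no
#' padding.
#'
#' @param ep An [epoch()] (or any list with elements `X` and `fs`).
#' @param seg_len_s Segment length in seconds.
#' @param report_band Reporting band in Hz; `power`/`freqs` are restricted to
#'   it, while `full_power`/`full_freqs` keep the whole 0..fs/2 grid for SNR.
#' @return Object of class `psd_result`: `freqs`, `power` (Ne x Nfreq,
#'   microvolt^2/Hz), `full_freqs`, `full_power`, `segment_count`, `window`.
#' @export
compute_psd <- function(ep, seg_len_s = 2.0, report_band = c(2, 50)) {
  X <- ep$X
  fs <- ep$fs
  nseg_len <- round(seg_len_s * fs)
  nt <- ncol(X)
  n_seg <- floor(nt / nseg_len)
  if (n_seg < 1) {
    stop("epoch shorter than one PSD segment (", seg_len_s, " s)",
         call. = FALSE)
  }
  w <- hanning_window(nseg_len)
  u <- sum(w^2)                       # taper power normalization
  n_onesided <- floor(nseg_len / 2) + 1
  full_freqs <- (seq_len(n_onesided) - 1) * fs / nseg_len
  pw <- matrix(0, nrow(X), n_onesided)
  for (s in seq_len(n_seg)) {
    cols <- (s - 1) * nseg_len + seq_len(nseg_len)
    seg <- X[, cols, drop = FALSE]
    seg <- seg - rowMeans(seg)        # detrend mean per segment
    for (e in seq_len(nrow(X))) {
      sp <- fft(seg[e, ] * w)[seq_len(n_onesided)]
      p <- Mod(sp)^2 / (fs * u)
      # one-sided: double interior bins (not DC; not Nyquist when present)
      dbl <- 2:(n_onesided - if (nseg_len %% 2 == 0) 1 else 0)
      p[dbl] <- 2 * p[dbl]
      pw[e, ] <- pw[e, ] + p
    }
  }
  pw <- pw / n_seg
  rownames(pw) <- rownames(X)
  keep <- which(full_freqs >= report_band[1] & full_freqs <= report_band[2])
  structure(
    list(freqs = full_freqs[keep], power = pw[, keep, drop = FALSE],
         full_freqs = full_freqs, full_power = pw,
         segment_count = n_seg, window = "hanning"),
    class = "psd_result"
  )
}

hanning_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' @export
print.psd_result <- function(x, ...) {
  cat("<psd_result>", nrow(x$power), "channels,", length(x$freqs),
      "reported bins (", min(x$freqs), "-", max(x$freqs), "Hz ),",
      x$segment_count, "segment(s),", x$window, "taper\n")
  invisible(x)
}

#' Wide-band signal-to-noise ratio of an SSVEP response
#'
#' `SNR = 10*log10( sum_k P(k*f) / (sum_f P(f) - sum_k P(k*f)) )` for
#' harmonics `k = 1..n_harmonics`, with the denominator summed over the full
#' one-sided 0..fs/2 grid. Harmonic powers are looked up at the nearest grid
#' bin (at the 0.5-Hz default grid, 8.5714 Hz maps to the 8.5 Hz bin);
#' harmonics beyond Nyquist are dropped. Returned per channel together with
#' the channel-averaged value (mean of the per-channel dB values).
#'
#' @param psd A `psd_result` from [compute_psd()].
#' @param f Fundamental stimulation frequency in Hz; must lie on the grid
#'   span.
#' @param n_harmonics Number of harmonics summed into the numerator.
#' @param cap_db Finite sentinel returned when the non-harmonic power
#'   underflows to zero (all power at the harmonics).
#' @return List with `per_channel` (named dB vector) and `mean_db`.
#' @export
wideband_snr <- function(psd, f, n_harmonics = 4, cap_db = 300) {
  full_f <- psd$full_freqs
  if (f <= 0 || f > max(full_f)) {
    stop("f outside the PSD grid", call. = FALSE)
  }
  harmonics <- f * seq_len(n_harmonics)
  harmonics <- harmonics[harmonics <= max(full_f)]
  bins <- unique(vapply(harmonics, function(h) which.min(abs(full_f - h)),
                        integer(1)))
  p <- psd$full_power
  num <- rowSums(p[, bins, drop = FALSE])
  den <- rowSums(p) - num
  snr <- ifelse(den <= num * 10^(-cap_db / 10), cap_db,
                10 * log10(num / den))
  snr <- pmin(snr, cap_db)
  names(snr) <- rownames(p)
  list(per_channel = snr, mean_db = mean(snr))
}

#' Stimulation-versus-baseline channel-frequency significance map
#'
#' For every (channel, frequency-bin) cell, a two-sample rank test compares
#' the per-epoch PSD values of the stimulation epochs against the
#' no-stimulation epochs, Bonferroni-corrected over all `Ne x Nfreq` cells.
#' The default is the unpaired Wilcoxon rank-sum test; `paired = TRUE`
#' switches to the signed-rank test (requires equal epoch counts).
#'
#' @param stim,nostim Lists of epochs, same channel set, at least 2 each.
#' @param alpha Per-family significance level (default 0.01).
#' @param paired Use the paired signed-rank test instead of rank-sum.
#' @param ... Passed to [compute_psd()].
#' @return Object of class `contrast_map`: `pvalues` and `significant`
#'   (Ne x Nfreq matrices), `freqs`, `alpha`, `corrected_alpha`, `n_tests`.
#' @export
condition_contrast <- function(stim, nostim, alpha = 0.01, paired = FALSE,
                               ...) {
  if (length(stim) < 2 || length(nostim) < 2) {
    stop("need at least 2 epochs per condition for a rank test",
         call. = FALSE)
  }
  chan <- rownames(stim[[1]]$X)
  if (!identical(chan, rownames(nostim[[1]]$X))) {
    stop("stimulation and baseline epochs have mismatched channels",
         call. = FALSE)
  }
  if (paired && length(stim) != length(nostim)) {
    stop("paired test requires equal epoch counts", call. = FALSE)
  }
  psd_s <- lapply(stim, compute_psd, ...)
  psd_n <- lapply(nostim, compute_psd, ...)
  freqs <- psd_s[[1]]$freqs
  ne <- nrow(psd_s[[1]]$power)
  nf <- length(freqs)
  arr_s <- vapply(psd_s, function(p) p$power, matrix(0, ne, nf))
  arr_n <- vapply(psd_n, function(p) p$power, matrix(0, ne, nf))
  pvals <- matrix(NA_real_, ne, nf, dimnames = list(chan, NULL))
  for (e in seq_len(ne)) {
    for (k in seq_len(nf)) {
      a <- arr_s[e, k, ]
      b <- arr_n[e, k, ]
      pvals[e, k] <- if (paired) {
        suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
      } else {
        suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
      }
    }
  }
  n_tests <- ne * nf
  corrected <- alpha / n_tests
  structure(
    list(pvalues = pvals, significant = pvals < corrected, freqs = freqs,
         alpha = alpha, corrected_alpha = corrected, n_tests = n_tests,
         test = if (paired) "wilcoxon-signed-rank" else "wilcoxon-rank-sum"),
    class = "contrast_map"
  )
}

#' @export
print.contrast_map <- function(x, ...) {
  cat("<contrast_map>", nrow(x$pvalues), "channels x", length(x$freqs),
      "bins;", x$test, "; alpha =", x$alpha, "Bonferroni ->",
      signif(x$corrected_alpha, 3), ";", sum(x$significant),
      "significant cells\n")
  invisible(x)
}

#' Tidy export of a PSD or contrast map
#'
#' @param x A `psd_result` or `contrast_map`.
#' @return A tibble with one row per (channel, frequency) cell.
#' @export
as_tidy_spectrum <- function(x) {
  if (inherits(x, "psd_result")) {
    tibble::tibble(
      channel = rep(rownames(x$power) %||%
                      paste0("ch", seq_len(nrow(x$power))),
                    times = ncol(x$power)),
      frequency = rep(x$freqs, each = nrow(x$power)),
      power = as.vector(x$power)
    )
  } else if (inherits(x, "contrast_map")) {
    tibble::tibble(
      channel = rep(rownames(x$pvalues) %||%
                      paste0("ch", seq_len(nrow(x$pvalues))),
                    times = ncol(x$pvalues)),
      frequency = rep(x$freqs, each = nrow(x$pvalues)),
      p_value = as.vector(x$pvalues),
      significant = as.vector(x$significant)
    )
  } else {
    stop("unsupported object", call. = FALSE)
  }
}
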