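#' Filter-bank specification for FBCCA
#'
#' Five Chebyshev type I band-pass filters with a common high edge, whose low
#' edges step up past successive harmonics, are the standard decomposition:
#' each sub-band drops one more low-order component, so the weighted
#' recombination emphasizes the informative harmonics. Sub-band weights
#' follow `w(n) = n^(-a) + b`.
#'
#' @param bands List (or 2-column matrix) of `(low, high)` pass-band edges in
#'   Hz; default `(6,90), (9,90), (13,90), (18,90), (22,90)`.
#' @param a,b Sub-band weight parameters, defaults `a = 1.25`, `b = 0.25`.
#' @param order Chebyshev type I filter order.
#' @param ripple_db Pass-band ripple in dB. The default 0.2 dB keeps the
#'   zero-phase (squared) response within 5% of unity across the pass band.
#' @return Object of class `filter_bank_spec`.
#' @export
filter_bank_spec <- function(bands = list(c(6, 90), c(9, 90), c(13, 90),
                                          c(18, 90), c(22, 90)),
                             a = 1.25, b = 0.25, order = 4,
                             ripple_db = 0.2) {
  if (is.matrix(bands)) bands <- asplit(bands, 1)
  bands <- lapply(bands, as.numeric)
  if (length(bands) < 1) stop("need at least one sub-band", call. = FALSE)
  for (bd in bands) {
    if (length(bd) != 2 || bd[1] <= 0 || bd[1] >= bd[2]) {
      stop("each band must be (low, high) with 0 < low < high", call. = FALSE)
    }
  }
  sb <- length(bands)
  weights <- seq_len(sb)^(-a) + b
  if (any(weights <= 0)) stop("sub-band weights must be positive",
                              call. = FALSE)
  structure(
    list(bands = bands, weights = weights, a = a, b = b, order = order,
         ripple_db = ripple_db),
    class = "filter_bank_spec"
  )
}

#' @export
print.filter_bank_spec <- function(x, ...) {
  edges <- vapply(x$bands, function(b) paste(b, collapse = "-"), "")
  cat("<filter_bank_spec>", length(x$bands), "Chebyshev-I band(s):",
      paste(edges, collapse = ", "), "Hz; w(n) = n^(-", x$a, ") +", x$b, "\n")
  invisible(x)
}

#' Realize a filter bank at a given sampling rate
#'
#' Designs the Chebyshev type I band-pass filters, clipping high edges that
#' exceed 95% of Nyquist, and asserts stability (all poles strictly inside
#' the unit circle). Filters are meant for zero-phase application
#' ([signal::filtfilt()]).
#'
#' @param spec A [filter_bank_spec()].
#' @param fs Sampling rate in Hz.
#' @return List of `Arma` filter objects (one per band) with attribute
#'   `bands` holding the realized (possibly clipped) edges.
#' @export
design_filter_bank <- function(spec, fs) {
  nyq <- fs / 2
  realized <- list()
  edges <- list()
  for (i in seq_along(spec$bands)) {
    bd <- spec$bands[[i]]
    hi <- min(bd[2], 0.95 * nyq)
    if (bd[1] >= hi) {
      stop("band ", i, " collapses after Nyquist clipping at fs = ", fs,
           call. = FALSE)
    }
    fl <- signal::cheby1(spec$order, spec$ripple_db, c(bd[1], hi) / nyq,
                         "pass")
    poles <- polyroot(rev(fl$a))
    if (any(Mod(poles) >= 1)) {
      stop("unstable filter design for band ", bd[1], "-", hi,
           " Hz; lower the order", call. = FALSE)
    }
    realized[[i]] <- fl
    edges[[i]] <- c(bd[1], hi)
  }
  attr(realized, "bands") <- edges
  realized
}

# zero-phase application of one bank filter to all channels
apply_bank_filter <- function(fl, X) {
  out <- X
  for (e in seq_len(nrow(X))) out[e, ] <- signal::filtfilt(fl, X[e, ])
  out
}

#' Filter-bank CCA score for one candidate frequency
#'
#' Computes the canonical correlation between each sub-band-filtered version
#' of the signal and the (unfiltered) harmonic reference, and combines them
#' as `rho_tilde = sum_n w(n) * rho_n^2`.
#'
#' @param X Ne x Nt signal matrix.
#' @param f Candidate frequency in Hz.
#' @param bank A [filter_bank_spec()], or `NULL` for a single all-pass band
#'   (reduces to squared plain CCA when the weight is 1).
#' @param Nh Harmonics in the reference template.
#' @param fs Sampling rate in Hz.
#' @param subbands Optional precomputed list of sub-band-filtered signals
#'   (`length(bank$bands)` matrices shaped like `X`); lets sliding detection
#'   filter a whole epoch once.
#' @param template Optional pre-built `reference_template`.
#' @return Object of class `fbcca_score`: `rho_tilde`, `rho_per_band`,
#'   `weights`.
#' @export
fbcca_score <- function(X, f, bank = filter_bank_spec(), Nh = 4, fs = 256,
                        subbands = NULL, template = NULL) {
  if (is.null(template)) {
    template <- suppressMessages(build_reference(f, Nh, fs, ncol(X)))
  }
  if (is.null(subbands)) {
    filters <- design_filter_bank(bank, fs)
    subbands <- lapply(filters, function(fl) apply_bank_filter(fl, X))
  }
  rho <- vapply(subbands,
                function(Xj) canonical_correlation(Xj, template$Y)$rho,
                numeric(1))
  structure(
    list(rho_tilde = sum(bank$weights * rho^2), rho_per_band = rho,
         weights = bank$weights),
    class = "fbcca_score"
  )
}

#' FBCCA frequency detection on one epoch window
#'
#' @inheritParams fbcca_score
#' @param stimulus A [stimulus_spec()] with the candidate frequencies.
#' @param templates Optional pre-built template list (see [cca_detect()]).
#' @return List with `frequency` and `scores` (the combined
#'   `rho_tilde` per candidate).
#' @export
fbcca_detect <- function(X, stimulus = stimulus_spec(),
                         bank = filter_bank_spec(), Nh = 4, fs = 256,
                         subbands = NULL, templates = NULL) {
  if (is.null(subbands)) {
    filters <- design_filter_bank(bank, fs)
    subbands <- lapply(filters, function(fl) apply_bank_filter(fl, X))
  }
  if (is.null(templates)) {
    templates <- reference_set(stimulus$frequencies, Nh, fs, ncol(X))
  }
  scores <- vapply(seq_along(templates), function(i) {
    fbcca_score(X, stimulus$frequencies[i], bank, Nh, fs,
                subbands = subbands, template = templates[[i]])$rho_tilde
  }, numeric(1))
  names(scores) <- signif(stimulus$frequencies, 8)
  pick_argmax(stimulus$frequencies, scores)
}
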