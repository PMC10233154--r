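#' Sinusoidal reference template for one candidate frequency
#'
#' Builds the 2*Nh x Nt harmonic reference matrix whose rows alternate
#' `sin(2*pi*k*f*t)` and `cos(2*pi*k*f*t)` for harmonics `k = 1..Nh`,
#' evaluated at `t = n/fs`, `n = 0..Nt-1`. Harmonics at or above Nyquist are
#' dropped (reported via a message).
#'
#' @param f Candidate frequency in Hz (> 0).
#' @param Nh Number of harmonics.
#' @param fs Sampling rate in Hz.
#' @param Nt Number of samples.
#' @return Object of class `reference_template` with fields `Y` (matrix),
#'   `f`, `Nh` (harmonics kept), `fs`.
#' @export
build_reference <- function(f, Nh = 4, fs = 256, Nt) {
  if (f <= 0) stop("f must be positive", call. = FALSE)
  keep <- which(seq_len(Nh) * f < fs / 2)
  if (length(keep) == 0) {
    stop("no harmonic of f = ", f, " Hz lies below Nyquist", call. = FALSE)
  }
  if (length(keep) < Nh) {
    message("build_reference: dropping ", Nh - length(keep),
            " harmonic(s) at or above Nyquist for f = ", f, " Hz")
  }
  t <- (seq_len(Nt) - 1) / fs
  Y <- matrix(0, 2 * length(keep), Nt)
  for (i in seq_along(keep)) {
    k <- keep[i]
    Y[2 * i - 1, ] <- sin(2 * pi * k * f * t)
    Y[2 * i, ] <- cos(2 * pi * k * f * t)
  }
  structure(list(Y = Y, f = f, Nh = length(keep), fs = fs),
            class = "reference_template")
}

#' Maximum canonical correlation between a signal and a template
#'
#' Centers both row sets, forms the cross- and auto-covariance matrices and
#' solves the generalized eigenvalue problem
#' `Cpp^-1 Cpq Cqq^-1 Cqp w_p = rho^2 w_p`. A small ridge
#' (`ridge * trace/dim * I`) stabilizes the auto-covariance inverses.
#'
#' @param X Ne x Nt signal matrix.
#' @param Y 2*Nh x Nt reference matrix (or a `reference_template`).
#' @param ridge Relative ridge added to the auto-covariances.
#' @return Object of class `cca_result`: `rho` (max canonical correlation),
#'   `w_p` (Ne channel weights), `w_q` (template weights).
#' @export
canonical_correlation <- function(X, Y, ridge = 1e-9) {
  if (inherits(Y, "reference_template")) Y <- Y$Y
  if (ncol(X) != ncol(Y)) stop("X and Y must share Nt", call. = FALSE)
  nt <- ncol(X)
  if (nt <= max(nrow(X), nrow(Y))) {
    stop("need more samples than variables for CCA", call. = FALSE)
  }
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  if (max(abs(Xc)) < 1e-12) {
    stop("degenerate input: signal is constant across time", call. = FALSE)
  }
  cpp <- tcrossprod(Xc) / (nt - 1)
  cqq <- tcrossprod(Yc) / (nt - 1)
  cpq <- tcrossprod(Xc, Yc) / (nt - 1)
  cpp <- cpp + diag(ridge * sum(diag(cpp)) / nrow(cpp), nrow(cpp))
  cqq <- cqq + diag(ridge * sum(diag(cqq)) / nrow(cqq), nrow(cqq))
  m <- tryCatch(
    solve(cpp, cpq %*% solve(cqq, t(cpq))),
    error = function(e) {
      stop("rank-deficient covariance beyond ridge rescue: ",
           conditionMessage(e), call. = FALSE)
    })
  eg <- eigen(m)
  vals <- Re(eg$values)
  i <- which.max(vals)
  rho2 <- max(min(vals[i], 1), 0)
  w_p <- Re(eg$vectors[, i])
  w_q <- drop(solve(cqq, t(cpq)) %*% w_p)
  nq <- sqrt(sum(w_q^2))
  if (nq > 0) w_q <- w_q / nq
  structure(list(rho = sqrt(rho2), w_p = w_p, w_q = w_q),
            class = "cca_result")
}

#' CCA frequency detection on one epoch window
#'
#' Scores every candidate frequency by the maximum canonical correlation
#' between the signal and that frequency's harmonic reference, then picks the
#' argmax. Ties are broken toward the lowest candidate frequency.
#'
#' @param X Ne x Nt signal matrix.
#' @param stimulus A [stimulus_spec()] providing the candidate frequencies.
#' @param Nh Harmonics per reference template.
#' @param fs Sampling rate in Hz.
#' @param templates Optional pre-built list of `reference_template`s matching
#'   `ncol(X)` (a per-window-length cache for sliding detection).
#' @return List with `frequency` (detected, Hz) and `scores` (named vector of
#'   canonical correlations per candidate).
#' @export
cca_detect <- function(X, stimulus = stimulus_spec(), Nh = 4,
                       fs = 256, templates = NULL) {
  if (is.null(templates)) {
    templates <- reference_set(stimulus$frequencies, Nh, fs, ncol(X))
  }
  scores <- vapply(templates,
                   function(tm) canonical_correlation(X, tm$Y)$rho,
                   numeric(1))
  names(scores) <- signif(stimulus$frequencies, 8)
  pick_argmax(stimulus$frequencies, scores)
}

# template cache for a fixed window length
reference_set <- function(frequencies, Nh, fs, Nt) {
  lapply(frequencies, function(f)
    suppressMessages(build_reference(f, Nh, fs, Nt)))
}

# argmax with lowest-frequency tie-break (stable under exact ties)
pick_argmax <- function(frequencies, scores) {
  ord <- order(frequencies)
  best <- ord[which.max(scores[ord])]
  list(frequency = frequencies[best], scores = scores)
}
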