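#' Fit the minimum energy combination model for one candidate frequency
#'
#' Regresses the (row-centered) signal onto the harmonic reference rows by
#' least squares, `G = X Y^T (Y Y^T)^-1`, leaving the non-SSVEP residual
#' `eta = X - G Y`. Spatial filters are the eigenvectors of `M = eta eta^T`
#' with the smallest eigenvalues, scaled to `v_i / sqrt(lambda_i)` so each
#' filtered residual has unit energy. The number of retained filters `Nm` is
#' the smallest count of ascending eigenvalues whose cumulative sum first
#' exceeds `retention * sum(lambda)` (at least 1).
#'
#' @param X Ne x Nt signal matrix.
#' @param f Candidate frequency in Hz.
#' @param Nh Harmonics in the reference template.
#' @param fs Sampling rate in Hz.
#' @param retention Fraction of residual (noise) energy retained by the
#'   selected filters; default 0.10.
#' @param template Optional pre-built `reference_template`.
#' @return Object of class `mec_model`: `G`, `residual`, `eigenvalues`
#'   (ascending), `eigenvectors`, `Nm`, `W` (Ne x Nm spatial filters), `f`,
#'   `Nh`.
#' @export
mec_fit <- function(X, f, Nh = 4, fs = 256, retention = 0.10,
                    template = NULL) {
  if (is.null(template)) {
    template <- suppressMessages(build_reference(f, Nh, fs, ncol(X)))
  }
  Y <- template$Y
  if (ncol(X) <= nrow(Y)) stop("need Nt > 2*Nh samples", call. = FALSE)
  Xc <- X - rowMeans(X)
  G <- Xc %*% t(Y) %*% solve(tcrossprod(Y))
  eta <- Xc - G %*% Y
  M <- tcrossprod(eta)
  eg <- eigen(M, symmetric = TRUE)
  lambda <- rev(eg$values)               # ascending
  V <- eg$vectors[, rev(seq_len(ncol(eg$vectors))), drop = FALSE]
  lambda <- pmax(lambda, 0)
  total <- sum(lambda)
  if (total <= 1e-12 * max(ncol(X), 1)) {
    warning("residual is (near) zero: perfect template fit; using one unit filter",
            call. = FALSE)
    nm <- 1L
    W <- V[, 1, drop = FALSE]
  } else {
    csum <- cumsum(lambda)
    nm <- max(1L, which(csum > retention * total)[1])
    floor_l <- 1e-12 * max(lambda)
    W <- V[, seq_len(nm), drop = FALSE] %*%
      diag(1 / sqrt(pmax(lambda[seq_len(nm)], floor_l)), nm)
  }
  structure(
    list(G = G, residual = eta, eigenvalues = lambda, eigenvectors = V,
         Nm = nm, W = W, f = template$f, Nh = template$Nh),
    class = "mec_model"
  )
}

#' @export
print.mec_model <- function(x, ...) {
  cat("<mec_model> f =", signif(x$f, 6), "Hz,", x$Nh, "harmonics, Nm =",
      x$Nm, "spatial filter(s)\n")
  invisible(x)
}

#' MEC average power score at the model's candidate frequency
#'
#' Projects each spatially filtered channel onto each reference row and
#' averages the squared projections:
#' `p = 1/(Nm*Nh) * sum_i sum_j ( y_j . (X^T w_i) )^2`. The squared form is
#' the established minimum-energy power estimate; `literal = TRUE` instead
#' sums the raw (unsquared) products, which cancel for arbitrary phases and
#' is provided for comparison only.
#'
#' @param X Ne x Nt signal matrix (same window the model was fitted on, or a
#'   new one).
#' @param model A fitted `mec_model`.
#' @param template The `reference_template` for the model's frequency (must
#'   match `model$f`); built on the fly when omitted.
#' @param fs Sampling rate (only used when building the template).
#' @param literal Use the unsquared raw-product form.
#' @return Scalar power score `p`.
#' @export
mec_power <- function(X, model, template = NULL, fs = 256, literal = FALSE) {
  if (is.null(template)) {
    template <- suppressMessages(
      build_reference(model$f, model$Nh, fs, ncol(X)))
  }
  if (abs(template$f - model$f) > 1e-9) {
    stop("template frequency does not match the fitted model", call. = FALSE)
  }
  Xc <- X - rowMeans(X)
  proj <- template$Y %*% crossprod(Xc, model$W)   # (2Nh) x Nm
  if (literal) {
    sum(proj) / (model$Nm * model$Nh)
  } else {
    sum(proj^2) / (model$Nm * model$Nh)
  }
}

#' MEC frequency detection on one epoch window
#'
#' Fits a minimum energy combination model per candidate frequency and picks
#' the frequency with the largest average power score.
#'
#' @inheritParams mec_fit
#' @param stimulus A [stimulus_spec()] with the candidate frequencies.
#' @param templates Optional pre-built template list (see [cca_detect()]).
#' @return List with `frequency` and `scores` (power per candidate).
#' @export
mec_detect <- function(X, stimulus = stimulus_spec(), Nh = 4, fs = 256,
                       retention = 0.10, templates = NULL) {
  if (is.null(templates)) {
    templates <- reference_set(stimulus$frequencies, Nh, fs, ncol(X))
  }
  if (max(abs(X - rowMeans(X))) < 1e-12) {
    stop("degenerate input: signal is constant across time", call. = FALSE)
  }
  scores <- vapply(seq_along(templates), function(i) {
    tm <- templates[[i]]
    mdl <- mec_fit(X, tm$f, tm$Nh, fs, retention, template = tm)
    mec_power(X, mdl, template = tm)
  }, numeric(1))
  names(scores) <- signif(stimulus$frequencies, 8)
  pick_argmax(stimulus$frequencies, scores)
}

#' Uniform detector interface
#'
#' Dispatches to [cca_detect()], [fbcca_detect()] or [mec_detect()] under one
#' signature, the contract shared by all pseudo-online evaluation code:
#' score every candidate frequency, return the argmax and the score vector.
#'
#' @param X Ne x Nt signal matrix.
#' @param stimulus A [stimulus_spec()].
#' @param method `"cca"`, `"fbcca"` or `"mec"`.
#' @param Nh Harmonics per reference template.
#' @param fs Sampling rate in Hz.
#' @param bank Filter bank for FBCCA.
#' @param ... Passed through to the method-specific detector.
#' @return List with `frequency` and `scores`.
#' @export
ssvep_detect <- function(X, stimulus = stimulus_spec(),
                         method = c("cca", "fbcca", "mec"), Nh = 4,
                         fs = 256, bank = filter_bank_spec(), ...) {
  method <- match.arg(method)
  switch(method,
    cca = cca_detect(X, stimulus, Nh, fs, ...),
    fbcca = fbcca_detect(X, stimulus, bank, Nh, fs, ...),
    mec = mec_detect(X, stimulus, Nh, fs, ...)
  )
}
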