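#' Sliding-window configuration for pseudo-online detection
#'
#' @param T_win Window length in seconds (default 1).
#' @param T_shift Window step in seconds (default 0.05).
#' @param consecutive_required Number of consecutive agreeing windows that
#'   fixes the decision (default 3).
#' @return Object of class `window_config`.
#' @export
window_config <- function(T_win = 1.0, T_shift = 0.05,
                          consecutive_required = 3) {
  if (!(T_shift > 0 && T_shift <= T_win)) {
    stop("need 0 < T_shift <= T_win", call. = FALSE)
  }
  if (consecutive_required < 1) {
    stop("consecutive_required must be >= 1", call. = FALSE)
  }
  structure(list(T_win = T_win, T_shift = T_shift,
                 consecutive_required = consecutive_required),
            class = "window_config")
}

#' Pseudo-online sliding-window detection over one epoch
#'
#' Applies a detector to every window `[t, t + T_win)` with `t` running from
#' the epoch start in `T_shift` steps while `t + T_win <= stimulation end`.
#' Windows that end at or before stimulation onset (`t = 0`) are scored but
#' excluded from the agreement counter, so detection time measures post-onset
#' evidence only. The final decision is the first frequency to win
#' `consecutive_required` consecutive post-onset windows; its detection time
#' (DT) is the end time of the last of those windows. If no run of agreeing
#' windows occurs, the trace falls back to the last window's decision with
#' `DT = ` stimulation length and is marked undetected-by-rule.
#'
#' @param ep A `detection`-kind [epoch()] (6 s, `t0 = -1`).
#' @param method Detector name (`"cca"`, `"fbcca"`, `"mec"`), ignored when
#'   `detector_fun` is given.
#' @param cfg A [window_config()].
#' @param stimulus A [stimulus_spec()]; defaults to the candidate set implied
#'   by the epoch's paradigm and package defaults.
#' @param Nh Harmonics per reference template.
#' @param bank Filter bank (FBCCA only).
#' @param stim_end_s End of the stimulation phase relative to onset, seconds.
#' @param detector_fun Optional override: `function(X, t_end)` returning a
#'   frequency; used e.g. for chance-level baselines.
#' @param correct_by_last_window Count a no-agreement fallback trial as
#'   correct when its last-window decision matches the target (default
#'   `FALSE`: such trials count as incorrect).
#' @return Object of class `detection_trace`: `window_end_times`,
#'   `decisions`, `final_frequency`, `DT`, `detected_by_rule`, `correct`,
#'   plus `target_frequency`, `method`, `paradigm`, `trial_index`.
#' @export
sliding_trace <- function(ep, method = c("cca", "fbcca", "mec"),
                          cfg = window_config(),
                          stimulus = NULL, Nh = 4,
                          bank = filter_bank_spec(), stim_end_s = 5,
                          detector_fun = NULL,
                          correct_by_last_window = FALSE) {
  if (!inherits(ep, "eeg_epoch") || ep$kind != "detection") {
    stop("sliding_trace expects a detection-kind epoch", call. = FALSE)
  }
  fs <- ep$fs
  if (is.null(stimulus)) {
    freqs <- if (!is.null(attr(ep, "frequencies"))) attr(ep, "frequencies")
             else stimulation_frequencies()
    par <- if (ep$paradigm %in% PARADIGMS) ep$paradigm else "OOR"
    stimulus <- stimulus_spec(par, freqs)
  }
  n_win_samples <- round(cfg$T_win * fs)
  duration <- ncol(ep$X) / fs
  if (duration < cfg$T_win) {
    stop("epoch shorter than one window", call. = FALSE)
  }
  starts <- seq(ep$t0, stim_end_s - cfg$T_win + 1e-9, by = cfg$T_shift)
  ends <- starts + cfg$T_win

  decide <- detector_fun
  if (is.null(decide)) {
    method <- match.arg(method)
    templates <- reference_set(stimulus$frequencies, Nh, fs, n_win_samples)
    subepoch <- NULL
    if (method == "fbcca") {
      filters <- design_filter_bank(bank, fs)
      subepoch <- lapply(filters, function(fl) apply_bank_filter(fl, ep$X))
    }
    decide <- function(Xw, t_end, iw) {
      switch(method,
        cca = cca_detect(Xw, stimulus, Nh, fs, templates = templates),
        mec = mec_detect(Xw, stimulus, Nh, fs, templates = templates),
        fbcca = {
          sub <- lapply(subepoch, function(S) S[, iw, drop = FALSE])
          fbcca_detect(ep$X[, iw, drop = FALSE], stimulus, bank, Nh, fs,
                       subbands = sub, templates = templates)
        })$frequency
    }
  } else {
    user_fun <- decide
    decide <- function(Xw, t_end, iw) user_fun(Xw, t_end)
  }

  decisions <- numeric(length(starts))
  for (k in seq_along(starts)) {
    i0 <- round((starts[k] - ep$t0) * fs)       # 0-based
    iw <- (i0 + 1):(i0 + n_win_samples)
    decisions[k] <- decide(ep$X[, iw, drop = FALSE], ends[k], iw)
  }

  final <- NA_real_
  dt <- NA_real_
  detected <- FALSE
  run_len <- 0L
  run_freq <- NA_real_
  for (k in seq_along(decisions)) {
    if (ends[k] <= 1e-9) next                    # pre-onset evidence excluded
    if (!is.na(run_freq) && isTRUE(all.equal(decisions[k], run_freq))) {
      run_len <- run_len + 1L
    } else {
      run_freq <- decisions[k]
      run_len <- 1L
    }
    if (run_len >= cfg$consecutive_required) {
      final <- run_freq
      dt <- ends[k]
      detected <- TRUE
      break
    }
  }
  if (!detected) {
    final <- decisions[length(decisions)]
    dt <- stim_end_s
  }
  correct <- if (detected || correct_by_last_window) {
    isTRUE(all.equal(final, ep$target_frequency, tolerance = 1e-6))
  } else FALSE

  structure(
    list(window_end_times = ends, decisions = decisions,
         final_frequency = final, DT = dt, detected_by_rule = detected,
         correct = correct, target_frequency = ep$target_frequency,
         method = if (is.null(detector_fun)) method else "custom",
         paradigm = ep$paradigm, trial_index = ep$trial_index),
    class = "detection_trace"
  )
}

#' @export
print.detection_trace <- function(x, ...) {
  cat("<detection_trace>", length(x$decisions), "windows; final",
      signif(x$final_frequency, 6), "Hz (target",
      signif(x$target_frequency, 6), "Hz ), DT =", x$DT, "s,",
      if (x$correct) "correct" else "incorrect",
      if (!x$detected_by_rule) "(no-agreement fallback)" else "", "\n")
  invisible(x)
}

#' Detection accuracy over a set of traces
#'
#' `DA = N_detects / N_trials`, stratified by (method, paradigm, target
#' frequency). Trials where the consecutive-agreement rule never fired count
#' as incorrect unless their traces were built with
#' `correct_by_last_window = TRUE`.
#'
#' @param traces List of `detection_trace` objects.
#' @param by Stratification columns; use `character(0)` for one pooled row.
#' @return A tibble with the strata, `n_trials`, `n_correct`, `DA`, `DT_mean`
#'   and `DT_sd` (detection times averaged over all trials; see
#'   [run_assessment()] for the detected-only variant).
#' @export
detection_accuracy <- function(traces,
                               by = c("method", "paradigm", "frequency")) {
  if (length(traces) == 0) stop("no traces", call. = FALSE)
  df <- data.frame(
    method = vapply(traces, function(t) as.character(t$method), ""),
    paradigm = vapply(traces, function(t) as.character(t$paradigm), ""),
    frequency = vapply(traces, function(t) t$target_frequency, 0),
    correct = vapply(traces, function(t) t$correct, FALSE),
    DT = vapply(traces, function(t) t$DT, 0)
  )
  if (length(by) == 0) {
    return(tibble::tibble(
      n_trials = nrow(df), n_correct = sum(df$correct),
      DA = mean(df$correct), DT_mean = mean(df$DT), DT_sd = sd(df$DT)))
  }
  sp <- split(df, df[by], drop = TRUE)
  rows <- lapply(sp, function(d) {
    cbind(d[1, by, drop = FALSE],
          data.frame(n_trials = nrow(d), n_correct = sum(d$correct),
                     DA = mean(d$correct), DT_mean = mean(d$DT),
                     DT_sd = if (nrow(d) > 1) sd(d$DT) else NA_real_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tibble::as_tibble(out[order(out$method, out$paradigm, out$frequency), ])
}

#' Information transfer rate (bits per minute)
#'
#' `ITR = s * (log2(N) + DA*log2(DA) + (1-DA)*log2((1-DA)/(N-1)))` with
#' `s = 60/DT` selections per minute. `DA = 1` is handled by the
#' `0*log(0) = 0` limit; accuracies at or below chance (`DA <= 1/N`) return
#' 0, as the formula turns negative there.
#'
#' @param DA Detection accuracy as a fraction in `[0, 1]` (vectorized).
#' @param DT Detection time per selection, seconds (> 0; vectorized).
#' @param N Number of selectable targets (>= 2).
#' @return ITR in bits per minute.
#' @examples
#' itr(1, 60)        # log2(5) bits/min
#' itr(0.5, 60)      # 0.3219 bits/min
#' @export
itr <- function(DA, DT, N = 5) {
  if (any(DT <= 0)) stop("DT must be positive", call. = FALSE)
  if (any(DA < 0 | DA > 1)) stop("DA must lie in [0, 1]", call. = FALSE)
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  bits <- log2(N) +
    ifelse(DA > 0, DA * log2(pmax(DA, .Machine$double.xmin)), 0) +
    ifelse(DA < 1, (1 - DA) * log2((1 - DA) / (N - 1)), 0)
  out <- (60 / DT) * bits
  out[DA <= 1 / N] <- 0
  pmax(out, 0)
}

#' Cross-condition comparison of a performance metric
#'
#' Kruskal-Wallis omnibus test across condition groups followed by pairwise
#' rank-sum tests with family-wise (Holm) correction, reporting the
#' significance tier (0.001 / 0.01 / 0.05) of each pair.
#'
#' @param metric_samples Named list of numeric vectors, one per condition
#'   (>= 2 groups, each with >= 2 values).
#' @param alpha Family-wise significance level.
#' @return Object of class `condition_comparison`: `H`, `df`, `p_omnibus`,
#'   `pairwise` (tibble with `group1`, `group2`, `p_adj`, `tier`,
#'   `significant`), `alpha`, `adjust`.
#' @export
compare_conditions <- function(metric_samples, alpha = 0.05) {
  if (length(metric_samples) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(metric_samples, length, 0L) < 2)) {
    stop("every group needs >= 2 samples", call. = FALSE)
  }
  all_vals <- unlist(metric_samples)
  if (length(unique(all_vals)) < 2) {
    stop("degenerate groups: all values identical, rank test undefined",
         call. = FALSE)
  }
  if (is.null(names(metric_samples))) {
    names(metric_samples) <- paste0("group", seq_along(metric_samples))
  }
  kw <- kruskal.test(metric_samples)
  gn <- names(metric_samples)
  pairs <- utils::combn(gn, 2)
  praw <- apply(pairs, 2, function(pr) {
    suppressWarnings(
      wilcox.test(metric_samples[[pr[1]]], metric_samples[[pr[2]]],
                  exact = FALSE)$p.value)
  })
  padj <- p.adjust(praw, method = "holm")
  tier <- ifelse(padj <= 0.001, "p<=0.001",
                 ifelse(padj <= 0.01, "p<=0.01",
                        ifelse(padj <= alpha, paste0("p<=", alpha), "ns")))
  structure(
    list(H = unname(kw$statistic), df = unname(kw$parameter),
         p_omnibus = kw$p.value,
         pairwise = tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                                   p_raw = praw, p_adj = padj, tier = tier,
                                   significant = padj <= alpha),
         alpha = alpha, adjust = "holm"),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison> Kruskal-Wallis H =", signif(x$H, 4), ", df =",
      x$df, ", p =", signif(x$p_omnibus, 3), "\n")
  cat("  pairwise (", x$adjust, "-corrected, alpha = ", x$alpha, "):\n",
      sep = "")
  print(as.data.frame(x$pairwise))
  invisible(x)
}

#' Full factorial pseudo-online assessment
#'
#' Runs the sliding-window detection over every detection epoch of every
#' recording with every requested method, and tabulates detection accuracy,
#' detection time and information transfer rate per (method, paradigm,
#' frequency) cell.
#'
#' @param recordings List of `eeg_recording` objects (e.g. one per paradigm
#'   from [generate_session()]).
#' @param methods Detector names to assess.
#' @param cfg A [window_config()].
#' @param Nh Harmonics per reference template.
#' @param bank Filter bank for FBCCA.
#' @param dt_mode `"all"` averages detection time over every trial (the
#'   no-agreement fallback contributing the full stimulation length);
#'   `"detected"` averages over rule-detected trials only.
#' @param preprocess_first Apply the default band-pass + notch
#'   [preprocess()] before epoching.
#' @return A `metrics_table` tibble with columns `method`, `paradigm`,
#'   `frequency`, `n_trials`, `n_correct`, `DA`, `DT_mean`, `DT_sd`, `ITR`.
#' @export
run_assessment <- function(recordings, methods = c("cca", "fbcca", "mec"),
                           cfg = window_config(), Nh = 4,
                           bank = filter_bank_spec(),
                           dt_mode = c("all", "detected"),
                           preprocess_first = TRUE) {
  dt_mode <- match.arg(dt_mode)
  methods <- match.arg(methods, c("cca", "fbcca", "mec"), several.ok = TRUE)
  traces <- list()
  for (rec in recordings) {
    use <- if (preprocess_first) preprocess(rec) else rec
    eps <- extract_epochs(use, "detection")
    stim <- stimulus_spec(rec$paradigm, rec$frequencies)
    for (m in methods) {
      for (ep in eps) {
        traces[[length(traces) + 1]] <-
          sliding_trace(ep, m, cfg, stimulus = stim, Nh = Nh, bank = bank)
      }
    }
  }
  summarize_traces(traces, dt_mode = dt_mode)
}

#' Summarize detection traces into a metrics table
#'
#' @param traces List of `detection_trace` objects.
#' @param dt_mode See [run_assessment()].
#' @param N Number of targets used in the ITR formula; default = number of
#'   distinct target frequencies present.
#' @return A `metrics_table` tibble.
#' @export
summarize_traces <- function(traces, dt_mode = c("all", "detected"), N = NULL) {
  dt_mode <- match.arg(dt_mode)
  if (is.null(N)) {
    N <- length(unique(vapply(traces, function(t) t$target_frequency, 0)))
    N <- max(N, 2)
  }
  tab <- detection_accuracy(traces)
  if (dt_mode == "detected") {
    key <- function(t) paste(t$method, t$paradigm,
                             signif(t$target_frequency, 8))
    det <- Filter(function(t) t$detected_by_rule, traces)
    dts <- split(vapply(det, function(t) t$DT, 0),
                 vapply(det, key, ""))
    tk <- paste(tab$method, tab$paradigm, signif(tab$frequency, 8))
    tab$DT_mean <- vapply(tk, function(k) {
      v <- dts[[k]]
      if (is.null(v)) NA_real_ else mean(v)
    }, 0)
    tab$DT_sd <- vapply(tk, function(k) {
      v <- dts[[k]]
      if (is.null(v) || length(v) < 2) NA_real_ else sd(v)
    }, 0)
  }
  tab$ITR <- ifelse(is.na(tab$DT_mean) | tab$DT_mean <= 0, 0,
                    itr(tab$DA, pmax(tab$DT_mean, 1e-9), N))
  class(tab) <- c("metrics_table", class(tab))
  tab
}
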