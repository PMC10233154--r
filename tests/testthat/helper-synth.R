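# shared fixtures and independent oracles, built in code at test time

# independent canonical-correlation oracle: orthonormal bases via QR, then
# the largest singular value of the cross-product of the bases
oracle_cca_rho <- function(X, Y) {
  Xc <- t(X - rowMeans(X))
  Yc <- t(Y - rowMeans(Y))
  Qx <- qr.Q(qr(Xc))
  Qy <- qr.Q(qr(Yc))
  max(svd(crossprod(Qx, Qy))$d)
}

# one stimulation-phase signal matrix at frequency index ti (0-based)
make_stim_matrix <- function(cfg, stim, ti, seed, timing = trial_timing()) {
  tr <- generate_trial(cfg, stim, timing, ti, seed = seed)
  on <- (timing$fixation_s + timing$target_s + timing$preparation_s) * cfg$fs
  tr$data[, (on + 1):(on + timing$stimulation_s * cfg$fs), drop = FALSE]
}

# one 6-s detection epoch (1 s pre-onset) at frequency index ti
make_detection_epoch <- function(cfg, stim, ti, seed,
                                 timing = trial_timing()) {
  tr <- generate_trial(cfg, stim, timing, ti, seed = seed)
  on <- (timing$fixation_s + timing$target_s + timing$preparation_s) * cfg$fs
  epoch(tr$data[, (on - cfg$fs + 1):(on + timing$stimulation_s * cfg$fs),
                drop = FALSE],
        cfg$fs, -1, "detection", stim$frequencies[ti + 1], stim$paradigm, ti)
}

# trial-level detection accuracy over n trials cycling through all targets
trial_level_da <- function(method, snr_db, n_trials, seed_base,
                           paradigm = "OOR", config_seed = 77) {
  stim <- stimulus_spec(paradigm)
  cfg <- synthetic_config(seed = config_seed, target_snr_db = snr_db)
  ok <- 0L
  for (i in seq_len(n_trials)) {
    ti <- (i - 1) %% stim$n_targets
    X <- make_stim_matrix(cfg, stim, ti, seed = seed_base + i)
    d <- ssvep_detect(X, stim, method)
    ok <- ok + (abs(d$frequency - stim$frequencies[ti + 1]) < 1e-6)
  }
  ok / n_trials
}

# binomial 95% acceptance interval for an observed proportion
binom_ci <- function(p, n) {
  c(qbinom(0.025, n, p), qbinom(0.975, n, p)) / n
}
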