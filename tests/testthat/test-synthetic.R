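test_that("background noise is deterministic, zero-mean, and shaped", {
  cfg <- synthetic_config(seed = 5)
  a <- gen_background(cfg, 2)
  b <- gen_background(cfg, 2)
  expect_identical(a, b)
  expect_equal(dim(a), c(8, 512))
  expect_true(all(abs(rowMeans(a)) < 1e-8))
  expect_error(gen_background(cfg, 0), "positive")

  # white-noise limit: gamma = 0, no alpha -> flat log-log periodogram
  cfg_w <- synthetic_config(seed = 6, noise_gamma = 0, alpha_amp = 0)
  x <- gen_background(cfg_w, 60)[1, ]
  sp <- stats::spec.pgram(x, taper = 0, plot = FALSE)
  f_hz <- sp$freq * cfg_w$fs
  sel <- f_hz >= 2 & f_hz <= 40
  slope_w <- unname(coef(lm(log10(sp$spec[sel]) ~ log10(f_hz[sel])))[2])
  expect_lt(abs(slope_w), 0.2)

  # pink noise: gamma = 1 -> slope about -1 over 2-40 Hz
  cfg_p <- synthetic_config(seed = 7, noise_gamma = 1, alpha_amp = 0)
  xp <- gen_background(cfg_p, 60)[1, ]
  spp <- stats::spec.pgram(xp, taper = 0, plot = FALSE)
  f_hz <- spp$freq * cfg_p$fs
  sel <- f_hz >= 2 & f_hz <= 40
  slope_p <- unname(coef(lm(log10(spp$spec[sel]) ~ log10(f_hz[sel])))[2])
  expect_lt(abs(slope_p - (-1)), 0.2)
})

test_that("evoked component matches its closed form", {
  # single unit-amplitude harmonic, zero phase: RMS = 1/sqrt(2) over whole
  # cycles
  cfg <- synthetic_config(n_harmonics = 1,
                          harmonic_amplitudes = matrix(1, 8, 1),
                          target_snr_db = NULL)
  ev <- gen_evoked(cfg, 16, 1, "OOR")   # 16 cycles in 1 s
  expect_equal(sqrt(mean(ev[1, ]^2)), 1 / sqrt(2), tolerance = 1e-3)
  t <- (0:255) / 256
  expect_equal(ev[1, ], sin(2 * pi * 16 * t), tolerance = 1e-12)

  # all four harmonics of 24 Hz stay below Nyquist and appear in the FFT
  cfg4 <- synthetic_config(target_snr_db = NULL)
  ev4 <- gen_evoked(cfg4, 24, 2, "OOR")
  sp <- Mod(fft(ev4["Oz", ]))[1:512]
  f_grid <- (0:511) * 256 / 512
  peaks <- f_grid[sp > max(sp) * 0.05]
  for (h in c(24, 48, 72, 96)) expect_true(any(abs(peaks - h) < 0.5))

  # paradigm gain linearity: CBR amplitude = (1/3) x OOR
  ev_oo <- gen_evoked(cfg4, 15, 1, "OOR")
  ev_cb <- gen_evoked(cfg4, 15, 1, "CBR")
  expect_equal(sd(ev_cb[1, ]) / sd(ev_oo[1, ]), 1 / 3, tolerance = 1e-9)

  expect_error(gen_evoked(cfg4, 200, 1), "Nyquist")
  expect_error(gen_evoked(cfg4, -1, 1), "positive")
  # harmonics above Nyquist are truncated with a note, never aliased
  expect_message(gen_evoked(cfg4, 40, 1), "dropping")
})

test_that("trials carry the five phase markers and confine the response", {
  cfg <- synthetic_config(seed = 2)
  tr <- generate_trial(cfg, stimulus_spec(), trial_timing(), 3, seed = 9)
  expect_equal(tr$markers$sample, round(c(0, 2, 4, 5, 10) * 256))
  expect_equal(tr$markers$code, 1:5)
  expect_equal(tr$markers$payload[2], 3L)
  expect_equal(ncol(tr$data), 15 * 256)

  # zero noise: signal is exactly zero outside the stimulation interval
  cfg0 <- synthetic_config(noise_rms = 0, alpha_amp = 0,
                           target_snr_db = NULL)
  tr0 <- generate_trial(cfg0, stimulus_spec(), trial_timing(), 0)
  stim_idx <- (5 * 256 + 1):(10 * 256)
  expect_true(all(tr0$data[, -stim_idx] == 0))
  expect_gt(max(abs(tr0$data[, stim_idx])), 0)

  expect_error(generate_trial(cfg, target_index = 5), "target_index")
  expect_error(generate_trial(cfg, target_index = -1), "target_index")
})

test_that("stimulation segments attain the requested wide-band SNR", {
  cfg <- synthetic_config(seed = 31, target_snr_db = 0)
  stim <- stimulus_spec("OOR")
  snrs <- vapply(1:20, function(i) {
    ti <- (i - 1) %% 5
    X <- make_stim_matrix(cfg, stim, ti, seed = 400 + i)
    f <- stim$frequencies[ti + 1]
    wideband_snr(compute_psd(epoch(X, 256, 0, "stimulation", f)), f)$mean_db
  }, numeric(1))
  expect_lt(abs(mean(snrs) - 0), 2)
})

test_that("measured SNR grows monotonically with the evoked amplitude", {
  stim <- stimulus_spec("OOR")
  mean_snr <- vapply(c(0.5, 1, 2, 4), function(amp) {
    cfg <- synthetic_config(seed = 13, target_snr_db = NULL,
                            harmonic_amplitudes = amp * outer(rep(1, 8),
                                                              1 / (1:4)))
    mean(vapply(1:20, function(i) {
      X <- make_stim_matrix(cfg, stim, 2, seed = 600 + i)
      wideband_snr(compute_psd(epoch(X, 256, 0, "stimulation", 15)),
                   15)$mean_db
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_snr) > 0))
})

test_that("sessions have the run/trial layout with balanced seeded orders", {
  cfg <- synthetic_config(seed = 8)
  ses <- generate_session(cfg, trials_per_frequency = 1,
                          paradigms = c("OOR", "CBR"))
  expect_named(ses, c("OOR", "CBR"))
  rec <- ses$OOR
  expect_equal(ncol(rec$data), 5 * 15 * 256)
  expect_equal(nrow(rec$markers), 25)
  targets <- rec$markers$payload[rec$markers$code == 2]
  expect_setequal(targets, 0:4)

  # balanced counts at the default 8 trials per frequency
  ses8 <- generate_session(synthetic_config(seed = 9, noise_rms = 1,
                                            alpha_amp = 0),
                           trials_per_frequency = 2, paradigms = "OOS")
  tg <- ses8$OOS$markers$payload[ses8$OOS$markers$code == 2]
  expect_equal(as.vector(table(tg)), rep(2L, 5))

  # determinism: identical seed, identical recordings
  ses_b <- generate_session(cfg, trials_per_frequency = 1,
                            paradigms = c("OOR", "CBR"))
  expect_identical(ses$OOR$data, ses_b$OOR$data)
  expect_identical(ses$CBR$markers, ses_b$CBR$markers)

  expect_error(generate_session(cfg, trials_per_frequency = 0), ">= 1")
})

test_that("marker labels agree with the injected frequency (spectral truth)", {
  cfg <- synthetic_config(seed = 17, target_snr_db = 0)
  ses <- generate_session(cfg, trials_per_frequency = 2, paradigms = "OOR")
  eps <- extract_epochs(ses$OOR, "stimulation")
  hits <- vapply(eps, function(ep) {
    psd <- compute_psd(ep)
    peak <- psd$freqs[which.max(psd$power["Oz", ])]
    abs(peak - psd$freqs[which.min(abs(psd$freqs - ep$target_frequency))]) <
      1e-9
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
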