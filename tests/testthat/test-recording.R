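make_test_recording <- function(seed = 4, trials_per_frequency = 1,
                                paradigm = "OOR") {
  cfg <- synthetic_config(seed = seed)
  generate_session(cfg, trials_per_frequency = trials_per_frequency,
                   paradigms = paradigm)[[paradigm]]
}

test_that("recordings survive a write/read round trip", {
  rec <- make_test_recording()
  path <- file.path(withr::local_tempdir(), "run_OOR")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$channel_names, rec$channel_names)
  expect_equal(back$markers$sample, rec$markers$sample)
  expect_equal(back$markers$code, rec$markers$code)
  expect_equal(back$markers$payload, rec$markers$payload)
  expect_equal(back$paradigm, rec$paradigm)
  expect_equal(back$frequencies, rec$frequencies)
})

test_that("a full run carries five markers per trial", {
  rec <- make_test_recording(seed = 6, trials_per_frequency = 2)
  expect_equal(nrow(rec$markers), 5 * 10)
  expect_false(is.unsorted(rec$markers$sample))
})

test_that("degenerate and corrupt files are handled explicitly", {
  dir <- withr::local_tempdir()
  # empty marker list round-trips
  rec <- recording(matrix(rnorm(2 * 100), 2), 256, c("Oz", "O2"))
  p0 <- file.path(dir, "nomark")
  write_recording(rec, p0)
  expect_equal(nrow(read_recording(p0)$markers), 0)

  expect_error(read_recording(file.path(dir, "absent")), "no recording")

  # truncated data file: format error, not silent corruption
  p1 <- file.path(dir, "trunc")
  write_recording(rec, p1)
  txt <- readLines(paste0(p1, ".tsv"))
  writeLines(c(txt[1:5], "not a number\tstill not"), paste0(p1, ".tsv"))
  expect_error(read_recording(p1), "corrupt|scan")

  # foreign sidecar dialect
  p2 <- file.path(dir, "foreign")
  write_recording(rec, p2)
  jsonlite::write_json(list(format = "other"), paste0(p2, ".json"),
                       auto_unbox = TRUE)
  expect_error(read_recording(p2), "dialect")
})

test_that("recording validation enforces the container invariants", {
  expect_error(recording(matrix(0, 2, 10), 256, "Oz"), "mismatch")
  bad_m <- data.frame(sample = c(5L, 2L), code = c(1L, 2L),
                      payload = c(NA, 1L))
  expect_error(recording(matrix(0, 1, 10), 256, "Oz", bad_m),
               "non-decreasing")
  out_m <- data.frame(sample = 50L, code = 1L, payload = NA_integer_)
  expect_error(recording(matrix(0, 1, 10), 256, "Oz", out_m), "inside")
})

test_that("preprocessing attenuates out-of-band and preserves in-band", {
  fs <- 256
  t <- (0:(10 * fs - 1)) / fs
  mk <- function(f) recording(matrix(sin(2 * pi * f * t), 1), fs, "Oz")
  mid <- (2 * fs):(8 * fs)   # interior, away from filter edges

  r80 <- preprocess(mk(80))
  expect_lt(20 * log10(sd(r80$data[1, mid]) / (1 / sqrt(2))), -20)

  r15 <- preprocess(mk(15))
  expect_lt(abs(sd(r15$data[1, mid]) / (1 / sqrt(2)) - 1), 0.05)

  r60 <- preprocess(mk(60))
  expect_lt(20 * log10(sd(r60$data[1, mid]) / (1 / sqrt(2))), -20)

  # idempotence in the passband: filtering twice changes RMS by < 1%
  once <- preprocess(mk(15))
  twice <- preprocess(once)
  expect_lt(abs(sd(twice$data[1, mid]) / sd(once$data[1, mid]) - 1), 0.01)

  # markers pass through untouched
  rec <- make_test_recording(seed = 11)
  expect_identical(preprocess(rec)$markers, rec$markers)

  expect_error(preprocess(mk(15), band = c(0, 60)), "band")
  expect_error(preprocess(mk(15), band = c(10, 200)), "band")
})

test_that("epoch extraction yields the three epoch kinds of the protocol", {
  rec <- make_test_recording(seed = 12, trials_per_frequency = 2)

  stim <- extract_epochs(rec, "stimulation")
  expect_length(stim, 10)
  expect_true(all(vapply(stim, function(e) ncol(e$X), 0) == 5 * 256))
  expect_true(all(vapply(stim, function(e) e$t0, 0) == 0))

  det <- extract_epochs(rec, "detection")
  expect_true(all(vapply(det, function(e) ncol(e$X), 0) == 6 * 256))
  expect_true(all(vapply(det, function(e) e$t0, 0) == -1))

  nos <- extract_epochs(rec, "no_stimulation")
  expect_true(all(vapply(nos, function(e) ncol(e$X), 0) == 5 * 256))

  # no_stimulation epoch is exactly the 5 s preceding stimulation onset
  onset <- rec$markers$sample[rec$markers$code == 4][1]
  expect_equal(nos[[1]]$X,
               rec$data[, (onset - 5 * 256 + 1):onset, drop = FALSE])

  # target frequencies come from the marker payloads
  payloads <- rec$markers$payload[rec$markers$code == 2]
  expect_equal(vapply(stim, function(e) e$target_frequency, 0),
               rec$frequencies[payloads + 1])

  # a trial with a missing stimulation marker is skipped with a warning
  broken <- rec
  drop_row <- which(broken$markers$code == 4)[1]
  broken$markers <- broken$markers[-drop_row, ]
  expect_warning(eps <- extract_epochs(broken, "stimulation"), "skipped")
  expect_length(eps, 9)
})

test_that("the pipeline honors a non-default sampling rate", {
  cfg <- synthetic_config(fs = 512, seed = 19, target_snr_db = 0)
  ses <- generate_session(cfg, trials_per_frequency = 1, paradigms = "OOR")
  rec <- ses$OOR
  expect_equal(ncol(rec$data), 5 * 15 * 512)
  eps <- extract_epochs(rec, "stimulation")
  expect_equal(ncol(eps[[1]]$X), 5 * 512)
  stimsp <- stimulus_spec("OOR")
  hits <- vapply(eps, function(e) {
    d <- cca_detect(e$X, stimsp, Nh = 4, fs = rec$fs)
    abs(d$frequency - e$target_frequency) < 1e-6
  }, logical(1))
  expect_gte(mean(hits), 0.8)    # well above the 0.2 chance level
})
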