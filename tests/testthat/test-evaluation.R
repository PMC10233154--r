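noise_detection_epoch <- function(seed, target = 15, paradigm = "OOR") {
  cfg <- synthetic_config(seed = seed, noise_rms = 1, alpha_amp = 0)
  epoch(gen_background(cfg, 6, seed = seed), 256, -1, "detection", target,
        paradigm, 1)
}

test_that("sliding windows and the consecutive-agreement rule behave", {
  ep <- noise_detection_epoch(101)
  cfg <- window_config()

  # 101 windows: t = -1.00, -0.95, ..., 4.00
  trc <- sliding_trace(ep, detector_fun = function(X, t_end) 15)
  expect_length(trc$decisions, 101)
  expect_equal(trc$window_end_times[1], 0)
  expect_equal(trc$window_end_times[101], 5)

  # constant detector: first three post-onset windows end at .05/.10/.15
  expect_equal(trc$DT, 0.15)
  expect_true(trc$detected_by_rule)
  expect_true(trc$correct)

  # consecutive_required = 1: DT is the first post-onset window's end
  trc1 <- sliding_trace(ep, cfg = window_config(consecutive_required = 1),
                        detector_fun = function(X, t_end) 15)
  expect_equal(trc1$DT, 0.05)

  # scripted decisions: agreement starting only late in the epoch
  script <- function() {
    k <- 0
    function(X, t_end) {
      k <<- k + 1
      if (k <= 40) c(10.90909, 8.571429)[1 + k %% 2] else 15
    }
  }
  trc2 <- sliding_trace(ep, detector_fun = script())
  # agreement starts at window 41; windows 41-43 end at 2.00/2.05/2.10
  expect_equal(trc2$DT, 2.10, tolerance = 1e-9)
  expect_equal(trc2$final_frequency, 15)

  # never three in a row: fallback to last decision, DT = 5, incorrect
  flip <- function() {
    k <- 0
    function(X, t_end) { k <<- k + 1; c(15, 20)[1 + k %% 2] }
  }
  trc3 <- sliding_trace(ep, detector_fun = flip())
  expect_false(trc3$detected_by_rule)
  expect_equal(trc3$DT, 5)
  expect_false(trc3$correct)

  # the fallback can optionally credit a correct last window
  trc4 <- sliding_trace(ep, detector_fun = flip(),
                        correct_by_last_window = TRUE)
  expect_equal(trc4$correct,
               isTRUE(all.equal(trc4$final_frequency, 15, tolerance = 1e-6)))

  # window count formula for other shift values
  trc5 <- sliding_trace(ep, cfg = window_config(T_shift = 0.25),
                        detector_fun = function(X, t_end) 15)
  expect_length(trc5$decisions, floor((6 - 1) / 0.25) + 1)

  expect_error(sliding_trace(epoch(ep$X, 256, 0, "stimulation", 15),
                             detector_fun = function(X, t) 15),
               "detection-kind")
  expect_error(window_config(T_shift = 0), "T_shift")
  expect_error(window_config(consecutive_required = 0), ">= 1")
})

test_that("detection accuracy counts correct trials per stratum", {
  mk <- function(correct, dt = 1, m = "cca", p = "OOR", f = 15) {
    structure(list(final_frequency = if (correct) f else f + 1, DT = dt,
                   detected_by_rule = TRUE, correct = correct,
                   target_frequency = f, method = m, paradigm = p,
                   trial_index = 1),
              class = "detection_trace")
  }
  tr8 <- c(lapply(1:5, function(i) mk(TRUE)), lapply(1:3, function(i)
    mk(FALSE)))
  tab <- detection_accuracy(tr8)
  expect_equal(tab$DA, 0.625)
  expect_equal(tab$n_trials, 8)

  all_ok <- lapply(1:4, function(i) mk(TRUE))
  expect_equal(detection_accuracy(all_ok)$DA, 1)

  # pooled DA equals the trial-weighted mean of the stratum DAs
  mixed <- c(lapply(1:6, function(i) mk(TRUE, f = 15)),
             lapply(1:2, function(i) mk(FALSE, f = 15)),
             lapply(1:1, function(i) mk(TRUE, f = 20)),
             lapply(1:3, function(i) mk(FALSE, f = 20)))
  strat <- detection_accuracy(mixed)
  pooled <- detection_accuracy(mixed, by = character(0))
  expect_equal(pooled$DA,
               sum(strat$DA * strat$n_trials) / sum(strat$n_trials))
})

test_that("ITR matches its closed forms and monotonicities", {
  expect_equal(itr(1, 60, 5), log2(5), tolerance = 1e-12)
  expect_equal(itr(0.2, 60, 5), 0)
  expect_equal(itr(0.15, 60, 5), 0)      # below chance clamps to zero
  expect_equal(itr(0.5, 60, 5), 0.3219, tolerance = 1e-4)
  expect_equal(itr(1, 1, 5), 60 * log2(5), tolerance = 1e-9)

  da_grid <- seq(0.25, 1, by = 0.05)
  expect_true(all(diff(itr(da_grid, 2, 5)) > 0))
  dt_grid <- seq(0.5, 5, by = 0.5)
  expect_true(all(diff(itr(0.9, dt_grid, 5)) < 0))

  expect_error(itr(0.5, 0), "DT")
  expect_error(itr(1.2, 1), "DA")
  expect_error(itr(0.5, 1, N = 1), "N")
})

test_that("condition comparison flags real differences and rejects degenerate input", {
  set.seed(105)
  groups <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20) + 3,
                 d = rnorm(20) + 3)
  rep <- compare_conditions(groups)
  expect_lt(rep$p_omnibus, 0.01)
  pw <- rep$pairwise
  key <- function(g1, g2) pw$significant[pw$group1 == g1 & pw$group2 == g2]
  expect_true(key("a", "c"))
  expect_true(key("b", "d"))
  expect_false(key("a", "b"))
  expect_false(key("c", "d"))

  expect_error(compare_conditions(list(a = 1:5)), ">= 2 groups")
  expect_error(compare_conditions(list(a = 1:5, b = 2)), ">= 2 samples")
  expect_error(compare_conditions(list(a = rep(1, 5), b = rep(1, 5))),
               "degenerate")
})

test_that("the full assessment grid is complete and deterministic", {
  cfg <- synthetic_config(seed = 67, target_snr_db = 0)
  ses <- generate_session(cfg, trials_per_frequency = 1,
                          paradigms = c("OOR", "CBR"))
  wcfg <- window_config(T_shift = 0.5)
  tab <- run_assessment(ses, methods = c("cca", "mec"), cfg = wcfg,
                        preprocess_first = FALSE)
  expect_s3_class(tab, "metrics_table")
  expect_equal(nrow(tab), 2 * 2 * 5)
  expect_true(all(tab$DA >= 0 & tab$DA <= 1))
  expect_true(all(tab$ITR >= 0))
  expect_true(all(tab$DT_mean > 0 & tab$DT_mean <= 5))

  tab2 <- run_assessment(ses, methods = c("cca", "mec"), cfg = wcfg,
                         preprocess_first = FALSE)
  expect_identical(tab, tab2)

  # detected-only DT mode reports NA where the rule never fired
  undetected <- structure(
    list(final_frequency = 15, DT = 5, detected_by_rule = FALSE,
         correct = FALSE, target_frequency = 15, method = "cca",
         paradigm = "OOR", trial_index = 1),
    class = "detection_trace")
  tabd <- summarize_traces(list(undetected, undetected),
                           dt_mode = "detected")
  expect_true(is.na(tabd$DT_mean[1]))
})
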