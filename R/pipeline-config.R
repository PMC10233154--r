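#' Default pipeline configuration
#'
#' Nested configuration covering every stage: synthetic session generation,
#' stimulus layout, trial timing, preprocessing, the FBCCA filter bank, the
#' sliding-window rule, the method list and the master seed. All defaults
#' reproduce the standard study parameters (256 Hz, 8 occipital channels,
#' Nh = 4, 1-s windows shifted by 0.05 s, bands 6/9/13/18/22-90 Hz).
#'
#' @return A named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    seed = 1L,
    methods = c("cca", "fbcca", "mec"),
    paradigms = PARADIGMS,
    trials_per_frequency = 8L,
    synthetic = list(
      fs = 256, channels = DEFAULT_CHANNELS, n_harmonics = 4,
      noise_gamma = 1, noise_rms = 10, alpha_amp = 2,
      target_snr_db = 0
    ),
    stimulus = list(
      refresh_hz = 240, frame_divisors = c(28, 22, 16, 12, 10)
    ),
    timing = list(
      fixation_s = 2, target_s = 2, preparation_s = 1,
      stimulation_s = 5, rest_s = 5
    ),
    preprocessing = list(band = c(0.5, 60), notch = 60),
    filter_bank = list(
      low_edges = c(6, 9, 13, 18, 22), high_edge = 90,
      a = 1.25, b = 0.25, order = 4, ripple_db = 0.2
    ),
    window = list(T_win = 1.0, T_shift = 0.05, consecutive_required = 3)
  ), class = "pipeline_config")
}

#' Load and validate a pipeline configuration file
#'
#' Reads a JSON or YAML file, fills every omitted field with the defaults of
#' [default_pipeline_config()], and rejects unknown keys (with a suggestion
#' when a close match exists). An empty file yields the all-defaults
#' configuration.
#'
#' @param path Path to a `.json`, `.yaml`/`.yml` file, or `NULL` for pure
#'   defaults.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_pipeline_config()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw) || length(raw) == 0) return(defaults)
  check_keys(raw, defaults, prefix = "")
  cfg <- modifyList(unclass(defaults), raw)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

# recursive unknown-key rejection with closest-match suggestion
check_keys <- function(given, known, prefix) {
  gk <- names(given)
  kk <- names(known)
  unknown <- setdiff(gk, kk)
  if (length(unknown) > 0) {
    key <- unknown[1]
    hit <- agrep(key, kk, max.distance = 0.4, ignore.case = TRUE, value = TRUE)
    hint <- if (length(hit) > 0) paste0("; did you mean \"", hit[1], "\"?")
            else ""
    stop("unknown config key \"", prefix, key, "\"", hint, call. = FALSE)
  }
  for (k in gk) {
    if (is.list(known[[k]]) && !is.null(names(known[[k]])) &&
        is.list(given[[k]])) {
      check_keys(given[[k]], known[[k]], paste0(prefix, k, "."))
    }
  }
  invisible(TRUE)
}

#' Serialize a pipeline configuration to YAML
#'
#' @param cfg A `pipeline_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Short stable hash of a configuration (recorded in output artifacts)
#' @param cfg A `pipeline_config`.
#' @return Character scalar.
#' @export
config_hash <- function(cfg) {
  txt <- yaml::as.yaml(unclass(cfg))
  # small rolling hash; only used to label outputs, not for security
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 2^28
  sprintf("%07x", h)
}

# expand the nested config into the stage objects
config_objects <- function(cfg) {
  syn <- cfg$synthetic
  freqs <- stimulation_frequencies(cfg$stimulus$refresh_hz,
                                   cfg$stimulus$frame_divisors)
  list(
    config = synthetic_config(
      fs = syn$fs, channels = syn$channels, n_harmonics = syn$n_harmonics,
      noise_gamma = syn$noise_gamma, noise_rms = syn$noise_rms,
      alpha_amp = syn$alpha_amp, target_snr_db = syn$target_snr_db,
      seed = cfg$seed),
    stimulus = stimulus_spec("OOR", freqs),
    timing = do.call(trial_timing, cfg$timing),
    bank = filter_bank_spec(
      bands = lapply(cfg$filter_bank$low_edges,
                     function(lo) c(lo, cfg$filter_bank$high_edge)),
      a = cfg$filter_bank$a, b = cfg$filter_bank$b,
      order = cfg$filter_bank$order, ripple_db = cfg$filter_bank$ripple_db),
    window = do.call(window_config, cfg$window)
  )
}
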