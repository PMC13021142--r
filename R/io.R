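#' Default run configuration
#'
#' Nested list of every tunable parameter with its default: the controller
#' block (gain, update rate, membership parameters, rule singletons, clamp),
#' the plant block (baseline, sensitivities, block onset, time constant, beat
#' jitter), the schedule block (phase durations and ramp geometry), the
#' metrics block (target band, oscillation threshold, alpha) plus the master
#' seed and output directory.
#'
#' @return A `run_config` list.
#' @export
default_config <- function() {
  structure(list(
    controller = list(gain = 5, update_rate = 2,
                      error_below_mid = -5, error_above_mid = 5,
                      error_steepness = 0.8,
                      slope_decreasing_full = -1, slope_increasing_full = 1,
                      singletons = list(above_increasing = 1,
                                        above_decreasing = 0.4,
                                        near = 0,
                                        below_increasing = -0.4,
                                        below_decreasing = -1),
                      cout_limits = c(-200, 200)),
    plant = list(baseline_hr = 400, perturb_sensitivity = 9.2,
                 control_sensitivity = 9.2, block_start_amp = 1.8,
                 block_sensitivity = 64.3, tau = 3, rr_jitter_sd_ms = 2),
    schedule = list(pre_control_s = 120, ramp_up_s = 300, ramp_down_s = 300,
                    post_control_s = 120, step_hz = 1, step_dwell_s = 10,
                    peak_freq = 30),
    metrics = list(band_lower = 40, band_upper = 60,
                   oscillation_threshold = 5, alpha = 0.005),
    seed = 0,
    out_dir = "."
  ), class = "run_config")
}

## recursive merge of user values onto defaults; unknown keys are hard errors
## so config typos never silently fall back to a default.
merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = "$")
    if (!key %in% names(defaults)) {
      abort(sprintf("unknown configuration key `%s`.", here),
            class = "vagusloop_config_error")
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        abort(sprintf("`%s` must be a block, not a scalar.", here),
              class = "vagusloop_config_error")
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

## build the module objects, so every invariant is checked with its field name
validate_config <- function(cfg) {
  ctl <- cfg$controller
  fuzzy_config(gain = ctl$gain, update_rate = ctl$update_rate, setpoint = 300,
               error_below_mid = ctl$error_below_mid,
               error_above_mid = ctl$error_above_mid,
               error_steepness = ctl$error_steepness,
               slope_decreasing_full = ctl$slope_decreasing_full,
               slope_increasing_full = ctl$slope_increasing_full,
               singletons = unlist(ctl$singletons),
               cout_limits = as.numeric(unlist(ctl$cout_limits)))
  do.call(plant_params, cfg$plant)
  do.call(trial_schedule, cfg$schedule)
  m <- cfg$metrics
  if (!(m$band_lower < m$band_upper)) {
    abort("`metrics$band_lower` must be < `metrics$band_upper`.",
          class = "vagusloop_config_error")
  }
  if (m$alpha <= 0 || m$alpha >= 1) {
    abort("`metrics$alpha` must be in (0, 1).", class = "vagusloop_config_error")
  }
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills every unset value from
#' [default_config()], rejects unknown keys, and validates all blocks against
#' the module invariants before anything is simulated. An empty file yields
#' the all-defaults configuration (gain 5, tau 3 s, seed 0).
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("configuration file '%s' does not exist.", path),
          class = "vagusloop_io_error")
  }
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user %||% list())
  cfg <- structure(cfg, class = "run_config")
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param config A `run_config` list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Helpers building module objects from a run configuration
#'
#' @param config A `run_config` (see [load_config()]).
#' @return `config_plant()` a [plant_params()], `config_schedule()` a
#'   [trial_schedule()], `config_controller()` a [fuzzy_config()] with the
#'   given setpoint.
#' @param setpoint Setpoint in bpm for the controller.
#' @export
config_plant <- function(config) do.call(plant_params, config$plant)

#' @rdname config_plant
#' @export
config_schedule <- function(config) do.call(trial_schedule, config$schedule)

#' @rdname config_plant
#' @export
config_controller <- function(config, setpoint) {
  ctl <- config$controller
  fuzzy_config(gain = ctl$gain, update_rate = ctl$update_rate,
               setpoint = setpoint,
               error_below_mid = ctl$error_below_mid,
               error_above_mid = ctl$error_above_mid,
               error_steepness = ctl$error_steepness,
               slope_decreasing_full = ctl$slope_decreasing_full,
               slope_increasing_full = ctl$slope_increasing_full,
               singletons = unlist(ctl$singletons),
               cout_limits = as.numeric(unlist(ctl$cout_limits)))
}

trial_file_magic <- "# vagusloop trial"

#' Write / read a trial record as delimited text
#'
#' The trial log is written as CSV preceded by `#` header lines carrying the
#' package version, seed, gain, setpoint and anchors, with numeric columns
#' rounded to 6 significant digits. `read_trial()` is the inverse on the
#' logged precision and fails with a format error on a missing header or a
#' column-schema mismatch.
#'
#' @param trial A [run_trial()] result.
#' @param path Output file path.
#' @return `write_trial()` the path, invisibly; `read_trial()` a `vns_trial`.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "vns_trial"))
  anchors <- attr(trial, "anchors")
  hdr <- c(
    sprintf("%s v%s", trial_file_magic, as.character(utils::packageVersion("vagusloop"))),
    sprintf("# seed: %s", attr(trial, "seed")),
    sprintf("# gain: %s", attr(trial, "gain")),
    sprintf("# control: %s", isTRUE(attr(trial, "control"))),
    sprintf("# setpoint_bpm: %.6g", attr(trial, "setpoint")),
    sprintf("# hr_0pct: %.6g", anchors$hr_0pct),
    sprintf("# hr_100pct: %.6g", anchors$hr_100pct)
  )
  rec <- tidy(trial) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 6)))
  writeLines(hdr, path)
  readr::write_csv(rec, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("trial file '%s' does not exist.", path),
          class = "vagusloop_io_error")
  }
  first <- readLines(path, n = 1L)
  if (!startsWith(first, trial_file_magic)) {
    abort("not a trial file: missing header line.", class = "vagusloop_format_error")
  }
  hdr <- grep("^#", readLines(path, n = 16L), value = TRUE)
  get_num <- function(key) {
    line <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(line)) return(NA_real_)
    as.numeric(sub(sprintf("^# %s:\\s*", key), "", line[1]))
  }
  rec <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("time_s", "hr_bpm", "hr_norm", "phase", "err_bpm", "slope_bpm_s",
            "dcout", "cout", "mode", "freq_hz", "amp_ma", "perturb_hz")
  if (!all(need %in% names(rec))) {
    abort(sprintf("trial file schema mismatch; missing: %s",
                  paste(setdiff(need, names(rec)), collapse = ", ")),
          class = "vagusloop_format_error")
  }
  anchors <- structure(list(hr_0pct = get_num("hr_0pct"),
                            hr_100pct = get_num("hr_100pct")),
                       class = "vns_anchors")
  structure(tibble::as_tibble(rec),
            class = c("vns_trial", class(tibble::tibble()))) |>
    `attr<-`("anchors", anchors) |>
    `attr<-`("setpoint", get_num("setpoint_bpm")) |>
    `attr<-`("gain", get_num("gain")) |>
    `attr<-`("seed", get_num("seed"))
}
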