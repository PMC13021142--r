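#' Trial schedule: the perturbation ramp and controller-on phases
#'
#' The controller-on window consists of a pre-control phase with no
#' perturbation, a ramp of perturbation-electrode stimulation from
#' `step_hz` up to `peak_freq` in `step_hz` steps held `step_dwell_s` each,
#' the mirrored descending ramp, and a post-control phase. At the defaults
#' (120 s + 300 s + 300 s + 120 s) the controller is on for 840 s and the ramp
#' covers 1-30 Hz at 10 s per 1 Hz step.
#'
#' @param pre_control_s,ramp_up_s,ramp_down_s,post_control_s Phase durations (s).
#' @param step_hz Frequency increment per ramp step (Hz).
#' @param step_dwell_s Dwell per ramp step (s).
#' @param peak_freq Ramp peak frequency (Hz).
#' @return An object of class `trial_schedule`.
#' @examples
#' sched <- trial_schedule()
#' schedule_duration(sched)
#' perturb_freq_at(sched, c(60, 275, 500))
#' @export
trial_schedule <- function(pre_control_s = 120, ramp_up_s = 300,
                           ramp_down_s = 300, post_control_s = 120,
                           step_hz = 1, step_dwell_s = 10, peak_freq = 30) {
  n_steps <- peak_freq / step_hz
  if (abs(n_steps - round(n_steps)) > 1e-9 ||
      abs(n_steps * step_dwell_s - ramp_up_s) > 1e-9 ||
      abs(n_steps * step_dwell_s - ramp_down_s) > 1e-9) {
    abort("ramp durations must equal (peak_freq / step_hz) * step_dwell_s.",
          class = "vagusloop_config_error")
  }
  if (min(pre_control_s, post_control_s) < 0) {
    abort("phase durations must be >= 0.", class = "vagusloop_config_error")
  }
  structure(list(pre_control_s = pre_control_s, ramp_up_s = ramp_up_s,
                 ramp_down_s = ramp_down_s, post_control_s = post_control_s,
                 step_hz = step_hz, step_dwell_s = step_dwell_s,
                 peak_freq = peak_freq),
            class = "trial_schedule")
}

#' @rdname trial_schedule
#' @param schedule A `trial_schedule`.
#' @export
schedule_duration <- function(schedule) {
  with(schedule, pre_control_s + ramp_up_s + ramp_down_s + post_control_s)
}

#' @rdname trial_schedule
#' @param t Trial time(s) in seconds from controller start; vectorised.
#' @return `perturb_freq_at()`: the perturbation frequency (Hz) at each `t`
#'   (piecewise constant; 0 outside the ramps).
#' @export
perturb_freq_at <- function(schedule, t) {
  s <- schedule
  up0 <- s$pre_control_s
  down0 <- up0 + s$ramp_up_s
  post0 <- down0 + s$ramp_down_s
  f <- numeric(length(t))
  in_up <- t >= up0 & t < down0
  f[in_up] <- pmin(floor((t[in_up] - up0) / s$step_dwell_s) + 1, s$peak_freq / s$step_hz) * s$step_hz
  in_down <- t >= down0 & t < post0
  f[in_down] <- (s$peak_freq / s$step_hz -
                   floor((t[in_down] - down0) / s$step_dwell_s)) * s$step_hz
  f
}

#' @rdname trial_schedule
#' @export
phase_at <- function(schedule, t) {
  s <- schedule
  edges <- cumsum(c(s$pre_control_s, s$ramp_up_s, s$ramp_down_s, s$post_control_s))
  labs <- c("pre", "ramp_up", "ramp_down", "post")
  labs[pmin(findInterval(t, c(-Inf, edges[1:3])), 4L)]
}

#' Measure the normalization anchors
#'
#' Runs the pre-trial responsiveness check on the synthetic plant: maximal
#' 30 Hz, 50 us stimulation on the control electrode for at most 30 s, during
#' which the minimum rolling heart-rate estimate defines the 0% anchor; after a
#' 2-minute recovery, the resting estimate defines the 100% anchor.
#'
#' @param params A [plant_params()] or a [sample_animals()] row.
#' @param seed Optional seed for the beat-jitter stream.
#' @param stim_s Duration of the maximal stimulation (s, <= 30).
#' @param recovery_s Recovery wait before reading the 100% anchor (s).
#' @param min_span Minimum anchor separation (bpm); smaller separations raise
#'   an unresponsive-plant error, mirroring the in-vivo responsiveness check.
#' @return A list with `hr_0pct` and `hr_100pct` (bpm), class `vns_anchors`.
#' @export
measure_anchors <- function(params, seed = NULL, stim_s = 30,
                            recovery_s = 120, min_span = 20) {
  params <- as_plant_params(params)
  stopifnot(stim_s <= 30)
  pre <- 5
  segs <- tibble::tibble(duration = c(pre, stim_s, recovery_s),
                         f_stim = c(0, 30, 0), amp = 0, perturb = 0)
  grid <- seq(pre + 2, pre + stim_s, by = 0.5)
  at <- c(grid, pre + stim_s + recovery_s)
  sd_anchor <- if (is.null(seed)) NULL else derive_seed(seed, "anchors")
  hr <- measure_profile(params, segs, at, seed = sd_anchor)
  hr_0 <- min(hr[seq_along(grid)])
  hr_100 <- hr[length(at)]
  if (!is.finite(hr_0) || !is.finite(hr_100) || (hr_100 - hr_0) < min_span) {
    abort(sprintf("unresponsive plant: anchors %.1f / %.1f bpm are within %.0f bpm.",
                  hr_0, hr_100, min_span),
          class = "vagusloop_unresponsive_error")
  }
  structure(list(hr_0pct = hr_0, hr_100pct = hr_100), class = "vns_anchors")
}

#' Normalize heart rate against the trial anchors
#'
#' Linear rescaling so that the maximal-stimulation minimum maps to 0% and the
#' post-check resting baseline to 100%; values outside \[0, 100\] are allowed.
#'
#' @param hr Heart rate(s) in bpm.
#' @param anchors A [measure_anchors()] result (or list with `hr_0pct`,
#'   `hr_100pct`).
#' @return Normalized heart rate in percent.
#' @export
normalize_hr <- function(hr, anchors) {
  if (!(anchors$hr_0pct < anchors$hr_100pct)) {
    abort("anchors must satisfy hr_0pct < hr_100pct.", class = "vagusloop_config_error")
  }
  100 * (hr - anchors$hr_0pct) / (anchors$hr_100pct - anchors$hr_0pct)
}

## The closed-loop engine. Advances the plant in dt_sub substeps between
## controller updates, emits jittered beats, feeds the rolling R-R estimator
## into the controller and logs one row per update. `perturb_fn(t)` gives the
## perturbation frequency over [t, t + update period). With control = FALSE
## the controller is bypassed (cout pinned at 0, electrode off).
run_closed_loop <- function(params, config, calib, duration_s, perturb_fn,
                            seed = NULL, control = TRUE, dt_sub = 0.05,
                            preroll_s = 3, window = 2) {
  params <- as_plant_params(params)
  stopifnot(inherits(config, "fuzzy_config"))
  period <- 1 / config$update_rate
  nsub <- round(period / dt_sub)
  if (abs(nsub * dt_sub - period) > 1e-9) {
    abort("update period must be a multiple of the plant substep.",
          class = "vagusloop_config_error")
  }
  n_ticks <- round(duration_s / period)
  decay <- exp(-dt_sub / params$tau) ^ seq_len(nsub)
  jitter_sd <- params$rr_jitter_sd_ms / 1000
  sp <- config$setpoint

  n_pre <- round(preroll_s / dt_sub)
  max_beats <- ceiling((duration_s + preroll_s) * (params$baseline_hr + 100) / 60) + 16L
  beats <- numeric(max_beats)
  nb <- 0L

  run <- function() {
    hr <- params$baseline_hr
    phase <- 0
    last_ideal <- -preroll_s
    last_actual <- -preroll_s

    emit <- function(t0, hr0, hr_path, phase0, phase_path) {
      m_first <- floor(phase0) + 1
      m_last <- floor(phase_path[length(phase_path)])
      if (m_last < m_first) return(invisible())
      ideal <- stats::approx(c(phase0, phase_path),
                             c(t0, t0 + dt_sub * seq_along(phase_path)),
                             xout = seq(m_first, m_last))$y
      iv <- diff(c(last_ideal, ideal))
      if (jitter_sd > 0) iv <- pmax(iv + rnorm(length(iv), 0, jitter_sd), 0.02)
      new_beats <- last_actual + cumsum(iv)
      beats[nb + seq_along(new_beats)] <<- new_beats
      nb <<- nb + length(new_beats)
      last_ideal <<- ideal[length(ideal)]
      last_actual <<- new_beats[length(new_beats)]
      invisible()
    }

    advance <- function(t0, f_pert, f_stim, amp, n_steps, dec) {
      target <- params$baseline_hr - plant_drive(params, f_pert, f_stim, amp)
      hr_path <- target + (hr - target) * dec
      mid <- (c(hr, hr_path[-n_steps]) + hr_path) / 2
      phase_path <- phase + cumsum(mid) / 60 * dt_sub
      emit(t0, hr, hr_path, phase, phase_path)
      hr <<- hr_path[n_steps]
      phase <<- phase_path[n_steps]
      invisible()
    }

    # pre-roll at rest so the estimator window is populated at t = 0
    advance(-preroll_s, 0, 0, 0, n_pre,
            exp(-dt_sub / params$tau) ^ seq_len(n_pre))

    n_rows <- n_ticks + 1L
    col_t <- numeric(n_rows); col_hr <- numeric(n_rows)
    col_err <- numeric(n_rows); col_slope <- numeric(n_rows)
    col_dcout <- numeric(n_rows); col_cout <- numeric(n_rows)
    col_mode <- character(n_rows); col_freq <- numeric(n_rows)
    col_amp <- numeric(n_rows); col_pert <- numeric(n_rows)

    cout <- 0
    prev_err <- NA_real_
    n_updates <- 0L
    hr_est <- NA_real_
    glim <- config$gain / config$update_rate

    for (n in 0:n_ticks) {
      t <- n * period
      i1 <- findInterval(t + 1e-12, beats[seq_len(nb)])
      i0 <- findInterval(t - window, beats[seq_len(nb)])
      lo <- max(i0 + 1L, 2L)
      if (i1 >= lo) {
        hr_est <- 60 * (i1 - lo + 1L) / (beats[i1] - beats[lo - 1L])
      } # else hold previous estimate
      err <- hr_est - sp
      if (n == 0L) {
        slope <- 0; dcout <- 0
        prev_err <- err
      } else if (control) {
        slope <- (err - prev_err) * config$update_rate
        m <- fuzzify(err, slope, config)
        dcout <- defuzzify(m, config)
        cout <- clamp(cout + glim * dcout,
                      config$cout_limits[1], config$cout_limits[2])
        prev_err <- err
        n_updates <- n_updates + 1L
      } else {
        slope <- 0; dcout <- 0
        n_updates <- n_updates + 1L
      }
      if (cout > 0) {
        mode <- "stim"
        f_stim <- min(cout / calib$stim_sensitivity, 30); amp <- 0
        freq_log <- f_stim
      } else if (cout < 0) {
        mode <- "block"
        f_stim <- 0
        amp <- min(-cout / calib$block_sensitivity + calib$block_start_amp, 10)
        freq_log <- 10000
      } else {
        mode <- "off"; f_stim <- 0; amp <- 0; freq_log <- 0
      }
      f_pert <- perturb_fn(t)
      k <- n + 1L
      col_t[k] <- t; col_hr[k] <- hr_est; col_err[k] <- err
      col_slope[k] <- slope; col_dcout[k] <- dcout; col_cout[k] <- cout
      col_mode[k] <- mode; col_freq[k] <- freq_log; col_amp[k] <- amp
      col_pert[k] <- f_pert
      if (n < n_ticks) advance(t, f_pert, f_stim, amp, nsub, decay)
    }

    list(record = tibble::tibble(time_s = col_t, hr_bpm = col_hr,
                                 err_bpm = col_err, slope_bpm_s = col_slope,
                                 dcout = col_dcout, cout = col_cout,
                                 mode = col_mode, freq_hz = col_freq,
                                 amp_ma = col_amp, perturb_hz = col_pert),
         n_updates = n_updates)
  }

  if (is.null(seed)) run() else with_seed(derive_seed(seed, "beats"), run())
}

#' Run one full closed-loop trial
#'
#' Executes the complete protocol on a synthetic animal: calibration (unless a
#' calibration is supplied), the anchor/responsiveness check, setpoint
#' assignment at the 50% normalized heart rate, and the controller-on window
#' with the perturbation ramp, logging heart rate, normalized heart rate,
#' controller internals and the commanded waveform at every update.
#'
#' @param animal A [plant_params()] or one row of [sample_animals()].
#' @param gain Controller gain G (bpm/s); the study used 2, 5 and 10.
#' @param seed Integer seed; every noise stream in the trial is derived from
#'   it, so equal seeds give bit-identical trials.
#' @param calib Optional precomputed [calibrate_plant()] result.
#' @param schedule A [trial_schedule()].
#' @param control `FALSE` runs the perturbation-only reference condition (the
#'   controller stays off and `cout` is pinned at 0).
#' @param ... Further arguments to [fuzzy_config()] (membership parameters,
#'   singletons, `update_rate`, ...). The setpoint is always the anchor
#'   midpoint.
#' @return A `vns_trial`: the per-update record as a tibble (columns `time_s`,
#'   `hr_bpm`, `hr_norm`, `phase`, `err_bpm`, `slope_bpm_s`, `dcout`, `cout`,
#'   `mode`, `freq_hz`, `amp_ma`, `perturb_hz`) with the anchors, setpoint,
#'   gain, schedule, calibration and seed stored as attributes.
#' @examples
#' \donttest{
#' tr <- run_trial(plant_params(), gain = 5, seed = 1)
#' glance(tr)
#' }
#' @export
run_trial <- function(animal, gain = 5, seed = 0, calib = NULL,
                      schedule = trial_schedule(), control = TRUE, ...) {
  params <- as_plant_params(animal)
  if (is.null(calib)) {
    calib <- calibrate_plant(params, seed = derive_seed(seed, "calibration"))
  }
  anchors <- measure_anchors(params, seed = seed)
  setpoint <- (anchors$hr_0pct + anchors$hr_100pct) / 2
  config <- fuzzy_config(gain = gain, setpoint = setpoint, ...)
  duration <- schedule_duration(schedule)
  out <- run_closed_loop(params, config, calib, duration,
                         perturb_fn = function(t) perturb_freq_at(schedule, t),
                         seed = seed, control = control)
  rec <- out$record
  rec$hr_norm <- normalize_hr(rec$hr_bpm, anchors)
  rec$phase <- phase_at(schedule, rec$time_s)
  rec <- dplyr::relocate(rec, "time_s", "hr_bpm", "hr_norm", "phase")
  structure(rec,
            class = c("vns_trial", class(tibble::tibble()))) |>
    `attr<-`("anchors", anchors) |>
    `attr<-`("setpoint", setpoint) |>
    `attr<-`("gain", gain) |>
    `attr<-`("schedule", schedule) |>
    `attr<-`("calib", calib) |>
    `attr<-`("params", params) |>
    `attr<-`("seed", seed) |>
    `attr<-`("control", control) |>
    `attr<-`("n_updates", out$n_updates)
}

#' @rdname run_trial
#' @param x A `vns_trial`.
#' @param ... Unused.
#' @export
tidy.vns_trial <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname run_trial
#' @export
glance.vns_trial <- function(x, ...) {
  m <- trial_metrics(x)
  m$gain <- attr(x, "gain")
  m$setpoint_bpm <- attr(x, "setpoint")
  m$seed <- attr(x, "seed")
  dplyr::relocate(m, "gain")
}

#' Gain study: repeated trials across controller gains
#'
#' Draws `n_animals` synthetic animals, calibrates each once, then runs one
#' trial per gain per animal and collects the per-trial metrics -- the desk
#' analogue of the in-vivo gain comparison (nine statistical sets at gains 2,
#' 5 and 10).
#'
#' @param n_animals Number of synthetic animals.
#' @param gains Controller gains (bpm/s) to test.
#' @param seed Master seed; animal draws, calibrations and trials derive
#'   per-component seeds from it.
#' @param tau Plant time constant (s) applied to every animal.
#' @param band Target band in percent normalized heart rate.
#' @param ... Passed to [run_trial()].
#' @return A tibble of class `vns_gain_sweep`: one row per trial with the
#'   animal id, gain, metrics and category.
#' @examples
#' \donttest{
#' sw <- sweep_gains(n_animals = 2, seed = 1)
#' compare_gains(sw, metric = "time_in_band")
#' }
#' @export
sweep_gains <- function(n_animals = 9, gains = c(2, 5, 10), seed = 0,
                        tau = 3, band = c(40, 60), ...) {
  animals <- sample_animals(n_animals, seed = derive_seed(seed, "animal"),
                            tau = tau)
  rows <- purrr::map(seq_len(n_animals), function(i) {
    params <- as_plant_params(animals[i, ])
    trial_seed0 <- derive_seed(seed, "trial") + i * 1000L
    calib <- calibrate_plant(params, seed = trial_seed0)
    purrr::map(seq_along(gains), function(j) {
      tr <- run_trial(params, gain = gains[j], seed = trial_seed0 + j,
                      calib = calib, ...)
      m <- trial_metrics(tr, band = band)
      dplyr::bind_cols(tibble::tibble(animal = i, gain = gains[j]), m)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  structure(rows, class = c("vns_gain_sweep", class(tibble::tibble())),
            seed = seed, tau = tau, band = band)
}
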