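#' Electrode waveform command
#'
#' The control electrode's output at one update: low-frequency stimulation
#' (positive `cout`), 10 kHz KHFAC block (negative `cout`) or off. Stimulation
#' uses the maximal-threshold amplitude found during calibration (so only the
#' frequency is commanded, with 50 us pulses); block commands only an
#' amplitude.
#'
#' @param mode One of `"stim"`, `"block"`, `"off"`.
#' @param freq_hz Stimulation frequency (stim mode, 0-30 Hz) or the 10 kHz
#'   carrier (block mode).
#' @param amp_ma Block amplitude in mA peak-to-peak (block mode).
#' @param pulse_width_us Pulse width (stim mode, 50 us).
#' @return An object of class `waveform_command`.
#' @export
waveform_command <- function(mode = c("off", "stim", "block"),
                             freq_hz = 0, amp_ma = 0, pulse_width_us = 0) {
  mode <- match.arg(mode)
  structure(list(mode = mode, freq_hz = freq_hz, amp_ma = amp_ma,
                 pulse_width_us = pulse_width_us),
            class = "waveform_command")
}

## coefficient of determination computed directly (summary.lm warns on
## numerically perfect fits, which are routine for noiseless sweeps)
rsq <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) return(0)
  max(0, min(1, 1 - sum(stats::residuals(fit)^2) / sst))
}

#' Fit the stimulation calibration line
#'
#' Ordinary least-squares fit of heart-rate drop against stimulation frequency
#' over a 1-30 Hz sweep. The sensitivity is reported as a positive slope in
#' bpm/Hz. If `baseline_hr` is supplied the drop is `baseline_hr - hr_bpm`;
#' otherwise heart rate is regressed on frequency directly and the slope
#' magnitude is returned (a warning is raised if heart rate *rises* with
#' frequency, and a flat response yields slope 0 with a warning).
#'
#' @param data Data frame with columns `freq_hz` and `hr_bpm` (`hr_bpm` may
#'   already be a drop in bpm; the slope magnitude is unaffected).
#' @param baseline_hr Optional resting heart rate (bpm).
#' @return A one-row tibble: `stim_sensitivity` (bpm/Hz), `stim_r2`, `n`.
#' @examples
#' d <- tibble::tibble(freq_hz = 1:10, hr_bpm = 9.2 * (1:10))
#' fit_stim_calibration(d)
#' @export
fit_stim_calibration <- function(data, baseline_hr = NULL) {
  stopifnot(all(c("freq_hz", "hr_bpm") %in% names(data)))
  f <- data$freq_hz; y <- data$hr_bpm
  check_finite(f, "freq_hz"); check_finite(y, "hr_bpm")
  if (length(unique(f)) < 3L) {
    abort("need >= 3 distinct frequencies for a calibration fit.",
          class = "vagusloop_degenerate_fit_error")
  }
  if (!is.null(baseline_hr)) y <- baseline_hr - y
  fit <- lm(y ~ f)
  slope <- unname(coef(fit)[2])
  r2 <- rsq(fit, y)
  if (abs(slope) < sqrt(.Machine$double.eps)) {
    warn("flat heart-rate response: stimulation sensitivity is 0.",
         class = "vagusloop_degenerate_fit_warning")
    slope <- 0
  } else if (is.null(baseline_hr) && slope < 0) {
    # heart rate falling with frequency: the expected direction
    slope <- -slope
  } else if (!is.null(baseline_hr) && slope < 0) {
    warn("heart rate rises with stimulation frequency; reporting |slope|.",
         class = "vagusloop_degenerate_fit_warning")
    slope <- -slope
  }
  tibble::tibble(stim_sensitivity = slope, stim_r2 = r2, n = length(f))
}

#' Fit the block calibration
#'
#' Implements the KHFAC amplitude sweep analysis: under maximal perturbation,
#' block amplitude is swept upward in `resolution` (0.1 mA) steps; the largest
#' amplitude at which heart rate has not yet risen above the perturbed plateau
#' (by `rise_threshold` bpm) is the starting block current, and an OLS line
#' through the rising points from onset up to recovery of `baseline_hr` gives
#' the block sensitivity in bpm/mA p-p.
#'
#' With `refine_onset = TRUE` (default) the reported `block_start_amp` is the
#' amplitude where the fitted rising line crosses the perturbed-plateau level,
#' which removes the detection lag of the threshold rule for low-sensitivity
#' animals; the raw grid estimate is kept in `block_start_amp_grid`.
#'
#' @param data Data frame with strictly increasing `amp_ma` and measured
#'   `hr_bpm` columns.
#' @param baseline_hr Pre-perturbation resting heart rate (bpm); the fit stops
#'   at the first point recovering it.
#' @param rise_threshold Rise (bpm) above the running plateau mean that counts
#'   as "heart rate began to rise". Default 2.
#' @param resolution Sweep amplitude resolution (mA p-p), default 0.1.
#' @param refine_onset Refine the onset by back-extrapolating the fitted line.
#' @return One-row tibble: `block_start_amp`, `block_start_amp_grid`,
#'   `block_sensitivity`, `block_r2`, `n_fit`.
#' @export
fit_block_calibration <- function(data, baseline_hr, rise_threshold = 2,
                                  resolution = 0.1, refine_onset = TRUE) {
  stopifnot(all(c("amp_ma", "hr_bpm") %in% names(data)))
  a <- data$amp_ma; y <- data$hr_bpm
  check_finite(a, "amp_ma"); check_finite(y, "hr_bpm")
  check_finite(baseline_hr, "baseline_hr")
  if (any(diff(a) <= 0)) abort("`amp_ma` must be strictly increasing.",
                               class = "vagusloop_input_error")
  n <- length(a)
  plateau <- y[1]
  onset <- NA_integer_
  for (i in seq(2L, n)) {
    # a real onset keeps rising at the next amplitude too; a single noisy
    # reading above threshold must not trigger it
    confirmed <- y[i] > plateau + rise_threshold &&
      (i == n || y[i + 1L] > plateau + rise_threshold)
    if (confirmed) { onset <- i; break }
    plateau <- mean(y[seq_len(i)])
  }
  if (is.na(onset)) {
    abort("heart rate never rose during the block sweep: no block achieved.",
          class = "vagusloop_no_block_error")
  }
  start_grid <- if (onset == 2L) max(a[1] - resolution, 0) else a[onset - 1L]
  # fit from the starting point up to recovery of baseline; stop the segment
  # `rise_threshold` below baseline so the saturated flat tail (full block)
  # never leaks into the slope
  hi <- which(y >= baseline_hr - rise_threshold)
  hi <- if (length(hi[hi >= onset])) min(hi[hi >= onset]) else n
  lo <- max(onset - 1L, 1L)
  seg <- seq(lo, hi)
  if (length(seg) < 3L) {
    abort("need >= 3 points above block onset for a calibration fit.",
          class = "vagusloop_degenerate_fit_error")
  }
  fit <- lm(y[seg] ~ a[seg])
  slope <- unname(coef(fit)[2])
  r2 <- rsq(fit, y[seg])
  if (slope <= 0) {
    abort("non-positive block slope: heart rate does not recover with amplitude.",
          class = "vagusloop_degenerate_fit_error")
  }
  start <- start_grid
  if (refine_onset && onset > 2L) {
    cross <- (plateau - unname(coef(fit)[1])) / slope
    # keep the refinement within the sweep neighbourhood of the grid estimate
    if (is.finite(cross)) start <- clamp(cross, 0, a[onset])
  }
  tibble::tibble(block_start_amp = start, block_start_amp_grid = start_grid,
                 block_sensitivity = slope, block_r2 = r2, n_fit = length(seg))
}

#' Convert the controller output coefficient to a waveform command
#'
#' Positive `cout` divides by the stimulation sensitivity to give a
#' stimulation frequency (clamped to 0-30 Hz, 50 us pulses); negative `cout`
#' divides its magnitude by the block sensitivity and adds the starting block
#' current, so commanded block amplitudes always skip the sub-blocking dead
#' zone; zero gives `off`.
#'
#' @param cout Output coefficient (dimensionless, roughly bpm-equivalent).
#' @param calib A [calibrate_plant()] result, or any list with elements
#'   `stim_sensitivity`, `block_sensitivity`, `block_start_amp`.
#' @param freq_max Stimulation frequency clamp (Hz), default 30.
#' @param amp_cap Block amplitude cap (mA p-p), default 10.
#' @return A [waveform_command()].
#' @examples
#' cal <- list(stim_sensitivity = 9.2, block_sensitivity = 64.3,
#'             block_start_amp = 1.8)
#' cout_to_command(18.4, cal)$freq_hz
#' @export
cout_to_command <- function(cout, calib, freq_max = 30, amp_cap = 10) {
  check_finite(cout, "cout")
  if (cout > 0) {
    waveform_command("stim",
                     freq_hz = clamp(cout / calib$stim_sensitivity, 0, freq_max),
                     pulse_width_us = 50)
  } else if (cout < 0) {
    waveform_command("block", freq_hz = 10000,
                     amp_ma = min(abs(cout) / calib$block_sensitivity +
                                    calib$block_start_amp, amp_cap))
  } else {
    waveform_command("off")
  }
}

## closed-form heart-rate profile over piecewise-constant input segments;
## returns the time grid (t = 0 included) and instantaneous heart rate.
sim_profile <- function(params, segments, dt = 0.05, hr0 = NULL) {
  params <- as_plant_params(params)
  hr0 <- hr0 %||% params$baseline_hr
  t_all <- 0; hr_all <- hr0
  t_cur <- 0; hr_cur <- hr0
  for (i in seq_len(nrow(segments))) {
    n <- round(segments$duration[i] / dt)
    target <- plant_steady_hr(params, segments$perturb[i],
                              segments$f_stim[i], segments$amp[i])
    decay <- exp(-dt / params$tau) ^ seq_len(n)
    hr_seg <- target + (hr_cur - target) * decay
    t_all <- c(t_all, t_cur + dt * seq_len(n))
    hr_all <- c(hr_all, hr_seg)
    hr_cur <- hr_seg[n]; t_cur <- t_cur + dt * n
  }
  tibble::tibble(t = t_all, hr = hr_all)
}

## measure the rolling-HR estimate at given times on a simulated profile
measure_profile <- function(params, segments, at, dt = 0.05, hr0 = NULL,
                            seed = NULL, window = 2) {
  prof <- sim_profile(params, segments, dt = dt, hr0 = hr0)
  beats <- emit_beats(prof$t, prof$hr, params$rr_jitter_sd_ms, seed = seed)
  rolling_hr(beats, at, window = window)
}

#' Run the full calibration procedure on a synthetic animal
#'
#' Reproduces the two calibration sweeps on the simulated plant. First the
#' resting heart rate is measured; then control-electrode stimulation is swept
#' 1-30 Hz in 1 Hz steps (each held `dwell_s` seconds, heart rate read from the
#' rolling R-R estimator at the end of each dwell) and the drop-vs-frequency
#' line is fitted, excluding any saturated plateau at the top of the sweep.
#' Second, under maximal 30 Hz perturbation, block amplitude is swept upward
#' from `resolution` in `resolution` steps until the resting baseline is
#' recovered (or `amp_cap` is reached) and the onset and recovery slope are
#' fitted with [fit_block_calibration()].
#'
#' @param params A [plant_params()] or one row of [sample_animals()].
#' @param seed Optional seed for the beat-jitter measurement noise.
#' @param dwell_s Dwell per sweep step (s). Default 15 (5 time constants at
#'   the default tau = 3 s).
#' @param resolution Block sweep amplitude resolution (mA p-p).
#' @param rise_threshold Block onset threshold (bpm), see
#'   [fit_block_calibration()].
#' @param amp_cap Maximum swept block amplitude (mA p-p).
#' @param refine_onset Passed to [fit_block_calibration()].
#' @return An object of class `vns_calibration`: a list with the fitted
#'   `stim_sensitivity`, `stim_r2`, `stim_max_freq`, `block_start_amp`,
#'   `block_sensitivity`, `block_r2`, the measured `baseline_hr` and
#'   `perturbed_hr`, and the raw `sweeps` (tibbles).
#' @examples
#' cal <- calibrate_plant(plant_params(rr_jitter_sd_ms = 0))
#' glance(cal)
#' @export
calibrate_plant <- function(params, seed = NULL, dwell_s = 15,
                            resolution = 0.1, rise_threshold = 2,
                            amp_cap = 10, refine_onset = TRUE) {
  params <- as_plant_params(params)
  seed_stim <- if (is.null(seed)) NULL else derive_seed(seed, "calibration")
  seed_block <- if (is.null(seed)) NULL else derive_seed(seed + 1L, "calibration")

  # resting baseline (averaged over the last 4 s of the rest dwell to beat the
  # ~2 bpm estimator noise), then the 1-30 Hz stimulation sweep
  freqs <- 1:30
  seg_stim <- tibble::tibble(duration = dwell_s,
                             f_stim = c(0, freqs),
                             amp = 0, perturb = 0)
  at_base <- seq(dwell_s - 4, dwell_s, by = 0.5)
  at <- c(at_base, dwell_s * (1 + seq_along(freqs)))
  hr_meas <- measure_profile(params, seg_stim, at, seed = seed_stim)
  baseline_meas <- mean(hr_meas[seq_along(at_base)])
  stim_sweep <- tibble::tibble(freq_hz = freqs,
                               hr_bpm = hr_meas[-seq_along(at_base)])

  # trim the saturated plateau: keep points up to the first one whose drop is
  # within the rise threshold of the largest observed drop
  drop <- baseline_meas - stim_sweep$hr_bpm
  first_sat <- which(drop >= max(drop) - rise_threshold)[1]
  stim_fit <- fit_stim_calibration(stim_sweep[seq_len(first_sat), ],
                                   baseline_hr = baseline_meas)

  # block sweep under maximal perturbation: settle, then step the amplitude
  amps <- seq(resolution, amp_cap, by = resolution)
  seg_block <- tibble::tibble(duration = c(2 * dwell_s, rep(dwell_s, length(amps))),
                              f_stim = 0,
                              amp = c(0, amps),
                              perturb = 30)
  at_b <- cumsum(seg_block$duration)
  hr_b <- measure_profile(params, seg_block, at_b, seed = seed_block)
  perturbed_hr <- hr_b[1]
  block_sweep <- tibble::tibble(amp_ma = amps, hr_bpm = hr_b[-1])
  # the in-vivo sweep stops once the resting baseline is recovered
  rec <- which(block_sweep$hr_bpm >= baseline_meas - rise_threshold)
  if (length(rec)) block_sweep <- block_sweep[seq_len(min(max(rec[1], 3), nrow(block_sweep))), ]
  block_fit <- fit_block_calibration(block_sweep, baseline_hr = baseline_meas,
                                     rise_threshold = rise_threshold,
                                     resolution = resolution,
                                     refine_onset = refine_onset)

  structure(list(stim_sensitivity = stim_fit$stim_sensitivity,
                 stim_r2 = stim_fit$stim_r2,
                 stim_max_freq = stim_sweep$freq_hz[first_sat],
                 block_start_amp = block_fit$block_start_amp,
                 block_start_amp_grid = block_fit$block_start_amp_grid,
                 block_sensitivity = block_fit$block_sensitivity,
                 block_r2 = block_fit$block_r2,
                 baseline_hr = baseline_meas,
                 perturbed_hr = perturbed_hr,
                 sweeps = list(stim = stim_sweep, block = block_sweep)),
            class = "vns_calibration")
}

#' @export
print.vns_calibration <- function(x, ...) {
  cat("<vns_calibration>\n")
  cat(sprintf("  stimulation: %.2f bpm/Hz (r2 = %.4f, max freq %d Hz)\n",
              x$stim_sensitivity, x$stim_r2, x$stim_max_freq))
  cat(sprintf("  block: start %.3f mA p-p, %.2f bpm/mA (r2 = %.4f)\n",
              x$block_start_amp, x$block_sensitivity, x$block_r2))
  cat(sprintf("  baseline %.1f bpm, perturbed plateau %.1f bpm\n",
              x$baseline_hr, x$perturbed_hr))
  invisible(x)
}

#' @rdname calibrate_plant
#' @param x A `vns_calibration` object.
#' @param ... Unused.
#' @export
tidy.vns_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("stim_sensitivity", "block_start_amp", "block_sensitivity"),
    estimate = c(x$stim_sensitivity, x$block_start_amp, x$block_sensitivity),
    unit = c("bpm/Hz", "mA p-p", "bpm/mA p-p"),
    r_squared = c(x$stim_r2, NA_real_, x$block_r2)
  )
}

#' @rdname calibrate_plant
#' @export
glance.vns_calibration <- function(x, ...) {
  tibble::tibble(stim_sensitivity = x$stim_sensitivity, stim_r2 = x$stim_r2,
                 stim_max_freq = x$stim_max_freq,
                 block_start_amp = x$block_start_amp,
                 block_sensitivity = x$block_sensitivity,
                 block_r2 = x$block_r2, baseline_hr = x$baseline_hr,
                 perturbed_hr = x$perturbed_hr)
}
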