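#' Synthetic animal parameters
#'
#' Parameter set for the synthetic cardiac-vagal plant that stands in for the
#' rat: a first-order lag from vagal drive to heart rate, a linear
#' frequency-to-heart-rate-drop relation for stimulation, and a linear
#' amplitude-to-transmission relation for KHFAC block above the starting block
#' current.
#'
#' @param baseline_hr Resting heart rate (bpm), the 100% anchor.
#' @param perturb_sensitivity Heart-rate drop per Hz of perturbation-electrode
#'   stimulation (bpm/Hz).
#' @param control_sensitivity Heart-rate drop per Hz of control-electrode
#'   stimulation (bpm/Hz). Defaults to `perturb_sensitivity`: same nerve, same
#'   electrode design.
#' @param block_start_amp Largest block amplitude with no conduction block
#'   (mA peak-to-peak).
#' @param block_sensitivity Heart-rate recovery per mA p-p of block amplitude
#'   above `block_start_amp` (bpm/mA), under maximal perturbation.
#' @param tau First-order heart-rate time constant (s).
#' @param rr_jitter_sd_ms Beat-timing noise: sd of the additive Gaussian
#'   perturbation of each inter-beat interval (ms).
#' @param max_drop Heart-rate span from the 100% to the 0% anchor (bpm);
#'   defaults to `min(30 * perturb_sensitivity, 0.9 * baseline_hr)` so maximal
#'   30 Hz perturbation with no control defines the 0% anchor.
#' @return An object of class `plant_params`.
#' @examples
#' p <- plant_params()
#' transmission_factor(c(0, 2.5), p)
#' @export
plant_params <- function(baseline_hr = 400,
                         perturb_sensitivity = 9.2,
                         control_sensitivity = perturb_sensitivity,
                         block_start_amp = 1.8,
                         block_sensitivity = 64.3,
                         tau = 3,
                         rr_jitter_sd_ms = 2,
                         max_drop = min(30 * perturb_sensitivity,
                                        0.9 * baseline_hr)) {
  for (nm in c("baseline_hr", "perturb_sensitivity", "control_sensitivity",
               "block_start_amp", "block_sensitivity", "tau",
               "rr_jitter_sd_ms", "max_drop")) {
    check_finite(get(nm), nm)
  }
  if (!(baseline_hr > max_drop && max_drop > 0)) {
    abort("need baseline_hr > max_drop > 0.", class = "vagusloop_config_error")
  }
  if (perturb_sensitivity <= 0 || control_sensitivity <= 0 ||
      block_sensitivity <= 0) {
    abort("sensitivities must be > 0.", class = "vagusloop_config_error")
  }
  if (block_start_amp < 0) abort("`block_start_amp` must be >= 0.",
                                 class = "vagusloop_config_error")
  if (tau <= 0) abort("`tau` must be > 0.", class = "vagusloop_config_error")
  if (rr_jitter_sd_ms < 0) abort("`rr_jitter_sd_ms` must be >= 0.",
                                 class = "vagusloop_config_error")
  structure(list(baseline_hr = baseline_hr,
                 perturb_sensitivity = perturb_sensitivity,
                 control_sensitivity = control_sensitivity,
                 block_start_amp = block_start_amp,
                 block_sensitivity = block_sensitivity,
                 tau = tau, rr_jitter_sd_ms = rr_jitter_sd_ms,
                 max_drop = max_drop),
            class = "plant_params")
}

# population model: paper-reported mean/sd/range for each calibration metric.
# mu is solved so the *truncated* distribution mean equals the reported mean
# (the reported means are means of range-limited in-vivo samples).
.population <- list(
  perturb_sensitivity = list(mean = 9.2, sd = 2.5, lo = 5, hi = 12),
  block_start_amp = list(mean = 1.8, sd = 0.9, lo = 0.5, hi = 3),
  block_sensitivity = list(mean = 64.3, sd = 45, lo = 14.5, hi = 160)
)

.population_mu <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- purrr::map_dbl(.population,
                               ~ truncnorm_match_mu(.x$mean, .x$sd, .x$lo, .x$hi))
    }
    cache
  }
})

#' Draw synthetic animals from the population model
#'
#' Samples animal parameter sets whose calibration statistics match the
#' reported population: stimulation sensitivity with mean 9.2 bpm/Hz (sd 2.5,
#' range 5-12), starting block amplitude with mean 1.8 mA p-p (sd 0.9, range
#' 0.5-3) and block sensitivity with mean 64.3 bpm/mA p-p (sd 45, range
#' 14.5-160). Each is drawn from a truncated normal whose location is adjusted
#' so the truncated mean equals the reported mean. Baseline heart rate is
#' Normal(400, 30) bpm; control sensitivity equals perturbation sensitivity;
#' `max_drop = min(30 * perturb_sensitivity, 0.9 * baseline_hr)`.
#'
#' @param n Number of animals.
#' @param seed Optional integer seed (draws are bit-reproducible under a fixed
#'   seed; `NULL` uses the current RNG stream).
#' @param tau,rr_jitter_sd_ms Dynamics and noise parameters copied into every
#'   animal (the population model covers only the calibration metrics).
#' @return A tibble with one row per animal and the [plant_params()] fields.
#' @examples
#' sample_animals(3, seed = 1)
#' @export
sample_animals <- function(n, seed = NULL, tau = 3, rr_jitter_sd_ms = 2) {
  stopifnot(is.numeric(n), n >= 1)
  n <- as.integer(n)
  mu <- .population_mu()
  with_seed(seed, {
    ps <- rtruncnorm(n, mu[["perturb_sensitivity"]],
                     .population$perturb_sensitivity$sd,
                     .population$perturb_sensitivity$lo,
                     .population$perturb_sensitivity$hi)
    ba <- rtruncnorm(n, mu[["block_start_amp"]],
                     .population$block_start_amp$sd,
                     .population$block_start_amp$lo,
                     .population$block_start_amp$hi)
    bs <- rtruncnorm(n, mu[["block_sensitivity"]],
                     .population$block_sensitivity$sd,
                     .population$block_sensitivity$lo,
                     .population$block_sensitivity$hi)
    bl <- rnorm(n, 400, 30)
    tibble::tibble(
      animal = seq_len(n),
      baseline_hr = bl,
      perturb_sensitivity = ps,
      control_sensitivity = ps,
      block_start_amp = ba,
      block_sensitivity = bs,
      tau = tau,
      rr_jitter_sd_ms = rr_jitter_sd_ms,
      max_drop = pmin(30 * ps, 0.9 * bl)
    )
  })
}

#' Turn one row of [sample_animals()] output into a `plant_params` object
#'
#' @param animal A one-row data frame (or list) with the [plant_params()] fields.
#' @return A `plant_params` object.
#' @export
as_plant_params <- function(animal) {
  if (inherits(animal, "plant_params")) return(animal)
  a <- as.list(animal)
  plant_params(baseline_hr = a$baseline_hr,
               perturb_sensitivity = a$perturb_sensitivity,
               control_sensitivity = a$control_sensitivity %||% a$perturb_sensitivity,
               block_start_amp = a$block_start_amp,
               block_sensitivity = a$block_sensitivity,
               tau = a$tau %||% 3,
               rr_jitter_sd_ms = a$rr_jitter_sd_ms %||% 2,
               max_drop = a$max_drop %||%
                 min(30 * a$perturb_sensitivity, 0.9 * a$baseline_hr))
}

#' KHFAC transmission factor
#'
#' Fraction of perturbation-evoked vagal activity transmitted past the block
#' electrode. Unity at or below the starting block current, then decreasing
#' linearly at a rate chosen so that, under maximal (30 Hz) perturbation, the
#' simulated heart-rate recovery slope versus block amplitude equals the
#' animal's `block_sensitivity`.
#'
#' @param amp Block amplitude(s), mA peak-to-peak, >= 0.
#' @param params A [plant_params()].
#' @return Transmission in \[0, 1\], vectorised over `amp`.
#' @export
transmission_factor <- function(amp, params) {
  params <- as_plant_params(params)
  check_finite(amp, "amp")
  if (any(amp < 0)) abort("`amp` must be >= 0.", class = "vagusloop_input_error")
  ifelse(amp <= params$block_start_amp, 1,
         clamp(1 - params$block_sensitivity * (amp - params$block_start_amp) /
                 params$max_drop, 0, 1))
}

#' Initialise plant state
#'
#' @param params A [plant_params()].
#' @param hr Initial heart rate (bpm, default the baseline).
#' @param t Initial time (s).
#' @return An object of class `plant_state`.
#' @export
plant_state <- function(params, hr = NULL, t = 0) {
  params <- as_plant_params(params)
  hr <- hr %||% params$baseline_hr
  structure(list(hr = hr, target_hr = hr, t = t, beat_phase = 0),
            class = "plant_state")
}

## Steady-state vagal drive for a given input combination. Saturation is
## applied to the perturbation pathway before the block transmission factor so
## that the recovery slope under maximal perturbation is exactly
## block_sensitivity for every animal.
plant_drive <- function(params, perturb_freq, f_stim, amp) {
  d_pert <- min(params$perturb_sensitivity * perturb_freq, params$max_drop) *
    transmission_factor(amp, params)
  clamp(d_pert + params$control_sensitivity * f_stim, 0, params$max_drop)
}

## Heart rate the plant settles to under constant inputs.
plant_steady_hr <- function(params, perturb_freq = 0, f_stim = 0, amp = 0) {
  params$baseline_hr - plant_drive(params, perturb_freq, f_stim, amp)
}

#' Advance the plant by one time step
#'
#' First-order relaxation of heart rate toward the target set by the current
#' vagal drive: `hr <- target + (hr - target) * exp(-dt / tau)`, with
#' `target = baseline_hr - D` and
#' `D = clamp(min(S_p * f_perturb, max_drop) * T(amp) + S_c * f_stim, 0, max_drop)`.
#' Block attenuates only the perturbation-evoked activity (the control
#' electrode is either stimulating or blocking, never both).
#'
#' @param state A [plant_state()].
#' @param command A [waveform_command()] (or `NULL` for no control output).
#' @param perturb_freq Perturbation-electrode stimulation frequency (Hz).
#' @param dt Time step (s), `0 < dt <= 0.05`.
#' @param params A [plant_params()].
#' @return The advanced `plant_state`.
#' @export
plant_step <- function(state, command, perturb_freq, dt, params) {
  params <- as_plant_params(params)
  stopifnot(inherits(state, "plant_state"))
  check_finite(dt, "dt"); check_finite(perturb_freq, "perturb_freq")
  if (dt <= 0 || dt > 0.05) abort("`dt` must be in (0, 0.05] s.",
                                  class = "vagusloop_input_error")
  f_stim <- 0; amp <- 0
  if (!is.null(command) && command$mode != "off") {
    if (command$mode == "stim") f_stim <- command$freq_hz else amp <- command$amp_ma
  }
  target <- params$baseline_hr - plant_drive(params, perturb_freq, f_stim, amp)
  state$target_hr <- target
  state$hr <- target + (state$hr - target) * exp(-dt / params$tau)
  state$beat_phase <- state$beat_phase + state$hr / 60 * dt
  state$t <- state$t + dt
  state
}

#' Emit R-event times from a heart-rate trace
#'
#' Integrates the instantaneous beat rate `hr / 60` over the trace and emits a
#' beat each time the integral crosses an integer (crossing times by linear
#' interpolation). Each inter-beat interval is then perturbed by
#' `Normal(0, rr_jitter_sd_ms)`, truncated so intervals stay above a 20 ms
#' physiological floor; the first beat time is left unjittered and the
#' perturbed intervals are re-accumulated.
#'
#' @param time_s Strictly increasing time grid (s).
#' @param hr_bpm Instantaneous heart rate at each grid point (bpm, > 0).
#' @param rr_jitter_sd_ms Jitter sd (ms); 0 gives the ideal beat times.
#' @param seed Optional seed for the jitter stream.
#' @return Numeric vector of strictly increasing R-event times (s).
#' @examples
#' b <- emit_beats(seq(0, 60, 0.05), rep(400, 1201))
#' length(b); diff(b)[1]
#' @export
emit_beats <- function(time_s, hr_bpm, rr_jitter_sd_ms = 0, seed = NULL) {
  check_finite(time_s, "time_s"); check_finite(hr_bpm, "hr_bpm")
  if (any(hr_bpm <= 0)) abort("`hr_bpm` must be > 0.", class = "vagusloop_input_error")
  if (any(diff(time_s) <= 0)) abort("`time_s` must be strictly increasing.",
                                    class = "vagusloop_input_error")
  # trapezoidal cumulative phase in beats
  dt <- diff(time_s)
  phase <- c(0, cumsum((head(hr_bpm, -1) + tail(hr_bpm, -1)) / 2 / 60 * dt))
  # small tolerance so a crossing landing on the grid end is not lost to
  # floating-point accumulation
  n_beats <- floor(phase[length(phase)] + 1e-9)
  if (n_beats < 1) return(numeric(0))
  ideal <- stats::approx(phase, time_s, xout = seq_len(n_beats), rule = 2)$y
  if (rr_jitter_sd_ms <= 0 || n_beats < 2) return(ideal)
  with_seed(seed, {
    iv <- diff(ideal) + rnorm(n_beats - 1L, 0, rr_jitter_sd_ms / 1000)
    iv <- pmax(iv, 0.02)
    c(ideal[1], ideal[1] + cumsum(iv))
  })
}
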