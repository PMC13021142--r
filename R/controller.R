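#' Fuzzy controller configuration
#'
#' Builds the configuration of the fuzzy logic controller that maps heart-rate
#' error and its slope to increments of the output coefficient `cout`. Positive
#' `cout` commands low-frequency stimulation (lowers heart rate); negative
#' `cout` commands KHFAC block (raises heart rate).
#'
#' The error axis is fuzzified into three zones -- Below, Near and Above the
#' setpoint -- by a mirrored pair of sigmoids with a complementary Near zone;
#' the error-slope axis into two complementary trapezoids, Increasing and
#' Decreasing. Five rules with singleton outputs in \[-1, 1\] are combined by
#' the centre-of-area formula, which for singletons reduces to
#' `sum(i(r) * o(r))` over the rules, `i(r)` being the product of the rule's
#' input memberships.
#'
#' @param gain Controller gain G in bpm/s. Because each per-update increment is
#'   `(gain / update_rate) * dcout` with `|dcout| <= 1`, `gain` is exactly the
#'   maximum rate of change of `cout` (and hence, through calibration, of the
#'   commanded heart-rate effect) in bpm per second.
#' @param update_rate Controller update rate in Hz (nominal 2).
#' @param setpoint Heart-rate setpoint in bpm.
#' @param error_below_mid,error_above_mid Sigmoid midpoints (bpm) of the Below
#'   and Above error zones; `error_below_mid < 0 < error_above_mid`.
#' @param error_steepness Shared sigmoid slope parameter k (1/bpm).
#' @param slope_decreasing_full Error slope (bpm/s) at or below which the
#'   Decreasing membership is 1.
#' @param slope_increasing_full Error slope (bpm/s) at or above which the
#'   Increasing membership is 1.
#' @param singletons Named numeric vector of the five rule outputs
#'   (`above_increasing`, `above_decreasing`, `near`, `below_increasing`,
#'   `below_decreasing`), each in \[-1, 1\].
#' @param cout_limits Length-2 numeric: clamp bounds for `cout`
#'   (anti-windup; must bracket 0).
#'
#' @return An object of class `fuzzy_config` (a validated list).
#' @examples
#' cfg <- fuzzy_config(gain = 5, setpoint = 300)
#' fuzzify(0, 0, cfg)
#' @export
fuzzy_config <- function(gain = 5,
                         update_rate = 2,
                         setpoint = 300,
                         error_below_mid = -5,
                         error_above_mid = 5,
                         error_steepness = 0.8,
                         slope_decreasing_full = -1,
                         slope_increasing_full = 1,
                         singletons = c(above_increasing = 1,
                                        above_decreasing = 0.4,
                                        near = 0,
                                        below_increasing = -0.4,
                                        below_decreasing = -1),
                         cout_limits = c(-200, 200)) {
  check_finite(gain, "gain"); check_finite(setpoint, "setpoint")
  check_finite(update_rate, "update_rate")
  if (gain <= 0) abort("`gain` must be > 0.", class = "vagusloop_config_error")
  if (update_rate <= 0) abort("`update_rate` must be > 0.", class = "vagusloop_config_error")
  if (setpoint <= 0) abort("`setpoint` must be > 0.", class = "vagusloop_config_error")
  if (!(error_below_mid < 0 && 0 < error_above_mid)) {
    abort("`error_below_mid` must be negative and `error_above_mid` positive.",
          class = "vagusloop_config_error")
  }
  if (error_steepness <= 0) abort("`error_steepness` must be > 0.", class = "vagusloop_config_error")
  if (!(slope_decreasing_full < slope_increasing_full)) {
    abort("`slope_decreasing_full` must be < `slope_increasing_full`.",
          class = "vagusloop_config_error")
  }
  needed <- c("above_increasing", "above_decreasing", "near",
              "below_increasing", "below_decreasing")
  if (!all(needed %in% names(singletons)) || length(singletons) != 5L) {
    abort("`singletons` must name exactly the 5 rules.", class = "vagusloop_config_error")
  }
  if (any(abs(singletons) > 1)) {
    abort("rule singletons must lie in [-1, 1].", class = "vagusloop_config_error")
  }
  if (singletons[["near"]] != 0) {
    abort("the Near rule singleton must be 0.", class = "vagusloop_config_error")
  }
  if (!(length(cout_limits) == 2L && cout_limits[1] < 0 && cout_limits[2] > 0)) {
    abort("`cout_limits` must bracket 0.", class = "vagusloop_config_error")
  }
  structure(
    list(gain = gain, update_rate = update_rate, setpoint = setpoint,
         error_below_mid = error_below_mid, error_above_mid = error_above_mid,
         error_steepness = error_steepness,
         slope_decreasing_full = slope_decreasing_full,
         slope_increasing_full = slope_increasing_full,
         singletons = singletons[needed], cout_limits = cout_limits),
    class = "fuzzy_config")
}

#' Heart-rate error
#'
#' `compute_error()` is the controller's first input: measured heart rate minus
#' setpoint, positive when the heart is running above the setpoint.
#'
#' @param hr Measured heart rate (bpm), non-negative.
#' @param setpoint Setpoint (bpm), positive.
#' @return Error in bpm.
#' @export
compute_error <- function(hr, setpoint) {
  check_finite(hr, "hr"); check_finite(setpoint, "setpoint")
  if (hr < 0) abort("`hr` must be >= 0.", class = "vagusloop_input_error")
  if (setpoint <= 0) abort("`setpoint` must be > 0.", class = "vagusloop_input_error")
  hr - setpoint
}

#' Slope of the heart-rate error
#'
#' The controller's second input: the difference between the last two error
#' samples divided by the update period (0.5 s at the nominal 2 Hz rate).
#'
#' @param err_now,err_prev Successive error samples (bpm).
#' @param dt Update period in seconds (default 0.5).
#' @return Slope in bpm/s.
#' @export
compute_slope <- function(err_now, err_prev, dt = 0.5) {
  check_finite(err_now, "err_now"); check_finite(err_prev, "err_prev")
  check_finite(dt, "dt")
  if (dt <= 0) abort("`dt` must be > 0.", class = "vagusloop_input_error")
  (err_now - err_prev) / dt
}

## raw membership curves ------------------------------------------------------

mf_below <- function(err, cfg) {
  1 / (1 + exp(cfg$error_steepness * (err - cfg$error_below_mid)))
}

mf_above <- function(err, cfg) {
  1 / (1 + exp(-cfg$error_steepness * (err - cfg$error_above_mid)))
}

mf_increasing <- function(slope, cfg) {
  clamp((slope - cfg$slope_decreasing_full) /
          (cfg$slope_increasing_full - cfg$slope_decreasing_full), 0, 1)
}

#' Fuzzify controller inputs
#'
#' Evaluates the five input membership values at a given error and error-slope.
#' `Near` is the complement `max(0, 1 - Below - Above)`, so the three error
#' memberships sum to 1 wherever Near is active; `Increasing + Decreasing = 1`
#' everywhere.
#'
#' @param err Heart-rate error (bpm).
#' @param slope Error slope (bpm/s).
#' @param config A [fuzzy_config()].
#' @return Named numeric vector with elements `below`, `near`, `above`,
#'   `increasing`, `decreasing`, each in \[0, 1\].
#' @export
fuzzify <- function(err, slope, config) {
  stopifnot(inherits(config, "fuzzy_config"))
  check_finite(err, "err"); check_finite(slope, "slope")
  below <- mf_below(err, config)
  above <- mf_above(err, config)
  near <- 1 - below - above
  if (near < 0) {
    # a valid config keeps below + above <= 1 up to rounding; a materially
    # negative complement means the midpoints are crossed
    if (near < -1e-9) {
      warn("Below + Above membership exceeds 1; check error midpoints.",
           class = "vagusloop_config_warning")
    }
    near <- 0
  }
  inc <- mf_increasing(slope, config)
  c(below = below, near = near, above = above,
    increasing = inc, decreasing = 1 - inc)
}

#' Defuzzify to a `cout` increment
#'
#' Centre-of-area combination of the five singleton rules:
#' `dcout = sum(i(r) * o(r))`, where for the four corner rules `i(r)` is the
#' product of the error-zone and slope-zone memberships and for the Near rule
#' (slope zone "Any") it is the Near membership alone. The result is clamped to
#' \[-1, 1\].
#'
#' @param memberships Named membership vector as returned by [fuzzify()].
#' @param config A [fuzzy_config()] supplying the rule singletons.
#' @return Dimensionless increment in \[-1, 1\].
#' @export
defuzzify <- function(memberships, config) {
  stopifnot(inherits(config, "fuzzy_config"))
  need <- c("below", "near", "above", "increasing", "decreasing")
  if (!all(need %in% names(memberships))) {
    abort("`memberships` must contain below/near/above/increasing/decreasing.",
          class = "vagusloop_config_error")
  }
  m <- memberships
  o <- config$singletons
  out <- m[["above"]] * m[["increasing"]] * o[["above_increasing"]] +
    m[["above"]] * m[["decreasing"]] * o[["above_decreasing"]] +
    m[["near"]] * o[["near"]] +
    m[["below"]] * m[["increasing"]] * o[["below_increasing"]] +
    m[["below"]] * m[["decreasing"]] * o[["below_decreasing"]]
  clamp(out, -1, 1)
}

#' Initialise controller state
#'
#' The controller starts neutral: `cout = 0`, no stored error (the first update
#' therefore sees a zero slope), zero updates.
#'
#' @param cout Initial output coefficient (default 0).
#' @return An object of class `controller_state`.
#' @export
controller_state <- function(cout = 0) {
  structure(list(cout = cout, prev_error = NA_real_, n_updates = 0L),
            class = "controller_state")
}

#' One controller update
#'
#' Performs a full 2 Hz-style update: error, slope from the stored previous
#' error, fuzzification, defuzzification, then
#' `cout <- clamp(cout + (gain / update_rate) * dcout)`. Because
#' `|dcout| <= 1`, `cout` can change by at most `gain` bpm-equivalents per
#' second, which is what makes the gain a physiological rate bound.
#'
#' @param hr Measured heart rate (bpm).
#' @param state A [controller_state()].
#' @param config A [fuzzy_config()].
#' @return A list with elements `state` (updated state), `dcout`, `err`,
#'   `slope` and `memberships`.
#' @examples
#' cfg <- fuzzy_config(gain = 10, setpoint = 300)
#' st <- controller_state()
#' out <- controller_step(350, st, cfg)
#' out$state$cout
#' @export
controller_step <- function(hr, state, config) {
  stopifnot(inherits(state, "controller_state"), inherits(config, "fuzzy_config"))
  err <- compute_error(hr, config$setpoint)
  slope <- if (is.na(state$prev_error)) 0 else
    compute_slope(err, state$prev_error, dt = 1 / config$update_rate)
  m <- fuzzify(err, slope, config)
  dcout <- defuzzify(m, config)
  new_cout <- clamp(state$cout + (config$gain / config$update_rate) * dcout,
                    config$cout_limits[1], config$cout_limits[2])
  state$cout <- new_cout
  state$prev_error <- err
  state$n_updates <- state$n_updates + 1L
  list(state = state, dcout = dcout, err = err, slope = slope, memberships = m)
}

#' Controller response surface
#'
#' Evaluates the defuzzified increment on a grid of error and slope values.
#' With the default rule table the surface shows four plateaus (a large and a
#' small change on each side) and a flat region around zero error.
#'
#' @param config A [fuzzy_config()].
#' @param err Numeric vector of error values (bpm).
#' @param slope Numeric vector of slope values (bpm/s).
#' @return A tibble with columns `err`, `slope`, `dcout`.
#' @export
fuzzy_surface <- function(config,
                          err = seq(-30, 30, by = 0.5),
                          slope = seq(-5, 5, by = 0.25)) {
  stopifnot(inherits(config, "fuzzy_config"))
  grid <- tidyr::expand_grid(err = err, slope = slope)
  grid$dcout <- purrr::map2_dbl(grid$err, grid$slope,
                                ~ defuzzify(fuzzify(.x, .y, config), config))
  grid
}
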