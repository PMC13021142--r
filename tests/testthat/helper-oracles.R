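# Independent oracles and fixture builders used across the suite.

# Brute-force centre-of-area sum over the 5 singleton rules, written as an
# explicit rule-table loop, independent of the package's vectorised path.
oracle_defuzz <- function(m, singletons) {
  rules <- list(
    list(e = "above", s = "increasing", o = singletons[["above_increasing"]]),
    list(e = "above", s = "decreasing", o = singletons[["above_decreasing"]]),
    list(e = "near",  s = NA,           o = singletons[["near"]]),
    list(e = "below", s = "increasing", o = singletons[["below_increasing"]]),
    list(e = "below", s = "decreasing", o = singletons[["below_decreasing"]])
  )
  total <- 0
  for (r in rules) {
    act <- m[[r$e]]
    if (!is.na(r$s)) act <- act * m[[r$s]]
    total <- total + act * r$o
  }
  min(max(total, -1), 1)
}

# Random valid membership map: error triple sums to <= 1, slope pair sums to 1.
random_membership <- function() {
  below <- runif(1)
  above <- runif(1, 0, 1 - below)
  inc <- runif(1)
  c(below = below, near = 1 - below - above, above = above,
    increasing = inc, decreasing = 1 - inc)
}

# Normalized-HR square-wave trace with exactly k above/below alternations:
# k + 1 excursion events alternating 70% / 30%, separated by in-band rests.
square_wave_trace <- function(k, dt = 0.5, duration = 840) {
  t <- seq(0, duration, by = dt)
  y <- rep(50, length(t))
  if (k >= 0) {
    n_events <- k + 1
    for (j in seq_len(n_events)) {
      lo <- 20 * j            # seconds
      idx <- t >= lo & t < lo + 10
      y[idx] <- if (j %% 2 == 1) 70 else 30
    }
  }
  tibble::tibble(time_s = t, hr_norm = y)
}

# Deterministic plant for exact-value checks.
noiseless_plant <- function(...) {
  plant_params(rr_jitter_sd_ms = 0, ...)
}
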