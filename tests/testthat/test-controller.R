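cfg <- fuzzy_config(gain = 5, setpoint = 350)

test_that("error and slope inputs follow their definitions", {
  expect_equal(compute_error(400, 350), 50)
  expect_equal(compute_error(350, 350), 0)
  expect_equal(compute_error(300, 350), -50)
  expect_error(compute_error(NaN, 350), class = "vagusloop_input_error")
  expect_error(compute_error(Inf, 350), class = "vagusloop_input_error")

  expect_equal(compute_slope(12, 10), 4)
  expect_equal(compute_slope(10, 10), 0)
  expect_equal(compute_slope(-3, 2), -10)
  expect_error(compute_slope(NA_real_, 1), class = "vagusloop_input_error")
})

test_that("fuzzification respects the membership-set geometry", {
  m0 <- fuzzify(0, 0, cfg)
  expect_gt(m0[["near"]], 0.9)
  expect_lt(m0[["below"]], 0.05)
  expect_lt(m0[["above"]], 0.05)
  expect_equal(m0[["increasing"]], 0.5)
  expect_equal(m0[["decreasing"]], 0.5)

  msat <- fuzzify(100, 10, cfg)
  expect_gt(msat[["above"]], 1 - 1e-12)
  expect_equal(msat[["increasing"]], 1)

  # sigmoid evaluated at its own midpoint is exactly 1/2
  mmid <- fuzzify(cfg$error_below_mid, 0, cfg)
  expect_equal(mmid[["below"]], 0.5)
  expect_equal(fuzzify(cfg$error_above_mid, 0, cfg)[["above"]], 0.5)

  # membership bounds and partition over a grid
  for (e in seq(-40, 40, by = 2.5)) {
    for (s in c(-5, -0.5, 0, 0.5, 5)) {
      m <- fuzzify(e, s, cfg)
      expect_true(all(m >= 0 & m <= 1))
      expect_lte(m[["below"]] + m[["near"]] + m[["above"]], 1 + 1e-12)
      if (m[["near"]] > 0) {
        expect_equal(unname(m[["below"]] + m[["near"]] + m[["above"]]), 1)
      }
      expect_equal(unname(m[["increasing"]] + m[["decreasing"]]), 1)
    }
  }
})

test_that("defuzzification reproduces hand-computed singleton sums", {
  # all activation on the Near rule
  expect_equal(defuzzify(c(below = 0, near = 1, above = 0,
                           increasing = 0.5, decreasing = 0.5), cfg), 0)
  # single saturated corner rule
  expect_equal(defuzzify(c(below = 0, near = 0, above = 1,
                           increasing = 1, decreasing = 0), cfg), 1)
  # mixed case: 0.6*0.5*1 + 0.6*0.5*0.4 + 0.4*0 = 0.42
  expect_equal(defuzzify(c(below = 0, near = 0.4, above = 0.6,
                           increasing = 0.5, decreasing = 0.5), cfg), 0.42)
})

test_that("defuzzification equals the brute-force rule-sum oracle", {
  set.seed(42)
  for (i in 1:1000) {
    m <- random_membership()
    expect_equal(defuzzify(m, cfg), oracle_defuzz(as.list(m), cfg$singletons),
                 tolerance = 1e-12)
  }
})

test_that("controller output has the correct sign outside the dead zone", {
  for (e in c(1, 2, 5, 20, 100)) {
    for (s in c(-8, -1, 0, 1, 8)) {
      expect_gte(defuzzify(fuzzify(e, s, cfg), cfg), 0)
      expect_lte(defuzzify(fuzzify(-e, s, cfg), cfg), 0)
    }
  }
  # inside the dead zone the output is negligible whatever the slope
  for (e in seq(-0.9, 0.9, by = 0.3)) {
    for (s in c(-8, 0, 8)) {
      expect_lt(abs(defuzzify(fuzzify(e, s, cfg), cfg)), 0.05)
    }
  }
  expect_lt(abs(defuzzify(fuzzify(0, 0, cfg), cfg)), 0.05)
})

test_that("output increment is continuous in the error input", {
  # Lipschitz bound from the sigmoid steepness: |d dcout / d err| <= 0.7 k
  step <- 0.01
  bound <- 1.5 * 0.7 * cfg$error_steepness * step
  for (s in c(-2, 0, 2)) {
    v <- vapply(seq(-30, 30, by = step),
                function(e) defuzzify(fuzzify(e, s, cfg), cfg), 0)
    expect_lt(max(abs(diff(v))), bound)
  }
})

test_that("response surface shows the four corner plateaus and a zero region", {
  surf <- fuzzy_surface(cfg, err = c(-30, 0, 30), slope = c(-5, 0, 5))
  at <- function(e, s) surf$dcout[surf$err == e & surf$slope == s]
  expect_equal(at(30, 5), 1, tolerance = 1e-6)      # above & increasing
  expect_equal(at(30, -5), 0.4, tolerance = 1e-6)   # above & decreasing
  expect_equal(at(-30, -5), -1, tolerance = 1e-6)   # below & decreasing
  expect_equal(at(-30, 5), -0.4, tolerance = 1e-6)  # below & increasing
  expect_lt(abs(at(0, 0)), 0.05)                    # dead zone
})

test_that("gain bounds the cout rate of change exactly", {
  for (G in c(2, 5, 10)) {
    c10 <- fuzzy_config(gain = G, setpoint = 300)
    st <- controller_state()
    # ramping input keeps (Above, Increasing) fully saturated: dcout = +1
    couts <- numeric(21)
    for (n in 0:20) {
      out <- controller_step(400 + n, st, c10)
      st <- out$state
      couts[n + 1] <- st$cout
    }
    expect_equal(max(abs(diff(couts))), G / c10$update_rate)
    per_second <- abs(couts[-(1:2)] - couts[seq_len(19)])
    expect_true(all(per_second <= G + 1e-12))
    expect_equal(max(per_second), G)
  }
})

test_that("cout accumulates increments and stays clamped", {
  # constant dcout = +1 at G = 2: 10 updates (5 s) add exactly 10 to cout
  c2 <- fuzzy_config(gain = 2, setpoint = 300)
  st <- controller_state()
  st <- controller_step(500, st, c2)$state   # prime the slope memory
  c0 <- st$cout
  for (n in 1:10) st <- controller_step(500 + n, st, c2)$state
  expect_equal(st$cout - c0, 10)
  expect_equal(st$n_updates, 11L)

  # at the setpoint with zero slope, cout stays put
  st2 <- controller_state()
  for (i in 1:20) st2 <- controller_step(300, st2, c2)$state
  expect_lt(abs(st2$cout), 0.05 * 20 * 1)  # dead-zone leakage only
  expect_equal(st2$prev_error, 0)

  # clamp limits are respected
  cl <- fuzzy_config(gain = 10, setpoint = 300, cout_limits = c(-15, 15))
  st3 <- controller_state()
  for (i in 1:50) st3 <- controller_step(500 + i, st3, cl)$state
  expect_equal(st3$cout, 15)
})

test_that("misconfigured controllers are rejected with named errors", {
  expect_error(fuzzy_config(gain = -1), class = "vagusloop_config_error")
  expect_error(fuzzy_config(update_rate = 0), class = "vagusloop_config_error")
  expect_error(fuzzy_config(error_below_mid = 3), class = "vagusloop_config_error")
  expect_error(fuzzy_config(singletons = c(above_increasing = 2, above_decreasing = 0.4,
                                           near = 0, below_increasing = -0.4,
                                           below_decreasing = -1)),
               class = "vagusloop_config_error")
  expect_error(defuzzify(c(bogus = 1), cfg), class = "vagusloop_config_error")
  # crossed midpoints (possible only by mutating a config) floor Near at 0
  # with a warning; any constructor-valid config keeps Below + Above <= 1
  bad <- cfg
  bad$error_below_mid <- 5
  bad$error_above_mid <- -5
  expect_warning(m <- fuzzify(0, 0, bad), class = "vagusloop_config_warning")
  expect_equal(unname(m[["near"]]), 0)
})
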