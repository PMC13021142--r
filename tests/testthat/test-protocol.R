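test_that("the default schedule reproduces the trial arithmetic", {
  s <- trial_schedule()
  expect_equal(schedule_duration(s), 840)
  expect_equal(perturb_freq_at(s, 60), 0)                # pre phase
  expect_equal(perturb_freq_at(s, 120 + 155), 16)        # 16th ramp-up step
  expect_equal(perturb_freq_at(s, 120), 1)               # ramp starts at 1 Hz
  expect_equal(max(perturb_freq_at(s, seq(0, 840, 0.5))), 30)
  expect_equal(perturb_freq_at(s, 419.9), 30)            # ramp-up peak
  expect_equal(perturb_freq_at(s, 420), 30)              # ramp-down start
  expect_equal(perturb_freq_at(s, 719.9), 1)             # ramp-down end
  expect_equal(perturb_freq_at(s, 800), 0)               # post phase
  # every step dwells 10 s
  f <- perturb_freq_at(s, seq(120, 419.5, by = 0.5))
  expect_equal(as.integer(table(f)), rep(20L, 30))
  expect_error(trial_schedule(ramp_up_s = 250), class = "vagusloop_config_error")
})

test_that("anchors come out at the plant's steady states and gate responsiveness", {
  p <- noiseless_plant(baseline_hr = 400, perturb_sensitivity = 9.2,
                       max_drop = 200)
  a <- measure_anchors(p)
  expect_equal(a$hr_0pct, 200, tolerance = 0.5)
  expect_equal(a$hr_100pct, 400, tolerance = 0.5)

  weak <- noiseless_plant(baseline_hr = 400, max_drop = 10)
  expect_error(measure_anchors(weak), class = "vagusloop_unresponsive_error")

  # reproducible under the same seed
  pj <- plant_params()
  expect_identical(measure_anchors(pj, seed = 5), measure_anchors(pj, seed = 5))
})

test_that("normalization is the linear anchor map", {
  a <- structure(list(hr_0pct = 200, hr_100pct = 400), class = "vns_anchors")
  expect_equal(normalize_hr(200, a), 0)
  expect_equal(normalize_hr(400, a), 100)
  expect_equal(normalize_hr(300, a), 50)
  expect_equal(normalize_hr(450, a), 125)  # may exceed the anchor range
})

test_that("the closed loop updates at the controller rate", {
  p <- plant_params()
  cal <- list(stim_sensitivity = 9.2, block_sensitivity = 64.3,
              block_start_amp = 1.8)
  cfg <- fuzzy_config(gain = 5, setpoint = 300)
  out <- vagusloop:::run_closed_loop(p, cfg, cal, 10, function(t) 0, seed = 2)
  expect_equal(out$n_updates, 20L)                       # 2 per second for 10 s
  expect_equal(nrow(out$record), 21L)                    # t = 0 row included
  expect_equal(diff(out$record$time_s), rep(0.5, 20))
})

test_that("a full trial is deterministic, complete and mode-consistent", {
  an <- sample_animals(1, seed = 5)
  tr1 <- run_trial(an, gain = 5, seed = 3)
  tr2 <- run_trial(an, gain = 5, seed = 3)
  expect_identical(tidy(tr1), tidy(tr2))

  expect_equal(nrow(tr1), 1681L)                         # 840 s at 2 Hz, t = 0 included
  expect_equal(attr(tr1, "n_updates"), 1680L)
  expect_setequal(unique(tr1$phase), c("pre", "ramp_up", "ramp_down", "post"))
  expect_equal(attr(tr1, "setpoint"),
               mean(unlist(attr(tr1, "anchors"))))

  # command mode equals the sign of cout at every logged step
  expect_true(all((tr1$cout > 0) == (tr1$mode == "stim")))
  expect_true(all((tr1$cout < 0) == (tr1$mode == "block")))
  expect_true(all((tr1$cout == 0) == (tr1$mode == "off")))
  expect_true(all(tr1$amp_ma[tr1$mode == "block"] >=
                    attr(tr1, "calib")$block_start_amp - 1e-9))

  # trial starts near the 100% anchor
  expect_gt(tr1$hr_norm[1], 95)
})

test_that("cout always pushes toward the band when well outside it", {
  an <- sample_animals(1, seed = 8)
  tr <- run_trial(an, gain = 5, seed = 11)
  hi <- tr$hr_norm > 60
  sustained_hi <- which(hi[-length(hi)] & hi[-1])
  expect_true(all(diff(tr$cout)[sustained_hi] >= -1e-9))
  lo <- tr$hr_norm < 40
  sustained_lo <- which(lo[-length(lo)] & lo[-1])
  expect_true(all(diff(tr$cout)[sustained_lo] <= 1e-9))
})

test_that("without control the heart rate sits at the 100% anchor", {
  an <- sample_animals(1, seed = 13)
  p <- as_plant_params(an)
  cal <- calibrate_plant(p, seed = 2)
  cfg <- fuzzy_config(gain = 5, setpoint = 300)
  out <- vagusloop:::run_closed_loop(p, cfg, cal, 60, function(t) 0,
                                     seed = 4, control = FALSE)
  expect_true(all(out$record$cout == 0))
  expect_true(all(out$record$mode == "off"))
  expect_equal(mean(out$record$hr_bpm), p$baseline_hr, tolerance = 0.01)

  # and the no-control reference trial is dominated by the perturbation
  trn <- run_trial(p, gain = 5, seed = 4, calib = cal, control = FALSE)
  expect_equal(trial_metrics(trn)$category, "Slow")
  expect_lt(min(trn$hr_norm), 20)
})
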