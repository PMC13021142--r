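test_that("stimulation fit recovers an exact line and flags degeneracy", {
  d <- tibble::tibble(freq_hz = 1:10, hr_bpm = 9.2 * (1:10))  # drops on a line
  fit <- fit_stim_calibration(d)
  expect_equal(fit$stim_sensitivity, 9.2)
  expect_equal(fit$stim_r2, 1)

  # the same line expressed as falling heart rate
  d2 <- tibble::tibble(freq_hz = 1:10, hr_bpm = 400 - 9.2 * (1:10))
  expect_equal(fit_stim_calibration(d2)$stim_sensitivity, 9.2)
  expect_equal(fit_stim_calibration(d2, baseline_hr = 400)$stim_sensitivity, 9.2)

  flat <- tibble::tibble(freq_hz = 1:6, hr_bpm = rep(300, 6))
  expect_warning(f0 <- fit_stim_calibration(flat),
                 class = "vagusloop_degenerate_fit_warning")
  expect_equal(f0$stim_sensitivity, 0)

  same <- tibble::tibble(freq_hz = rep(5, 4), hr_bpm = c(1, 2, 3, 4))
  expect_error(fit_stim_calibration(same), class = "vagusloop_degenerate_fit_error")
})

test_that("block fit finds the onset and recovery slope of an exact sweep", {
  # flat at 250 up to 1.8 mA, then rising at 64.3 bpm/mA toward baseline 400
  amps <- seq(0.1, 4.1, by = 0.1)
  hr <- 250 + 64.3 * pmax(amps - 1.8, 0)
  fit <- fit_block_calibration(tibble::tibble(amp_ma = amps, hr_bpm = hr),
                               baseline_hr = 400)
  expect_equal(fit$block_start_amp, 1.8, tolerance = 1e-9)
  expect_equal(fit$block_start_amp_grid, 1.8)
  expect_equal(fit$block_sensitivity, 64.3, tolerance = 1e-9)
  expect_equal(fit$block_r2, 1)

  # monotone rise from the very first amplitude
  hr2 <- 250 + 80 * amps
  fit2 <- fit_block_calibration(tibble::tibble(amp_ma = amps, hr_bpm = hr2),
                                baseline_hr = 600)
  expect_equal(fit2$block_start_amp, 0.0)
  expect_equal(fit2$block_sensitivity, 80, tolerance = 1e-9)

  # no rise at all
  expect_error(
    fit_block_calibration(tibble::tibble(amp_ma = amps, hr_bpm = rep(250, length(amps))),
                          baseline_hr = 400),
    class = "vagusloop_no_block_error")
  expect_error(
    fit_block_calibration(tibble::tibble(amp_ma = c(1, 1, 2), hr_bpm = c(1, 2, 3)),
                          baseline_hr = 400),
    class = "vagusloop_input_error")
})

test_that("cout converts to commands per the calibration arithmetic", {
  cal <- list(stim_sensitivity = 9.2, block_sensitivity = 64.3,
              block_start_amp = 1.8)
  cmd <- cout_to_command(18.4, cal)
  expect_equal(cmd$mode, "stim")
  expect_equal(cmd$freq_hz, 2)
  expect_equal(cmd$pulse_width_us, 50)

  expect_equal(cout_to_command(0, cal)$mode, "off")

  blk <- cout_to_command(-10, cal)
  expect_equal(blk$mode, "block")
  expect_equal(blk$amp_ma, 1.8 + 10 / 64.3)
  expect_equal(blk$freq_hz, 10000)

  # frequency clamp at 30 Hz and amplitude cap
  expect_equal(cout_to_command(1e4, cal)$freq_hz, 30)
  expect_equal(cout_to_command(-1e5, cal)$amp_ma, 10)
  expect_error(cout_to_command(NaN, cal), class = "vagusloop_input_error")
})

test_that("commands skip the block dead zone and are monotone in cout", {
  cal <- list(stim_sensitivity = 7.5, block_sensitivity = 40, block_start_amp = 1.2)
  couts <- seq(-80, 80, by = 0.5)
  freq <- amp <- numeric(length(couts))
  for (i in seq_along(couts)) {
    cmd <- cout_to_command(couts[i], cal)
    freq[i] <- if (cmd$mode == "stim") cmd$freq_hz else 0
    amp[i] <- if (cmd$mode == "block") cmd$amp_ma else NA
  }
  expect_true(all(amp[couts < 0] >= cal$block_start_amp))
  expect_true(all(diff(freq[couts > 0]) >= 0))
  expect_true(all(diff(amp[couts < 0]) <= 0))  # |cout| decreasing along the grid
})

test_that("simulated calibration recovers the generating animal", {
  p <- noiseless_plant()
  cal <- calibrate_plant(p)
  expect_equal(cal$stim_sensitivity, p$perturb_sensitivity, tolerance = 0.01)
  expect_gt(cal$stim_r2, 0.999)
  expect_equal(cal$block_start_amp, p$block_start_amp, tolerance = 0.05)
  expect_equal(cal$block_sensitivity, p$block_sensitivity, tolerance = 0.01 * 64.3)
  expect_gt(cal$block_r2, 0.999)

  # with beat jitter, across a handful of animals
  an <- sample_animals(5, seed = 21)
  for (i in 1:5) {
    pp <- as_plant_params(an[i, ])
    cc <- calibrate_plant(pp, seed = 300 + i)
    expect_lt(abs(cc$stim_sensitivity - pp$perturb_sensitivity) /
                pp$perturb_sensitivity, 0.10)
    expect_lt(abs(cc$block_start_amp - pp$block_start_amp), 0.1)
    expect_lt(abs(cc$block_sensitivity - pp$block_sensitivity) /
                pp$block_sensitivity, 0.15)
  }
})

test_that("a command built from cout moves steady-state heart rate by about cout", {
  an <- sample_animals(4, seed = 31)
  for (i in 1:4) {
    p <- as_plant_params(an[i, ])
    p$rr_jitter_sd_ms <- 0
    cal <- calibrate_plant(p)
    for (co in c(-60, -25, -5, 5, 25, 60)) {
      cmd <- cout_to_command(co, cal)
      if (co > 0) {
        dhr <- p$baseline_hr - vagusloop:::plant_steady_hr(p, 0, cmd$freq_hz, 0)
      } else {
        plateau <- vagusloop:::plant_steady_hr(p, 30, 0, 0)
        dhr <- vagusloop:::plant_steady_hr(p, 30, 0, cmd$amp_ma) - plateau
      }
      expect_lt(abs(abs(dhr) - abs(co)) / abs(co), 0.15)
    }
  }
})

test_that("tidy and glance summarise a calibration", {
  cal <- calibrate_plant(noiseless_plant())
  td <- tidy(cal)
  expect_equal(td$term, c("stim_sensitivity", "block_start_amp", "block_sensitivity"))
  expect_equal(nrow(glance(cal)), 1)
})
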