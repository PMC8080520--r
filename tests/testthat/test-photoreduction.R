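test_that("without light nothing evolves", {
  run <- run_photoreduction(light = illumination_params(k_exc = 0),
                            times = seq(0, 50, by = 1))
  expect_equal(diff(range(run$a610)), 0, tolerance = 1e-12)
  expect_equal(diff(range(run$a395)), 0, tolerance = 1e-12)
})

test_that("the excitation-rate calibration reproduces the 2 uM/s radical flux", {
  expect_equal(calibrate_k_exc(), 2.6, tolerance = 0.01)
  run <- run_photoreduction(mv_tot = 300e-6, times = seq(0, 30, by = 0.1))
  fl <- run$trajectory$fluxes
  i10 <- which.min(abs(run$trajectory$time - 10))
  i30 <- length(run$trajectory$time)
  prod <- unname(fl[i30, "q_ce"] - fl[i10, "q_ce"]) /
    (run$trajectory$time[i30] - run$trajectory$time[i10])
  expect_equal(prod, 2e-6, tolerance = 0.1)
})

test_that("without mediator the resting enzyme stalls at three electrons", {
  run <- run_photoreduction(mv_tot = 0, times = seq(0, 3000, by = 10))
  conc_end <- run$trajectory$conc[nrow(run$trajectory$conc), ]
  el <- ladder_electrons(conc_end) / 30e-6
  expect_gt(el, 2); expect_lt(el, 3.05)
  ladder <- conc_end[c(paste0("T1o", 0:3), paste0("T1r", 0:3))]
  expect_identical(names(which.max(ladder)), "T1r2")
  expect_lt(conc_end[["T1r3"]] + conc_end[["MVad"]], 0.05 * 30e-6)
})

test_that("T1-reduction timing follows its closed forms and accelerates >10x with mediator", {
  ## constant trace never reaches the criterion
  flat <- time_to_t1_reduction(0:10, rep(0.168, 11), 0.168)
  expect_true(is.na(flat$time))
  ## single exponential: t = -ln(0.02)/r
  r <- 0.05; tt <- seq(0, 200, by = 0.1)
  ex <- time_to_t1_reduction(tt, 0.17 * exp(-r * tt), 0.17)
  expect_equal(ex$time, -log(0.02) / r, tolerance = 0.02)

  run300 <- run_photoreduction(mv_tot = 300e-6, times = seq(0, 200, by = 0.5))
  run0 <- run_photoreduction(mv_tot = 0, times = seq(0, 12000, by = 20))
  t300 <- time_to_t1_reduction(run300$trajectory$time, run300$a610,
                               run300$t1_a610_initial)$time
  t0 <- time_to_t1_reduction(run0$trajectory$time, run0$a610,
                             run0$t1_a610_initial)$time
  expect_gt(t0 / t300, 10)
})

test_that("reduction rate is linear in mediator concentration", {
  mvs <- c(0, 50e-6, 150e-6, 300e-6)
  rates <- vapply(mvs, function(mv) {
    tt <- if (mv == 0) seq(0, 12000, by = 20) else seq(0, 800, by = 1)
    run <- run_photoreduction(mv_tot = mv, times = tt)
    time_to_t1_reduction(run$trajectory$time, run$a610, run$t1_a610_initial)$rate
  }, 0)
  expect_gt(summary(lm(rates ~ mvs))$r.squared, 0.99)
})

test_that("the radical lag tracks the fourth-electron uptake and shrinks with mediator", {
  runs <- lapply(c(50e-6, 150e-6, 300e-6), function(mv) {
    run_photoreduction(mv_tot = mv, times = seq(0, 800, by = 1))
  })
  lags <- vapply(runs, function(r) {
    mv_lag_time(r$trajectory$time, r$a610, r$a395, r$t1_a610_initial)
  }, 0)
  expect_true(all(diff(lags) < 0))

  ## electron bookkeeping cross-check at 50 uM: the lag matches the time to
  ## push one enzyme equivalent of electrons at the radical production rate
  run <- runs[[1]]
  tt <- run$trajectory$time
  t_red <- time_to_t1_reduction(tt, run$a610, run$t1_a610_initial)$time
  fl <- run$trajectory$fluxes
  in_lag <- tt >= t_red & tt <= t_red + lags[1]
  prod <- diff(range(fl[in_lag, "q_ce"])) / diff(range(tt[in_lag]))
  expect_equal(lags[1], 30e-6 / prod, tolerance = 0.2)

  ## no enzyme: the radical rises essentially immediately (the finite
  ## detection threshold registers within a few seconds)
  run0 <- run_photoreduction(lac_tot = 0, mv_tot = 50e-6,
                             times = seq(0, 100, by = 0.5))
  expect_lt(mv_lag_time(run0$trajectory$time, run0$a610, run0$a395,
                        run0$t1_a610_initial), 10)
})

test_that("the viologen adduct sink withholds roughly one enzyme equivalent of radical", {
  tt <- seq(0, 1200, by = 2)
  with_sink <- run_photoreduction(mv_tot = 50e-6, times = tt)
  no_sink <- run_photoreduction(ladder_params(k_sink = 0), mv_tot = 50e-6, times = tt)
  d <- tail(species_conc(no_sink$trajectory, "MVr"), 1) -
    tail(species_conc(with_sink$trajectory, "MVr"), 1)
  expect_gt(d / 30e-6, 0.6); expect_lt(d / 30e-6, 1.25)
})

test_that("every donated electron is accounted for", {
  run <- run_photoreduction(mv_tot = 50e-6, times = seq(0, 400, by = 1),
                            rtol = 1e-10, atol = 1e-18)
  conc <- run$trajectory$conc
  ## exact balance: donor oxidations = electrons in the enzyme + free radical
  ## - oxidized sensitizer still awaiting its donor electron
  edox <- conc[, "EDox"]
  stored <- ladder_electrons(conc) + conc[, "MVr"] - conc[, "Ru3"]
  i <- edox > 1e-8
  expect_lt(max(abs(edox[i] - stored[i]) / edox[i]), 1e-6)
})

test_that("the photon-flux bound on enzyme reduction is a plain quotient", {
  expect_equal(max_enzyme_reduction_rate(2e-6, 30e-6), 0.0667, tolerance = 0.01)
  expect_equal(max_enzyme_reduction_rate(0, 30e-6), 0)
  expect_equal(max_enzyme_reduction_rate(2e-6, 15e-6),
               2 * max_enzyme_reduction_rate(2e-6, 30e-6))
  expect_error(max_enzyme_reduction_rate(2e-6, 0), class = "division_error")
})
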