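test_that("oxygen is untouched without light and follows 2e-/O2 stoichiometry without enzyme", {
  dark <- run_aerobic(light = illumination_params(k_exc = 0, edta_tot = 1e-3),
                      lac_tot = 0, times = seq(0, 60, by = 1))
  expect_equal(diff(range(dark$o2)), 0, tolerance = 1e-12)

  free <- run_aerobic(lac_tot = 0, times = seq(0, 200, by = 0.5))
  fl <- free$trajectory$fluxes
  last <- fl[nrow(fl), ]
  o2_consumed <- free$o2[1] - free$o2[length(free$o2)]
  ## 2 radicals oxidized per O2 consumed, 1 H2O2 per O2 consumed
  expect_equal(last[["B"]] / o2_consumed, 2, tolerance = 1e-3)
  expect_equal(tail(free$h2o2, 1) / o2_consumed, 1, tolerance = 1e-3)
  expect_equal(h2o2_yield(free), 1, tolerance = 1e-3)
})

test_that("initial rate extraction is exact on ramps and robust to noise", {
  t <- seq(0, 100, by = 1)
  expect_equal(initial_o2_rate(t, rep(250e-6, 101)), 0, tolerance = 1e-15)
  expect_equal(initial_o2_rate(t, 250e-6 - 2e-6 * t), 2e-6, tolerance = 1e-9)
  set.seed(9)
  noisy <- 250e-6 - 2e-6 * t + rnorm(101, sd = 1e-6)
  fit <- lm(noisy ~ t)
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(initial_o2_rate(t, noisy, window = c(0, 100)) - 2e-6), 2 * se)
  expect_error(initial_o2_rate(t, noisy, window = c(50, 500)), class = "range_error")
})

test_that("a modest enzyme load halves-and-more the oxygen consumption and kills peroxide", {
  free <- run_aerobic(lac_tot = 0, times = seq(0, 300, by = 0.5))
  withE <- run_aerobic(lac_tot = 16e-6, times = seq(0, 300, by = 0.5))
  expect_lt(initial_o2_rate(withE$time, withE$o2),
            0.6 * initial_o2_rate(free$time, free$o2))
  expect_lt(h2o2_yield(withE) / h2o2_yield(free), 0.3)
})

test_that("full enzyme routing gives the 4e-/O2 stoichiometric half rate at equal radical flux", {
  relay0 <- relay_scheme_params(kq_EnT = 0, ru_tot = 30e-6, mv_tot = 1e-3)
  li <- illumination_params(edta_tot = 10e-3)
  free <- run_aerobic(aerobic_params(phi_direct = 0), light = li, relay = relay0,
                      lac_tot = 0, times = seq(0, 100, by = 0.5))
  routed <- run_aerobic(aerobic_params(phi_direct = 0, k_dism = 0), light = li,
                        relay = relay0, lac_tot = 30e-6,
                        times = seq(0, 100, by = 0.5))
  ratio <- initial_o2_rate(routed$time, routed$o2, window = c(30, 70)) /
    initial_o2_rate(free$time, free$o2, window = c(30, 70))
  expect_equal(ratio, 0.5, tolerance = 0.02)
})

test_that("superoxide, not the radical, is the dominant enzyme reductant", {
  run <- run_aerobic(lac_tot = 16e-6, times = seq(0, 300, by = 1))
  expect_gt(superoxide_route_share(run), 0.5)

  ab <- pathway_ablation(lac_tot = 16e-6, times = seq(0, 300, by = 1))
  expect_identical(ab$dominant_route, "superoxide_route")
  expect_gt(ab$deviation[["superoxide_route"]], ab$deviation[["mv_route"]])
  expect_error(pathway_ablation(which = "no_such_route", both = FALSE,
                                lac_tot = 16e-6, times = seq(0, 10, by = 1)),
               class = "configuration_error")
})

test_that("zeroing both routes recovers the enzyme-free oxygen profile", {
  tt <- seq(0, 150, by = 1)
  free <- run_aerobic(lac_tot = 0, times = tt)
  aer00 <- aerobic_params(k_ad = 0, k_iet_adduct = 0, k_red_MV = 0,
                          phi_direct = 0)
  ## keep the excited-state quench identical by removing enzyme quenching too
  relay0 <- relay_scheme_params(kq_EnT = 0, ru_tot = 30e-6, mv_tot = 1e-3)
  both0 <- run_aerobic(aer00, relay = relay0, lac_tot = 16e-6, times = tt)
  free0 <- run_aerobic(aerobic_params(phi_direct = 0), relay = relay0,
                       lac_tot = 0, times = tt)
  expect_lt(max(abs(both0$o2 - free0$o2)), 1e-9)
  expect_lt(max(abs(free$o2 - free0$o2)) / 250e-6, 0.2)  # enzyme quench is minor
})

test_that("the adduct mechanism matches its steady-state effective rate at trace superoxide", {
  aer <- aerobic_params()
  li <- illumination_params(k_exc = 0, edta_tot = 0)
  relay <- relay_scheme_params(kq_EnT = 0, mv_tot = 0)
  netA <- aerobic_network(aer, li, relay)
  netS <- aerobic_network(aerobic_params(adduct_mode = FALSE,
                                         k_super_simple = effective_superoxide_rate(aer)),
                          li, relay)
  init <- stats::setNames(numeric(nrow(netA$species)), netA$species$id)
  init[c("O2m", "E0")] <- c(0.2e-6, 10e-6)
  tg <- seq(0, 20, by = 0.2)
  trA <- simulate(netA, init, tg)
  trS <- simulate(netS, init, tg)
  upA <- rowSums(trA$conc[, paste0("E", 1:4)]) +
    rowSums(trA$conc[, paste0("AD", 1:3)])
  upS <- rowSums(trS$conc[, paste0("E", 1:4)])
  i <- tg > 1
  expect_lt(max(abs(upA[i] - upS[i]) / upS[i]), 0.05)
})

test_that("superoxide-mediated T1 reduction is invisible on the 1 ms flash window", {
  aer <- aerobic_params()
  li <- illumination_params(k_exc = 0, edta_tot = 0)
  relay <- relay_scheme_params(kq_EnT = 0)
  net <- aerobic_network(aer, li, relay)
  init <- stats::setNames(numeric(nrow(net$species)), net$species$id)
  init[c("Ru", "MV2", "O2", "E0")] <- c(25e-6, 10e-3, 250e-6, 16e-6)
  init[c("MVr", "Ru3")] <- 1.52e-6
  tr <- simulate(net, init, c(0, 10^seq(-7, -3, length.out = 50)),
                 track_fluxes = TRUE)
  last <- tr$fluxes[nrow(tr$fluxes), ]
  super <- sum(last[paste0("iet", 0:3)])
  ## compare against the anaerobic mediator-route amplitude (~0.7 uM)
  expect_lt(super / 0.7e-6, 0.05)
})

test_that("oxygen bookkeeping closes exactly and the light can be switched off", {
  run <- run_aerobic(lac_tot = 16e-6, times = seq(0, 200, by = 1))
  bk <- o2_bookkeeping(run)
  expect_lt(abs(bk$residual) / max(bk$consumed, 1e-12), 1e-6)

  run_off <- run_aerobic(lac_tot = 0, times = seq(0, 120, by = 1), light_off = 40)
  i_dark <- run_off$time > 60
  ## after the light goes out (and transients relax) oxygen stops moving
  expect_lt(diff(range(run_off$o2[i_dark])) / 250e-6, 1e-3)
  expect_lt(max(run_off$o2), 255e-6)
})
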