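test_that("pre-flash binding equilibrium solves the quadratic exactly", {
  expect_equal(unname(preflash_equilibrium(0, 15e-6, 37e-6)["complex"]), 0)
  expect_equal(unname(preflash_equilibrium(Inf, 15e-6, 37e-6)["complex"]), 15e-6)
  eq <- preflash_equilibrium(4750, 15e-6, 37e-6)
  ## root of Ka (Ru-C)(L-C) = C, ~2.13 uM at the study totals
  expect_equal(4750 * eq[["ru_free"]] * eq[["lac_free"]], eq[["complex"]],
               tolerance = 1e-10)
  expect_equal(eq[["complex"]], 2.13e-6, tolerance = 0.005)
})

test_that("the flash partitions excitation over the ground-state populations", {
  state <- c(Ru = 8.75e-6, RuS = 0, Ru3 = 0, L = 30e-6, Lred = 0,
             C = 1.25e-6, CS = 0, Ccs = 0)
  out <- flash_initialize(state, flash_pulse(0))
  expect_identical(out, state)
  ## 12.5% complexed, 9.7 uM excited -> 1.21 uM in-complex, 8.49 uM free
  out2 <- flash_initialize(state, flash_pulse(9.7e-6))
  expect_equal(out2[["CS"]], 9.7e-6 * 0.125)
  expect_equal(out2[["RuS"]], 9.7e-6 * 0.875)
  expect_equal(out2[["Ru"]] + out2[["RuS"]] + out2[["C"]] + out2[["CS"]],
               state[["Ru"]] + state[["C"]])
  ## all sensitizer complexed -> all excitation lands in the complex
  state_all <- state; state_all[["Ru"]] <- 0; state_all[["C"]] <- 10e-6
  out3 <- flash_initialize(state_all, flash_pulse(4e-6))
  expect_equal(out3[["CS"]], 4e-6); expect_equal(out3[["RuS"]], 0)
  expect_error(flash_initialize(state, flash_pulse(1)), class = "configuration_error")
})

test_that("without charge separation the direct scheme leaves no products", {
  p <- direct_scheme_params(k_cs = 0)
  run <- run_direct_scheme(p, flash_pulse(9.7e-6), flash_grid(100))
  n <- length(run$a450)
  expect_lt(abs(run$a450[n]), 1e-8)
  expect_lt(abs(run$a610[n]), 1e-8)
  expect_lt(species_conc(run$trajectory, "Lred")[n], 1e-15)
  expect_equal(css_yield(run$trajectory, flash_pulse(9.7e-6)), 0, tolerance = 1e-6)
})

test_that("yield helpers reproduce the printed arithmetic", {
  expect_equal(branch_yield(1e5, 0), 100)
  expect_equal(branch_yield(1e5, 1e5), 50)
  expect_equal(branch_yield(1.2e5, 1.8e6), 6.25)
  expect_error(branch_yield(0, 0), class = "undefined_yield_error")
  expect_error(css_yield(toy_trajectory(0, list(RuS = 0, Ru3 = 0)), flash_pulse(0)),
               class = "undefined_yield_error")
})

test_that("css yield is monotone in the branching rates", {
  pulse <- flash_pulse(9.7e-6)
  tg <- flash_grid(80)
  base <- direct_scheme_params()
  y <- function(p) css_yield(run_direct_scheme(p, pulse, tg)$trajectory, pulse)
  y0 <- y(base)
  expect_gt(y(direct_scheme_params(k_off = 2 * base$k_off)), y0)
  expect_lt(y(direct_scheme_params(k_br = 2 * base$k_br)), y0)
})

test_that("pure energy transfer leaves both channels flat at long times", {
  ## enzyme quenching at the fitted bimolecular constant, charge separation off
  p <- direct_scheme_params(k_cs = 0, kq_EnT = 6.1e9)
  run <- run_direct_scheme(p, flash_pulse(9.7e-6), flash_grid(100))
  n <- length(run$a450)
  expect_lt(abs(run$a450[n]), 1e-8)
  expect_lt(abs(run$a610[n]), 1e-8)
})

test_that("the relay scheme mirrors, branches and responds to the enzyme", {
  tg <- flash_grid(120)
  pulse <- flash_pulse(7.8e-6)

  ## no cage escape -> no radical, no oxidized sensitizer beyond the flash
  r0 <- run_relay_scheme(relay_scheme_params(phi_ce = 0, lac_tot = 0), pulse, tg)
  expect_lt(max(species_conc(r0$trajectory, "MVr")), 1e-15)
  expect_lt(max(species_conc(r0$trajectory, "Ru3")), 1e-15)

  ## enzyme-free: radical and oxidized sensitizer are stoichiometric mirrors
  rm <- run_relay_scheme(relay_scheme_params(lac_tot = 0), pulse, tg)
  expect_lt(max(abs(species_conc(rm$trajectory, "Ru3") -
                    species_conc(rm$trajectory, "MVr"))), 1e-12)

  ## more enzyme accelerates radical decay and slows sensitizer recovery
  r16 <- run_relay_scheme(relay_scheme_params(lac_tot = 16e-6), pulse, tg)
  r30 <- run_relay_scheme(relay_scheme_params(lac_tot = 30e-6), pulse, tg)
  mid <- which.min(abs(tg - 1e-4))
  expect_lt(species_conc(r30$trajectory, "MVr")[mid],
            species_conc(r16$trajectory, "MVr")[mid])
  expect_lt(abs(r16$a450[mid]), abs(r30$a450[mid]) + 1e-12)
  expect_gt(abs(r30$a450[length(tg)]), abs(rm$a450[length(tg)]))

  ## simulated radical quantum yield close to the reported 19.5%
  ry <- relay_yields(r16$trajectory, pulse)
  expect_equal(unname(ry["mv_yield"]), 19.5, tolerance = 0.02)
  expect_gt(unname(ry["t1_yield"]), 40)
  ## no enzyme -> no T1 reduction
  expect_equal(unname(relay_yields(rm$trajectory, pulse)["t1_yield"]), 0)
})
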