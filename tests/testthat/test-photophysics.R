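cpl <- default_couples()

test_that("driving forces follow the sign convention and the printed potentials", {
  expect_equal(driving_force(cpl$t1, cpl$t1), 0)
  expect_equal(driving_force(cpl$ru_excited, cpl$t1), -1.52)
  expect_equal(driving_force(cpl$t1, cpl$ru_ground), -0.58)
  expect_equal(driving_force(cpl$mv, cpl$t1), -1.13)
  ## bipyrazine charge separation sits ~1 eV lower
  expect_equal(driving_force(cpl$bpz_excited, cpl$t1), -0.55)
  ## antisymmetry under donor/acceptor swap
  for (pair in list(c("ru_excited", "t1"), c("mv", "t1"), c("t1", "ru_ground"))) {
    expect_equal(driving_force(cpl[[pair[1]]], cpl[[pair[2]]]),
                 -driving_force(cpl[[pair[2]]], cpl[[pair[1]]]))
  }
})

test_that("quench fraction interpolates between 0 and 1", {
  expect_equal(quench_fraction(6.1e9, 600e-9, 0), 0)
  expect_equal(quench_fraction(6.1e9, 600e-9, 37e-6), 0.119, tolerance = 0.005)
  expect_equal(quench_fraction(1e12, 1, 1), 1, tolerance = 1e-6)
})

test_that("Stern-Volmer fits recover the quenching constant", {
  ## constant lifetime over quencher -> zero slope (exact data, so lm warns
  ## about a perfect fit; that is the point here)
  f0 <- suppressWarnings(stern_volmer_fit(c(0, 5e-3, 10e-3), rep(600e-9, 3)))
  expect_equal(f0$kq, 0, tolerance = 1e-6)
  ## two printed lifetimes give the derived constant
  f2 <- suppressWarnings(stern_volmer_fit(c(0, 10e-3), c(600e-9, 110e-9)))
  expect_equal(f2$kq, (1 / 110e-9 - 1 / 600e-9) / 0.01, tolerance = 1e-9)
  ## synthetic five-point data with 1% lifetime noise recovers within 5%
  set.seed(11)
  q <- c(0, 50e-6, 100e-6, 150e-6, 200e-6)
  tau <- 1 / (1 / 600e-9 + 6.1e9 * q) * (1 + rnorm(5, sd = 0.01))
  f3 <- stern_volmer_fit(q, tau)
  expect_equal(f3$kq, 6.1e9, tolerance = 0.05)
  expect_error(stern_volmer_fit(rep(1e-3, 3), c(1, 2, 3) * 1e-9), class = "fit_error")
})

test_that("Forster rates obey the defining R0 property and decay as r^-6", {
  fp <- forster_params(R0 = 2.6, tau0 = 600e-9)
  expect_equal(forster_rate(2.6, fp), 1 / 600e-9)
  expect_equal(forster_rate(5.2, fp), (1 / 600e-9) / 64)
  expect_equal(forster_rate(1.12, fp), 2.6e8, tolerance = 0.01)
  r <- seq(0.5, 6, by = 0.25)
  expect_true(all(diff(forster_rate(r, fp)) < 0))
  expect_error(forster_rate(0, fp), class = "domain_error")
  ## spin suppression is a plain multiplicative factor
  expect_equal(forster_rate(2.6, forster_params(spin_factor = 0.01)),
               0.01 / 600e-9)
})

test_that("Marcus rates peak at -lambda and are symmetric about the apex", {
  mp <- marcus_params(lambda = 1.05)
  k_apex <- marcus_rate(-1.05, mp)
  for (x in c(0.1, 0.3, 0.7)) {
    expect_equal(marcus_rate(-1.05 + x, mp), marcus_rate(-1.05 - x, mp),
                 tolerance = 1e-12)
    expect_lt(marcus_rate(-1.05 + x, mp), k_apex)
  }
  ## ratio of the two charge-separation rates at equal coupling matches the
  ## printed pair 8.5e6 / 6.6e6
  ratio <- marcus_rate(-1.52, mp) / marcus_rate(-0.55, mp)
  expect_equal(ratio, 8.5 / 6.6, tolerance = 0.03)
  ## strictly decreasing in distance; inverted region beyond lambda
  r <- seq(3, 20, by = 1)
  expect_true(all(diff(marcus_rate(-1.0, mp, r)) < 0))
  g <- seq(-1.05, -2.5, by = -0.1)
  expect_true(all(diff(vapply(g, marcus_rate, 0, params = mp)) < 0))
})

test_that("reorganization energy is recovered in closed form", {
  ## equal rates symmetric about the apex
  f <- marcus_fit_lambda(c(1e7, 1e7), c(-0.6, -1.4), c("a", "a"))
  expect_equal(f$lambda, 1.0, tolerance = 1e-9)

  ## the four printed intra-complex rates give 1.05 eV
  f2 <- marcus_fit_lambda(c(8.5e6, 6.6e6, 1.8e6, 1.2e6),
                          c(-1.52, -0.55, -0.58, -1.55),
                          class = c("cs", "cs", "br", "br"))
  expect_equal(round(f2$lambda, 2), 1.05)
  expect_equal(f2$lambda_refined, f2$lambda, tolerance = 0.01)

  ## exact synthetic rates at lambda = 0.80 eV, arbitrary couplings per class
  lam <- 0.80; kbt <- kBT_eV(298)
  g <- c(0.3, 0.7, 1.1, 1.5)
  cls <- c("a", "a", "b", "b")
  pref <- c(a = 1e12, b = 3e10)
  k <- pref[cls] * exp(-(lam - g)^2 / (4 * lam * kbt))
  f3 <- marcus_fit_lambda(k, -g, cls)
  expect_equal(f3$lambda, 0.80, tolerance = 1e-6)

  expect_error(marcus_fit_lambda(c(1e7, 2e7), c(-0.5, -0.5), c("a", "a")),
               class = "inconsistent_data_error")
  expect_error(marcus_fit_lambda(1e7, -0.5, "a"), class = "fit_error")
})

test_that("distance inference inverts the rate and respects the coupling decay", {
  mp <- marcus_params(lambda = 1.05, V0 = 0.02, beta = 1.1, r0 = 3)
  k12 <- marcus_rate(-1.0, mp, r = 12)
  expect_equal(marcus_infer_distance(k12, -1.0, mp), 12, tolerance = 1e-6)

  ## doubling beta halves (r - r0) at a fixed rate
  mp2 <- marcus_params(lambda = 1.05, V0 = 0.02, beta = 2.2, r0 = 3)
  r1 <- marcus_infer_distance(k12, -1.0, mp)
  r2 <- marcus_infer_distance(k12, -1.0, mp2)
  expect_equal(r2 - 3, (r1 - 3) / 2, tolerance = 1e-6)

  ## the documented default coupling places the printed charge-separation
  ## rate in the 12.5-13.5 Angstrom window (calibration, not ground truth)
  r_cs <- marcus_infer_distance(8.5e6, -1.52, mp)
  expect_gt(r_cs, 12.5); expect_lt(r_cs, 13.5)

  expect_error(marcus_infer_distance(1e15, -1.05, mp), class = "infeasible_rate_error")
})

test_that("detailed balance converts the IET rate ratio to ~0.216 eV", {
  expect_equal(equilibrium_delta_g(1, 1), 0)
  expect_equal(equilibrium_delta_g(1, 4500), 0.216, tolerance = 0.005)
  expect_equal(equilibrium_delta_g(4500, 1), -equilibrium_delta_g(1, 4500))
  expect_error(equilibrium_delta_g(0, 1), class = "domain_error")
})

test_that("the Forster/Marcus crossing sits below the docking distance", {
  fp <- forster_params(R0 = 2.6, tau0 = 600e-9)
  mp <- marcus_params(lambda = 1.05, V0 = 0.02, beta = 1.1, r0 = 3)
  cx <- rate_crossing_distance(fp, mp, delta_g = -1.52)
  expect_length(cx, 1L)
  expect_lt(cx, 11.2)
  ## rates really do cross there
  expect_equal(forster_rate(cx / 10, fp), marcus_rate(-1.52, mp, cx),
               tolerance = 1e-6)
  ## with transfer switched off there is no crossing
  expect_length(rate_crossing_distance(forster_params(spin_factor = 0), mp, -1.52), 0L)
})
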