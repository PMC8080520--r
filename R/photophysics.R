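#' Closed-form photophysics: driving forces, quenching, Forster and Marcus
#'
#' Conventions: redox potentials in V vs NHE; energies in eV; the free-energy
#' change of an electron transfer is `dG = -(E_acceptor - E_donor)` so that
#' negative means exergonic and the "driving force" quoted in the literature
#' is `-dG`. Marcus rates use the classical (high-temperature) nonadiabatic
#' expression; distances are in Angstrom, Forster radii in nm.
#'
#' @name photophysics
NULL

#' A redox couple
#' @param label free-text label
#' @param potential midpoint potential, V vs NHE
#' @return a `redox_couple`
#' @export
redox_couple <- function(label, potential) {
  stopifnot(is.finite(potential))
  structure(list(label = label, potential = potential), class = "redox_couple")
}

#' Redox couples of the system
#'
#' Potentials (V vs NHE): excited and ground couples of the bipyridine and
#' bipyrazine sensitizers, the laccase T1 copper, and methyl viologen
#' (standard literature value, configurable).
#' @return named list of `redox_couple`s
#' @export
default_couples <- function() {
  list(
    ru_excited  = redox_couple("Ru3+/Ru2+*", -0.84),
    ru_ground   = redox_couple("Ru3+/Ru2+", 1.26),
    t1          = redox_couple("T1 Cu2+/Cu+", 0.68),
    bpz_excited = redox_couple("Ru(bpz)3+/2+*", 0.13),
    bpz_ground  = redox_couple("Ru(bpz)3+/2+", 2.23),
    mv          = redox_couple("MV2+/MV.+", -0.45)
  )
}

#' Free-energy change of an electron transfer between two couples
#'
#' @param donor_couple,acceptor_couple `redox_couple` objects (or bare
#'   potentials in V) on the same reference scale
#' @return dG in eV; negative = exergonic
#' @examples
#' driving_force(-0.84, 0.68)  # -1.52 eV
#' @export
driving_force <- function(donor_couple, acceptor_couple) {
  ed <- if (inherits(donor_couple, "redox_couple")) donor_couple$potential else donor_couple
  ea <- if (inherits(acceptor_couple, "redox_couple")) acceptor_couple$potential else acceptor_couple
  -(ea - ed)
}

#' Fraction of excited states quenched by a bimolecular quencher
#'
#' Stern-Volmer competition of bimolecular quenching against intrinsic decay:
#' `kq [Q] tau0 / (1 + kq [Q] tau0)`. This bounds the product yield if every
#' quenching event were reactive.
#'
#' @param kq bimolecular quenching constant, M^-1 s^-1
#' @param tau0 unquenched excited-state lifetime, s
#' @param q_conc quencher concentration, M
#' @return dimensionless fraction in \[0, 1\]
#' @export
quench_fraction <- function(kq, tau0, q_conc) {
  stopifnot(kq >= 0, tau0 >= 0, q_conc >= 0)
  x <- kq * q_conc * tau0
  x / (1 + x)
}

#' Stern-Volmer fit of lifetime-vs-quencher data
#'
#' Linear fit of `1/tau` against `[Q]`: the slope is the bimolecular
#' quenching constant, the intercept `1/tau0`.
#'
#' @param q_conc quencher concentrations, M (>= 2 distinct values)
#' @param lifetimes excited-state lifetimes, s (> 0)
#' @return list with `kq`, `kq_se`, `tau0`, and the `lm` fit
#' @export
stern_volmer_fit <- function(q_conc, lifetimes) {
  stopifnot(length(q_conc) == length(lifetimes), all(lifetimes > 0))
  if (length(unique(q_conc)) < 2) {
    pl_error("Stern-Volmer fit needs >= 2 distinct quencher concentrations", "fit_error")
  }
  rate <- 1 / lifetimes
  fit <- stats::lm(rate ~ q_conc)
  co <- summary(fit)$coefficients
  list(kq = unname(co["q_conc", "Estimate"]),
       kq_se = unname(co["q_conc", "Std. Error"]),
       tau0 = 1 / unname(co["(Intercept)", "Estimate"]),
       fit = fit)
}

#' Forster transfer parameters
#' @param R0 Forster radius, nm (> 0)
#' @param tau0 donor lifetime, s (> 0)
#' @param spin_factor optional multiplicative suppression of the transfer
#'   rate (spin-statistics arguments suggest values < 1; default 1)
#' @return a `forster_params`
#' @export
forster_params <- function(R0 = 2.6, tau0 = 600e-9, spin_factor = 1) {
  stopifnot(R0 > 0, tau0 > 0, spin_factor >= 0)
  structure(list(R0 = R0, tau0 = tau0, spin_factor = spin_factor),
            class = "forster_params")
}

#' Forster resonance energy transfer rate at distance r
#'
#' `k(r) = (1/tau0) (R0/r)^6`, optionally scaled by the spin factor. By
#' construction `k(R0) = 1/tau0`.
#'
#' @param r donor-acceptor distance, nm (> 0)
#' @param params a `forster_params`
#' @return rate in s^-1
#' @export
forster_rate <- function(r, params = forster_params()) {
  if (any(r <= 0)) pl_error("distance must be > 0", "domain_error")
  params$spin_factor * (1 / params$tau0) * (params$R0 / r)^6
}

#' Marcus parameters
#'
#' @param lambda reorganization energy, eV (> 0)
#' @param V0 electronic coupling at contact, eV
#' @param beta exponential decay constant of the coupling, 1/Angstrom (> 0)
#' @param r0 contact distance, Angstrom
#' @param temperature K (> 0)
#' @return a `marcus_params`
#' @export
marcus_params <- function(lambda = 1.05, V0 = 0.02, beta = 1.1, r0 = 3,
                          temperature = 298) {
  stopifnot(lambda > 0, beta > 0, temperature > 0, V0 >= 0, r0 >= 0)
  structure(list(lambda = lambda, V0 = V0, beta = beta, r0 = r0,
                 temperature = temperature), class = "marcus_params")
}

#' Nonadiabatic classical Marcus rate
#'
#' `k = (2 pi / hbar) H_AB^2 (4 pi lambda kB T)^(-1/2)
#'      exp(-(dG + lambda)^2 / (4 lambda kB T))`
#' with distance-dependent coupling `H_AB = V0 exp(-beta (r - r0)/2)`.
#' Maximal (activationless) at `dG = -lambda`; symmetric about that apex,
#' hence the inverted region at `|dG| > lambda`.
#'
#' @param delta_g free-energy change, eV (negative = exergonic)
#' @param params a `marcus_params`
#' @param r donor-acceptor distance, Angstrom (default: contact, `r0`)
#' @return rate in s^-1
#' @export
marcus_rate <- function(delta_g, params = marcus_params(), r = params$r0) {
  kbt <- kBT_eV(params$temperature)
  hab <- params$V0 * exp(-params$beta * (r - params$r0) / 2)
  pre <- (2 * pi / .hbar_eV_s) * hab^2 / sqrt(4 * pi * params$lambda * kbt)
  pre * exp(-(delta_g + params$lambda)^2 / (4 * params$lambda * kbt))
}

#' Reorganization energy from rate pairs (closed-form pairwise solution)
#'
#' For two rates `k1, k2` of the same reaction class (equal electronic
#' coupling) measured at driving forces `|dG1|, |dG2|`,
#' `ln(k1/k2) = ((lambda-|dG2|)^2 - (lambda-|dG1|)^2) / (4 lambda kB T)`
#' is linear in lambda after expansion:
#' `lambda = (dG2^2 - dG1^2) / (4 kB T ln(k1/k2) - 2 (|dG1| - |dG2|))`.
#' All within-class pairs are solved and the per-class solutions averaged;
#' an optional least-squares refinement over all points shares one lambda
#' across classes with a free per-class coupling prefactor. Because the
#' coupling cancels within a class, the closed-form inference is
#' coupling-independent by construction.
#'
#' @param rates rates in s^-1
#' @param delta_g free-energy changes in eV (signs are dropped; supply the
#'   exergonic driving-force magnitudes or the signed dG)
#' @param class reaction-class labels (e.g. `"cs"`/`"br"`), same coupling
#'   assumed within a class
#' @param temperature K
#' @param refine run the shared-lambda least-squares refinement (default TRUE)
#' @return list with `lambda` (mean of per-pair closed forms), `per_pair`
#'   data.frame, `lambda_refined`, and per-class effective couplings
#'   `log_prefactor` from the refinement
#' @examples
#' marcus_fit_lambda(c(8.5e6, 6.6e6, 1.8e6, 1.2e6),
#'                   c(-1.52, -0.55, -0.58, -1.55),
#'                   class = c("cs", "cs", "br", "br"))$lambda  # ~1.05 eV
#' @export
marcus_fit_lambda <- function(rates, delta_g, class, temperature = 298,
                              refine = TRUE) {
  stopifnot(length(rates) == length(delta_g), length(class) == length(rates),
            all(rates > 0))
  kbt <- kBT_eV(temperature)
  g <- abs(delta_g)
  pairs <- list()
  for (cl in unique(class)) {
    idx <- which(class == cl)
    if (length(idx) < 2) {
      pl_error(sprintf("class '%s' needs >= 2 observations", cl), "fit_error")
    }
    cmb <- utils::combn(idx, 2)
    for (p in seq_len(ncol(cmb))) {
      i <- cmb[1, p]; j <- cmb[2, p]
      if (abs(g[i] - g[j]) < 1e-12) {
        if (abs(log(rates[i] / rates[j])) > 1e-9) {
          pl_error("equal driving forces with unequal rates are inconsistent",
                   "inconsistent_data_error")
        }
        next
      }
      lnr <- log(rates[i] / rates[j])
      lam <- (g[j]^2 - g[i]^2) / (4 * kbt * lnr - 2 * (g[i] - g[j]))
      if (!is.finite(lam) || lam <= 0) {
        pl_error("pairwise solution gives non-positive reorganization energy",
                 "domain_error")
      }
      pairs[[length(pairs) + 1L]] <- data.frame(class = cl, i = i, j = j,
                                                lambda = lam)
    }
  }
  if (!length(pairs)) pl_error("no informative rate pairs", "fit_error")
  per_pair <- do.call(rbind, pairs)
  lambda_cf <- mean(per_pair$lambda)

  out <- list(lambda = lambda_cf, per_pair = per_pair,
              temperature = temperature)
  if (refine) {
    ## shared-lambda fit of ln k = a_class - (lambda - |dG|)^2 / (4 lambda kBT),
    ## with the per-class intercepts profiled out analytically
    obj <- function(lam) {
      act <- -(lam - g)^2 / (4 * lam * kbt)
      res <- 0
      for (cl in unique(class)) {
        idx <- which(class == cl)
        r <- log(rates[idx]) - act[idx]
        res <- res + sum((r - mean(r))^2)
      }
      res
    }
    opt <- stats::optimize(obj, interval = c(max(1e-3, lambda_cf / 5), lambda_cf * 5))
    lam <- opt$minimum
    act <- -(lam - g)^2 / (4 * lam * kbt)
    prefs <- vapply(unique(class), function(cl) {
      idx <- which(class == cl)
      mean(log(rates[idx]) - act[idx])
    }, 0)
    out$lambda_refined <- lam
    out$log_prefactor <- prefs
  }
  out
}

#' Invert the Marcus rate for the donor-acceptor distance
#'
#' Monotone decreasing in the rate; fails with an infeasible-rate error when
#' the requested rate exceeds the value at contact distance.
#'
#' @param rate observed rate, s^-1 (> 0)
#' @param delta_g free-energy change, eV
#' @param params a `marcus_params` with coupling (V0, beta, r0) set
#' @param r_max upper bracket in Angstrom (default 100)
#' @return distance in Angstrom
#' @export
marcus_infer_distance <- function(rate, delta_g, params = marcus_params(),
                                  r_max = 100) {
  stopifnot(rate > 0)
  k_contact <- marcus_rate(delta_g, params, r = params$r0)
  if (rate > k_contact) {
    pl_error(sprintf("rate %.3g exceeds the contact-distance maximum %.3g",
                     rate, k_contact), "infeasible_rate_error")
  }
  f <- function(r) log(marcus_rate(delta_g, params, r)) - log(rate)
  stats::uniroot(f, lower = params$r0, upper = r_max, tol = 1e-10)$root
}

#' Free-energy change from a forward/backward rate ratio
#'
#' `dG = -kB T ln(k_forward / k_backward)`; the detailed-balance estimate
#' used for the endergonic third internal electron-transfer step of the
#' resting-oxidized enzyme (k+/k- ~ 1/4500 gives +0.216 eV at 298 K).
#'
#' @param k_forward,k_backward rates, s^-1 (> 0)
#' @param temperature K
#' @return dG in eV
#' @export
equilibrium_delta_g <- function(k_forward, k_backward, temperature = 298) {
  if (k_forward <= 0 || k_backward <= 0) {
    pl_error("rates must be positive", "domain_error")
  }
  -kBT_eV(temperature) * log(k_forward / k_backward)
}

#' Distances where the Forster and Marcus rate curves cross
#'
#' Scans `[r0, 5 R0]` (Angstrom) for sign changes of
#' `forster_rate(r) - marcus_rate(dG, r)` and polishes each bracket with
#' bisection. Returns an empty vector when the curves do not cross.
#'
#' @param forster a `forster_params` (R0 in nm)
#' @param marcus a `marcus_params`
#' @param delta_g free-energy change for the electron transfer, eV
#' @param n_grid scan resolution
#' @return numeric vector of crossing distances in Angstrom (possibly empty)
#' @export
rate_crossing_distance <- function(forster, marcus, delta_g, n_grid = 2000) {
  r_lo <- max(marcus$r0, 1e-3)
  r_hi <- 5 * forster$R0 * 10  # nm -> Angstrom
  if (r_hi <= r_lo) pl_error("empty search interval", "configuration_error")
  rg <- seq(r_lo, r_hi, length.out = n_grid)
  f <- function(r) {
    fr <- forster_rate(r / 10, forster)  # Angstrom -> nm
    mr <- marcus_rate(delta_g, marcus, r)
    log(fr) - log(mr)
  }
  vals <- vapply(rg, f, 0)
  if (all(abs(vals) < 1e-12)) {
    pl_error("rate functions are identical on the interval", "inconsistent_data_error")
  }
  crossings <- numeric()
  sgn <- sign(vals)
  for (i in seq_len(length(rg) - 1L)) {
    if (sgn[i] == 0) { crossings <- c(crossings, rg[i]); next }
    if (sgn[i] * sgn[i + 1L] < 0) {
      crossings <- c(crossings, stats::uniroot(f, lower = rg[i], upper = rg[i + 1L],
                                               tol = 1e-9)$root)
    }
  }
  unique(crossings)
}
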