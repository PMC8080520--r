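#' Anaerobic continuous-illumination photoreduction
#'
#' Under continuous light with a sacrificial donor (EDTA), the sensitizer
#' cycles and feeds electrons into the enzyme either through the viologen
#' radical or through a low-yield direct branch on the enzyme quench event.
#' The enzyme is an eight-state redox ladder: oxidized/reduced T1 crossed
#' with 0-3 electrons on the trinuclear cluster (TNC). Internal electron
#' transfer (IET) moves an electron from reduced T1 to the TNC; the third
#' TNC reduction is strongly endergonic in the resting-oxidized enzyme
#' (k+/k- ~ 1/4500), which produces the viologen-radical lag after T1 is
#' bleached. A slow 1:1 viologen adduct on the fully reduced enzyme removes
#' part of the mediator pool from circulation.
#'
#' @name continuous_photoreduction
NULL

.t1_ox_states <- paste0("T1o", 0:3)
.t1_red_states <- paste0("T1r", 0:3)

#' Redox-ladder parameters
#'
#' @param k_plus forward IET rates (s^-1) for steps `T1r_n -> T1o_{n+1}`,
#'   n = 0,1,2; defaults 1 s^-1 (first two steps close to equilibrium, the
#'   analysis is insensitive above ~0.1 s^-1)
#' @param k_minus backward IET rates (s^-1); default `c(1, 1, 4500)` making
#'   the third TNC reduction endergonic with K = 1/4500
#' @param k_red_MV viologen radical -> any oxidized-T1 state, M^-1 s^-1
#' @param phi_direct productive fraction of enzyme quench events of the
#'   excited sensitizer (effective low-yield direct reduction branch)
#' @param k_sink viologen + fully-reduced-enzyme adduct formation,
#'   M^-1 s^-1 (1:1, irreversible on the experiment timescale)
#' @return a `ladder_params`
#' @export
ladder_params <- function(k_plus = c(1, 1, 1), k_minus = c(1, 1, 4500),
                          k_red_MV = 3.8e8, phi_direct = 0.0075,
                          k_sink = 1e4) {
  stopifnot(length(k_plus) == 3, length(k_minus) == 3,
            all(k_plus >= 0), all(k_minus >= 0), k_red_MV >= 0, k_sink >= 0,
            phi_direct >= 0, phi_direct <= 1)
  structure(list(k_plus = k_plus, k_minus = k_minus, k_red_MV = k_red_MV,
                 phi_direct = phi_direct, k_sink = k_sink),
            class = "ladder_params")
}

#' Continuous-illumination parameters
#'
#' @param k_exc effective excitation rate per ground-state sensitizer under
#'   the lamp, s^-1. The default is calibrated with
#'   [calibrate_k_exc()] so the viologen-radical production rate matches
#'   2 uM/s in the 300 uM viologen reference configuration.
#' @param k_EDTA oxidized sensitizer + EDTA, M^-1 s^-1 (single-electron,
#'   irreversible, product inert)
#' @param edta_tot donor total, M
#' @return an `illumination_params`
#' @export
illumination_params <- function(k_exc = 2.6, k_EDTA = 1e7, edta_tot = 10e-3) {
  stopifnot(k_exc >= 0, k_EDTA >= 0, edta_tot >= 0)
  structure(list(k_exc = k_exc, k_EDTA = k_EDTA, edta_tot = edta_tot),
            class = "illumination_params")
}

#' Calibrate the effective excitation rate
#'
#' Solves the steady-state branching identity
#' `rate_MVr = k_exc * [Ru] * f_MV * phi_ce` for `k_exc`, where `f_MV` is
#' the fraction of excitations quenched by the viologen against intrinsic
#' decay and enzyme quenching.
#'
#' @param target_rate viologen-radical production rate, M/s (default 2e-6)
#' @param mv_conc reference viologen concentration, M (default 300e-6)
#' @param relay a `relay_scheme_params` (supplies kq_MV, phi_ce, k0, kq_EnT)
#' @param ru_tot,lac_tot reference totals, M
#' @return k_exc in s^-1
#' @export
calibrate_k_exc <- function(target_rate = 2e-6, mv_conc = 300e-6,
                            relay = relay_scheme_params(kq_EnT = 6.1e9),
                            ru_tot = 30e-6, lac_tot = 30e-6) {
  q_mv <- relay$kq_MV * mv_conc
  f_mv <- q_mv / (relay$k0 + q_mv + relay$kq_EnT * lac_tot)
  target_rate / (ru_tot * f_mv * relay$phi_ce)
}

#' Reaction network of the anaerobic photoreduction regime
#'
#' @param ladder a `ladder_params`
#' @param light an `illumination_params`
#' @param relay a `relay_scheme_params` (photogeneration block; set
#'   `kq_EnT` > 0 here, the direct branch is a fraction of those quench
#'   events)
#' @return a `reaction_network`
#' @export
photoreduction_network <- function(ladder, light, relay) {
  species <- data.frame(
    id = c("Ru", "RuS", "Ru3", "ED", "EDox", "MV2", "MVr",
           .t1_ox_states, .t1_red_states, "MVad"),
    role = c("sensitizer ground", "sensitizer excited", "sensitizer oxidized",
             "donor", "donor oxidized", "mediator", "mediator radical",
             paste("enzyme T1ox TNC", 0:3), paste("enzyme T1red TNC", 0:3),
             "viologen adduct on fully reduced enzyme")
  )
  rxn <- list(
    list(id = "exc",    reactants = c(Ru = 1), products = c(RuS = 1), k = light$k_exc),
    list(id = "decay",  reactants = c(RuS = 1), products = c(Ru = 1), k = relay$k0),
    list(id = "q_ce",   reactants = c(RuS = 1, MV2 = 1), products = c(Ru3 = 1, MVr = 1),
         k = relay$kq_MV * relay$phi_ce),
    list(id = "q_nc",   reactants = c(RuS = 1, MV2 = 1), products = c(Ru = 1, MV2 = 1),
         k = relay$kq_MV * (1 - relay$phi_ce)),
    list(id = "edta",   reactants = c(Ru3 = 1, ED = 1), products = c(Ru = 1, EDox = 1),
         k = light$k_EDTA),
    list(id = "rec_mv", reactants = c(MVr = 1, Ru3 = 1), products = c(MV2 = 1, Ru = 1),
         k = relay$k_rec_MV)
  )
  for (n in 0:3) {
    ox <- paste0("T1o", n); red <- paste0("T1r", n)
    rxn <- c(rxn, list(
      list(id = paste0("mvred", n),
           reactants = stats::setNames(c(1, 1), c("MVr", ox)),
           products = stats::setNames(c(1, 1), c("MV2", red)),
           k = ladder$k_red_MV),
      list(id = paste0("direct", n),
           reactants = stats::setNames(c(1, 1), c("RuS", ox)),
           products = stats::setNames(c(1, 1), c("Ru3", red)),
           k = relay$kq_EnT * ladder$phi_direct),
      list(id = paste0("ent", n),
           reactants = stats::setNames(c(1, 1), c("RuS", ox)),
           products = stats::setNames(c(1, 1), c("Ru", ox)),
           k = relay$kq_EnT * (1 - ladder$phi_direct))
    ))
  }
  for (n in 0:2) {
    red <- paste0("T1r", n); ox_next <- paste0("T1o", n + 1)
    rxn <- c(rxn, list(
      list(id = paste0("ietf", n), reactants = stats::setNames(1, red),
           products = stats::setNames(1, ox_next), k = ladder$k_plus[n + 1]),
      list(id = paste0("ietb", n), reactants = stats::setNames(1, ox_next),
           products = stats::setNames(1, red), k = ladder$k_minus[n + 1])
    ))
  }
  rxn <- c(rxn, list(
    list(id = "sink", reactants = c(MV2 = 1, T1r3 = 1), products = c(MVad = 1),
         k = ladder$k_sink)
  ))
  build_network(species, rxn)
}

#' Run the anaerobic photoreduction regime
#'
#' @param ladder a `ladder_params`
#' @param light an `illumination_params`
#' @param relay a `relay_scheme_params` with `kq_EnT` set (default 6.1e9
#'   here: the direct branch rides on enzyme quench events)
#' @param ru_tot,lac_tot,mv_tot totals, M (reference configuration: 30 uM
#'   sensitizer and enzyme, 10 mM donor)
#' @param times time grid, s
#' @param eps extinction set
#' @param track_fluxes keep the reaction-flux ledger (default TRUE; used by
#'   the electron bookkeeping)
#' @param ... passed to [simulate()]
#' @return list: `trajectory`, `a610`, `a395`, `t1_a610_initial` (the T1
#'   component of the initial 610 nm absorbance)
#' @export
run_photoreduction <- function(ladder = ladder_params(),
                               light = illumination_params(),
                               relay = relay_scheme_params(kq_EnT = 6.1e9),
                               ru_tot = 30e-6, lac_tot = 30e-6, mv_tot = 50e-6,
                               times = seq(0, 600, by = 0.5),
                               eps = default_extinctions(),
                               track_fluxes = TRUE, ...) {
  net <- photoreduction_network(ladder, light, relay)
  init <- stats::setNames(numeric(nrow(net$species)), net$species$id)
  init[["Ru"]] <- ru_tot
  init[["ED"]] <- light$edta_tot
  init[["MV2"]] <- mv_tot
  init[["T1o0"]] <- lac_tot  # resting-oxidized enzyme, fully oxidized
  traj <- simulate(net, init, times, track_fluxes = track_fluxes, ...)
  a610 <- eps$eps_t1_610 * rowSums(traj$conc[, .t1_ox_states, drop = FALSE]) +
    eps$eps_mvr_605 * traj$conc[, "MVr"]
  a395 <- eps$eps_mvr_395 * traj$conc[, "MVr"]
  list(trajectory = traj, a610 = a610, a395 = a395,
       t1_a610_initial = eps$eps_t1_610 * lac_tot)
}

#' Time to complete T1 reduction, and its reciprocal rate
#'
#' First time the 610 nm absorbance falls below a threshold fraction
#' (default 2%) of its initial T1 component.
#'
#' @param time time grid, s
#' @param a610 absorbance trace
#' @param t1_a610_initial initial T1 component of the absorbance
#' @param threshold fraction (default 0.02)
#' @return list: `time` (s; NA when never reached), `rate` (1/s)
#' @export
time_to_t1_reduction <- function(time, a610, t1_a610_initial, threshold = 0.02) {
  idx <- which(a610 < threshold * t1_a610_initial)
  if (!length(idx)) return(list(time = NA_real_, rate = NA_real_))
  t <- time[idx[1]]
  list(time = t, rate = 1 / t)
}

#' Lag between complete T1 reduction and radical accumulation
#'
#' Interval between the T1-reduction time (610 nm criterion) and the first
#' sustained rise of the 395 nm band above baseline + 3 sigma.
#'
#' @param time time grid, s
#' @param a610,a395 traces from one run
#' @param t1_a610_initial initial T1 component at 610 nm
#' @param sigma noise standard deviation of the 395 nm channel (0 for
#'   noiseless simulations; a small absolute floor is applied)
#' @param sustain number of consecutive above-threshold samples required
#' @return lag in seconds; NA when the radical never rises
#' @export
mv_lag_time <- function(time, a610, a395, t1_a610_initial, sigma = 0,
                        sustain = 3L) {
  red <- time_to_t1_reduction(time, a610, t1_a610_initial)
  t_red <- if (is.na(red$time)) time[1] else red$time
  base <- a395[1]
  ## during fourth-electron uptake the radical sits on a small
  ## production-limited plateau; "accumulation" means the bulk rise, so the
  ## threshold is baseline + 3 sigma with a floor of 5% of the excursion
  thr <- base + max(3 * sigma, 0.05 * max(abs(a395 - base), 1e-12))
  above <- a395 > thr
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ok <- which(run$values & run$lengths >= sustain)
  if (!length(ok)) return(NA_real_)
  t_rise <- time[starts[ok[1]]]
  max(0, t_rise - t_red)
}

#' Upper bound on the enzyme photoreduction rate
#'
#' The mediator production rate divided by the enzyme concentration: the
#' fastest per-enzyme reduction rate the photon flux can sustain.
#'
#' @param mv_production_rate M/s
#' @param enzyme_conc M, > 0
#' @return s^-1
#' @export
max_enzyme_reduction_rate <- function(mv_production_rate, enzyme_conc) {
  if (enzyme_conc <= 0) pl_error("enzyme concentration must be > 0", "division_error")
  mv_production_rate / enzyme_conc
}

#' Electrons stored in the enzyme ladder of a trajectory state
#'
#' @param conc one row (named) or the full concentration matrix
#' @return numeric: total enzyme-stored electrons (M equivalents); the
#'   viologen adduct on the fully reduced enzyme counts its 4 electrons
#' @export
ladder_electrons <- function(conc) {
  if (is.null(dim(conc))) conc <- matrix(conc, nrow = 1, dimnames = list(NULL, names(conc)))
  el <- numeric(nrow(conc))
  for (n in 0:3) {
    el <- el + n * conc[, paste0("T1o", n)] + (n + 1) * conc[, paste0("T1r", n)]
  }
  if ("MVad" %in% colnames(conc)) el <- el + 4 * conc[, "MVad"]
  el
}
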