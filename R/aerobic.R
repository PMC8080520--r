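#' Aerobic photocatalysis: superoxide routing and oxygen turnover
#'
#' With dioxygen present the viologen radical is intercepted by O2 to form
#' superoxide, which either dismutates to O2 + H2O2 or reduces the enzyme
#' through a reversible protein adduct with slow internal electron
#' transfer. The catalytically cycling enzyme is an electron counter
#' E0..E4 (aerobic IET is fast and nearly isoenergetic, so the anaerobic
#' eight-state ladder collapses); the fully reduced enzyme turns O2 over to
#' two waters. Flux ledgers track where every electron and oxygen molecule
#' ends up.
#'
#' @name aerobic_o2
NULL

.enzyme_states <- paste0("E", 0:4)
.adduct_states <- paste0("AD", 0:3)

#' Aerobic parameters
#'
#' @param k_B viologen radical + O2 -> superoxide, M^-1 s^-1
#' @param k_dism effective superoxide dismutation (second order in
#'   superoxide, protons implicit in the buffered medium), M^-1 s^-1
#' @param k_red_MV viologen radical + enzyme state, M^-1 s^-1
#' @param k_ad,k_mad superoxide-enzyme adduct formation / dissociation
#'   (M^-1 s^-1, s^-1)
#' @param k_iet_adduct internal electron transfer from the adduct, s^-1;
#'   the effective bimolecular constant
#'   `k_ad * k_iet / (k_mad + k_iet)` must stay below 5e6 M^-1 s^-1
#' @param k_F fully reduced enzyme + O2 -> oxidized enzyme + 2 H2O,
#'   M^-1 s^-1
#' @param phi_direct productive fraction of enzyme quench events (direct
#'   reduction branch, as anaerobically)
#' @param o2_initial dissolved oxygen at light-on, M (default 250 uM)
#' @param adduct_mode TRUE for the reversible-adduct realization; FALSE
#'   replaces it by a single effective bimolecular step at
#'   `k_super_simple`
#' @param k_super_simple effective superoxide -> enzyme constant used when
#'   `adduct_mode = FALSE`, M^-1 s^-1 (<= 5e6)
#' @return an `aerobic_params`
#' @export
aerobic_params <- function(k_B = 6.6e8, k_dism = 1e7, k_red_MV = 3.8e8,
                           k_ad = 1e8, k_mad = 1e4, k_iet_adduct = 100,
                           k_F = 2e6, phi_direct = 0.0075,
                           o2_initial = 250e-6, adduct_mode = TRUE,
                           k_super_simple = 1e6) {
  vals <- c(k_B, k_dism, k_red_MV, k_ad, k_mad, k_iet_adduct, k_F,
            o2_initial, k_super_simple)
  if (any(vals < 0)) pl_error("aerobic rates must be >= 0", "validation_error")
  stopifnot(phi_direct >= 0, phi_direct <= 1)
  p <- list(k_B = k_B, k_dism = k_dism, k_red_MV = k_red_MV, k_ad = k_ad,
            k_mad = k_mad, k_iet_adduct = k_iet_adduct, k_F = k_F,
            phi_direct = phi_direct, o2_initial = o2_initial,
            adduct_mode = adduct_mode, k_super_simple = k_super_simple)
  eff <- effective_superoxide_rate(p)
  if (eff > 5e6 * (1 + 1e-9)) {
    pl_error(sprintf("effective superoxide->enzyme rate %.3g exceeds 5e6 M^-1 s^-1", eff),
             "validation_error")
  }
  structure(p, class = "aerobic_params")
}

#' Effective bimolecular superoxide-to-enzyme rate of the adduct mechanism
#'
#' Steady-state elimination of the adduct:
#' `k_eff = k_ad * k_iet / (k_mad + k_iet)`.
#'
#' @param params an `aerobic_params` (or plain list with the three rates)
#' @return M^-1 s^-1
#' @export
effective_superoxide_rate <- function(params) {
  if (!params$adduct_mode) return(params$k_super_simple)
  if (params$k_mad + params$k_iet_adduct == 0) return(0)
  params$k_ad * params$k_iet_adduct / (params$k_mad + params$k_iet_adduct)
}

#' Reaction network of the aerobic regime
#'
#' @param aer an `aerobic_params`
#' @param light an `illumination_params`
#' @param relay a `relay_scheme_params` (photogeneration block, `kq_EnT`
#'   carries the enzyme quench on which the direct branch rides)
#' @return a `reaction_network`
#' @export
aerobic_network <- function(aer, light, relay) {
  species <- data.frame(
    id = c("Ru", "RuS", "Ru3", "ED", "EDox", "MV2", "MVr", "O2", "O2m",
           "H2O2", "H2O", .enzyme_states, .adduct_states),
    role = c("sensitizer ground", "sensitizer excited", "sensitizer oxidized",
             "donor", "donor oxidized", "mediator", "mediator radical",
             "dioxygen", "superoxide", "hydrogen peroxide", "water ledger",
             paste("enzyme,", 0:4, "electrons"),
             paste("superoxide adduct on enzyme state", 0:3))
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
         k = relay$k_rec_MV),
    list(id = "B",      reactants = c(MVr = 1, O2 = 1), products = c(MV2 = 1, O2m = 1),
         k = aer$k_B),
    list(id = "dism",   reactants = c(O2m = 2), products = c(O2 = 1, H2O2 = 1),
         k = aer$k_dism),
    list(id = "F",      reactants = c(E4 = 1, O2 = 1), products = c(E0 = 1, H2O = 2),
         k = aer$k_F)
  )
  for (n in 0:3) {
    en <- paste0("E", n); en1 <- paste0("E", n + 1); ad <- paste0("AD", n)
    rxn <- c(rxn, list(
      list(id = paste0("mvred", n),
           reactants = stats::setNames(c(1, 1), c("MVr", en)),
           products = stats::setNames(c(1, 1), c("MV2", en1)),
           k = aer$k_red_MV),
      list(id = paste0("direct", n),
           reactants = stats::setNames(c(1, 1), c("RuS", en)),
           products = stats::setNames(c(1, 1), c("Ru3", en1)),
           k = relay$kq_EnT * aer$phi_direct),
      list(id = paste0("ent", n),
           reactants = stats::setNames(c(1, 1), c("RuS", en)),
           products = stats::setNames(c(1, 1), c("Ru", en)),
           k = relay$kq_EnT * (1 - aer$phi_direct))
    ))
    if (aer$adduct_mode) {
      rxn <- c(rxn, list(
        list(id = paste0("ad", n),
             reactants = stats::setNames(c(1, 1), c("O2m", en)),
             products = stats::setNames(1, ad), k = aer$k_ad),
        list(id = paste0("adb", n),
             reactants = stats::setNames(1, ad),
             products = stats::setNames(c(1, 1), c("O2m", en)), k = aer$k_mad),
        list(id = paste0("iet", n),
             reactants = stats::setNames(1, ad),
             products = stats::setNames(c(1, 1), c(en1, "O2")),
             k = aer$k_iet_adduct)
      ))
    } else {
      rxn <- c(rxn, list(
        list(id = paste0("iet", n),
             reactants = stats::setNames(c(1, 1), c("O2m", en)),
             products = stats::setNames(c(1, 1), c(en1, "O2")),
             k = aer$k_super_simple)
      ))
    }
  }
  build_network(species, rxn)
}

#' Run the aerobic regime
#'
#' @param aer an `aerobic_params`
#' @param light an `illumination_params`
#' @param relay a `relay_scheme_params` (reference configuration: 30 uM
#'   sensitizer, 1 mM viologen, 1 mM donor)
#' @param ru_tot,lac_tot,mv_tot totals, M
#' @param times time grid, s
#' @param light_off optional time (s) at which illumination stops; the run
#'   is continued dark from there
#' @param electrode an `electrode_model` for the oxygen readout
#' @param ... passed to [simulate()]
#' @return list: `trajectory` (with flux ledger), `o2`, `h2o2`, `mvr`
#'   concentration traces, `time`
#' @export
run_aerobic <- function(aer = aerobic_params(),
                        light = illumination_params(edta_tot = 1e-3),
                        relay = relay_scheme_params(kq_EnT = 6.1e9,
                                                    ru_tot = 30e-6,
                                                    mv_tot = 1e-3),
                        ru_tot = relay$ru_tot, lac_tot = 16e-6,
                        mv_tot = relay$mv_tot,
                        times = seq(0, 300, by = 0.5), light_off = Inf,
                        electrode = electrode_model(), ...) {
  net <- aerobic_network(aer, light, relay)
  init <- stats::setNames(numeric(nrow(net$species)), net$species$id)
  init[["Ru"]] <- ru_tot
  init[["ED"]] <- light$edta_tot
  init[["MV2"]] <- mv_tot
  init[["O2"]] <- aer$o2_initial
  init[["E0"]] <- lac_tot
  if (is.finite(light_off) && light_off < max(times)) {
    t1 <- times[times <= light_off]
    if (!length(t1) || max(t1) < light_off) t1 <- c(t1, light_off)
    traj1 <- simulate(net, init, t1, track_fluxes = TRUE, ...)
    dark <- aerobic_network(aer, illumination_params(k_exc = 0,
                                                     k_EDTA = light$k_EDTA,
                                                     edta_tot = light$edta_tot),
                            relay)
    y_mid <- traj1$conc[nrow(traj1$conc), ]
    t2 <- unique(c(light_off, times[times >= light_off]))
    traj2 <- simulate(dark, y_mid, t2, track_fluxes = TRUE, ...)
    keep1 <- traj1$time < light_off
    time <- c(traj1$time[keep1], traj2$time)
    conc <- rbind(traj1$conc[keep1, , drop = FALSE], traj2$conc)
    flux <- rbind(traj1$fluxes[keep1, , drop = FALSE],
                  sweep(traj2$fluxes, 2, -traj1$fluxes[nrow(traj1$fluxes), ], `-`))
    traj <- structure(list(time = time, conc = conc, fluxes = flux,
                           network = net, solver_report = traj1$solver_report),
                      class = "trajectory")
  } else {
    traj <- simulate(net, init, times, track_fluxes = TRUE, ...)
  }
  list(trajectory = traj,
       time = traj$time,
       o2 = o2_trace(traj, electrode),
       h2o2 = species_conc(traj, "H2O2"),
       mvr = species_conc(traj, "MVr"))
}

#' Initial oxygen-consumption rate
#'
#' Least-squares slope of the oxygen trace on a window; by default the
#' window runs from the start until 10% of the initial oxygen has been
#' depleted (or the whole trace when depletion never reaches 10%).
#'
#' @param time time grid, s
#' @param o2 oxygen trace, M
#' @param window optional `c(t_start, t_end)` in seconds overriding the
#'   default depletion window
#' @param depletion_fraction fraction defining the default window (0.1)
#' @return consumption rate in M/s (positive when oxygen decreases)
#' @export
initial_o2_rate <- function(time, o2, window = NULL, depletion_fraction = 0.1) {
  if (is.null(window)) {
    thr <- o2[1] * (1 - depletion_fraction)
    idx_end <- which(o2 <= thr)
    idx <- if (length(idx_end)) seq_len(idx_end[1]) else seq_along(time)
  } else {
    if (window[1] < min(time) || window[2] > max(time) || window[2] <= window[1]) {
      pl_error("window outside the trace", "range_error")
    }
    idx <- which(time >= window[1] & time <= window[2])
  }
  if (length(idx) < 2) pl_error("window contains fewer than 2 samples", "range_error")
  fit <- stats::lm(o2[idx] ~ time[idx])
  -unname(stats::coef(fit)[2])
}

#' Oxygen-consumption rate versus enzyme concentration
#'
#' One aerobic run plus [initial_o2_rate()] per grid point. With
#' `with_mv = FALSE` the mediator is removed and only the direct
#' excited-state branch feeds the enzyme.
#'
#' @param lac_grid enzyme concentrations, M
#' @param with_mv include the mediator (at `mv_tot`)?
#' @param aer,light,relay parameter bundles
#' @param mv_tot mediator total when `with_mv`, M
#' @param times simulation grid, s
#' @param window passed to [initial_o2_rate()]
#' @param ... passed to [run_aerobic()]
#' @return data.frame with `lac_conc` and `initial_rate` (M/s)
#' @export
rate_vs_laccase_scan <- function(lac_grid, with_mv = TRUE,
                                 aer = aerobic_params(),
                                 light = illumination_params(edta_tot = 10e-3),
                                 relay = relay_scheme_params(kq_EnT = 6.1e9,
                                                             ru_tot = 30e-6),
                                 mv_tot = 250e-6,
                                 times = seq(0, 300, by = 0.5),
                                 window = NULL, ...) {
  if (any(lac_grid < 0)) pl_error("enzyme grid must be nonnegative", "configuration_error")
  rates <- vapply(lac_grid, function(lac) {
    run <- run_aerobic(aer, light, relay, lac_tot = lac,
                       mv_tot = if (with_mv) mv_tot else 0,
                       times = times, ...)
    initial_o2_rate(run$time, run$o2, window = window)
  }, 0)
  data.frame(lac_conc = lac_grid, initial_rate = rates)
}

#' Ablate one enzyme-reduction route and compare oxygen profiles
#'
#' Reruns the aerobic regime with the named route zeroed (superoxide-adduct
#' route or direct mediator route), everything else constant, and reports
#' which ablation perturbs the oxygen trace more (integrated absolute
#' deviation from the baseline run).
#'
#' @param aer baseline `aerobic_params`
#' @param which one of `"superoxide_route"`, `"mv_route"`
#' @param both if TRUE, run both ablations and give the dominance verdict
#' @param ... configuration passed to [run_aerobic()]
#' @return list with the baseline run, the ablated run(s), per-route
#'   integrated deviations, and `dominant_route` when `both`
#' @export
pathway_ablation <- function(aer = aerobic_params(), which = "superoxide_route",
                             both = TRUE, ...) {
  zero_route <- function(p, route) {
    if (route == "superoxide_route") {
      p$k_ad <- 0; p$k_iet_adduct <- 0; p$k_super_simple <- 0
    } else if (route == "mv_route") {
      p$k_red_MV <- 0
    } else {
      pl_error(paste0("unknown route: ", route), "configuration_error")
    }
    p
  }
  baseline <- run_aerobic(aer, ...)
  routes <- if (both) c("superoxide_route", "mv_route") else which
  runs <- list(); dev <- numeric()
  for (r in routes) {
    run_r <- run_aerobic(zero_route(aer, r), ...)
    runs[[r]] <- run_r
    dt <- diff(baseline$time)
    d <- abs(run_r$o2 - baseline$o2)
    dev[r] <- sum((d[-1] + d[-length(d)]) / 2 * dt)  # trapezoid
  }
  out <- list(baseline = baseline, ablations = runs, deviation = dev)
  if (both) out$dominant_route <- names(dev)[which.max(dev)]
  out
}

#' Share of enzyme reduction carried by the superoxide route
#'
#' Cumulative-flux ratio from the ledger: adduct internal-transfer events
#' over all enzyme-reduction events (adduct + mediator + direct).
#'
#' @param run output of [run_aerobic()]
#' @return fraction in \[0, 1\]
#' @export
superoxide_route_share <- function(run) {
  fl <- run$trajectory$fluxes
  if (is.null(fl)) pl_error("run has no flux ledger", "configuration_error")
  last <- fl[nrow(fl), ]
  s <- sum(last[paste0("iet", 0:3)])
  m <- sum(last[paste0("mvred", 0:3)])
  d <- sum(last[paste0("direct", 0:3)])
  if (s + m + d == 0) return(NA_real_)
  s / (s + m + d)
}

#' Fraction of photogenerated electrons ending in hydrogen peroxide
#'
#' `2 * cumulative H2O2 / (electrons leaving the radical pool + direct
#' reductions)`; 1 when everything dismutates, 0 when everything routes
#' through the enzyme.
#'
#' @param run output of [run_aerobic()]
#' @return fraction
#' @export
h2o2_yield <- function(run) {
  fl <- run$trajectory$fluxes
  if (is.null(fl)) pl_error("run has no flux ledger", "configuration_error")
  last <- fl[nrow(fl), ]
  electrons <- last[["B"]] + sum(last[paste0("mvred", 0:3)]) +
    sum(last[paste0("direct", 0:3)])
  if (electrons <= 0) pl_error("no photogenerated electron flux", "undefined_yield_error")
  2 * last[["dism"]] / electrons
}

#' Oxygen bookkeeping from the flux ledger
#'
#' Exact identity: O2 consumed = O2 taken up by the radical (B) + turnover
#' (F) - O2 regenerated by dismutation and adduct internal transfer.
#'
#' @param run output of [run_aerobic()]
#' @return list with the consumed/regenerated tallies and the residual of
#'   the identity against the trace (should be ~ solver tolerance)
#' @export
o2_bookkeeping <- function(run) {
  fl <- run$trajectory$fluxes
  last <- fl[nrow(fl), ]
  consumed <- last[["B"]] + last[["F"]]
  regenerated <- last[["dism"]] + sum(last[paste0("iet", 0:3)])
  net <- consumed - regenerated
  traced <- run$o2[1] - run$o2[length(run$o2)]
  list(consumed = consumed, regenerated = regenerated, net = net,
       traced = traced, residual = net - traced)
}
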