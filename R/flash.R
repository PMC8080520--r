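#' Laser-flash regimes
#'
#' Two flash-photolysis schemes: the direct sensitizer/enzyme scheme with a
#' pre-flash association equilibrium and intra-complex charge separation,
#' and the viologen-relay scheme where oxidative quenching with cage escape
#' feeds bimolecular relays. Both return trajectories plus the optical
#' traces actually measured.
#'
#' @name flash_kinetics
NULL

#' Pre-flash association equilibrium
#'
#' Exact root of the binding quadratic `Ka (Ru_tot - C)(L_tot - C) = C` on
#' `[0, min(Ru_tot, L_tot)]`.
#'
#' @param Ka association constant, M^-1
#' @param ru_tot,lac_tot totals, M
#' @return named vector: `ru_free`, `lac_free`, `complex` (M)
#' @export
preflash_equilibrium <- function(Ka, ru_tot, lac_tot) {
  stopifnot(Ka >= 0, ru_tot >= 0, lac_tot >= 0)
  if (Ka == 0 || ru_tot == 0 || lac_tot == 0) {
    C <- 0
  } else if (!is.finite(Ka)) {
    C <- min(ru_tot, lac_tot)
  } else {
    b <- ru_tot + lac_tot + 1 / Ka
    C <- (b - sqrt(b^2 - 4 * ru_tot * lac_tot)) / 2
  }
  c(ru_free = ru_tot - C, lac_free = lac_tot - C, complex = C)
}

#' Reaction network of the direct flash scheme
#'
#' Species: `Ru` (ground), `RuS` (excited), `Ru3` (oxidized), `L` (enzyme,
#' oxidized T1), `Lred` (reduced T1), `C` (ground pair), `CS` (excited
#' pair), `Ccs` (charge-separated pair).
#'
#' @param params a `direct_scheme_params`
#' @return a `reaction_network`
#' @export
direct_scheme_network <- function(params) {
  species <- data.frame(
    id = c("Ru", "RuS", "Ru3", "L", "Lred", "C", "CS", "Ccs"),
    role = c("sensitizer ground", "sensitizer excited", "sensitizer oxidized",
             "enzyme T1 oxidized", "enzyme T1 reduced", "ground complex",
             "excited complex", "charge-separated complex")
  )
  rxn <- list(
    list(id = "assoc",   reactants = c(Ru = 1, L = 1), products = c(C = 1),
         k = params$k_on_ground),
    list(id = "dissoc",  reactants = c(C = 1), products = c(Ru = 1, L = 1),
         k = params$k_off_ground),
    list(id = "decay",   reactants = c(RuS = 1), products = c(Ru = 1), k = params$k0),
    list(id = "ent",     reactants = c(RuS = 1, L = 1), products = c(Ru = 1, L = 1),
         k = params$kq_EnT),
    list(id = "cdecay",  reactants = c(CS = 1), products = c(C = 1), k = params$k0),
    list(id = "cs",      reactants = c(CS = 1), products = c(Ccs = 1), k = params$k_cs),
    list(id = "br",      reactants = c(Ccs = 1), products = c(C = 1), k = params$k_br),
    list(id = "off",     reactants = c(Ccs = 1), products = c(Ru3 = 1, Lred = 1),
         k = params$k_off),
    list(id = "on_cs",   reactants = c(Ru3 = 1, Lred = 1), products = c(Ccs = 1),
         k = params$k_on_cs),
    list(id = "rec_t1",  reactants = c(Ru3 = 1, Lred = 1), products = c(Ru = 1, L = 1),
         k = params$k_rec_T1)
  )
  build_network(species, rxn)
}

#' Partition a flash over the pre-flash ground-state populations
#'
#' The excitation is a delta pulse at t = 0; the excited population is split
#' between free sensitizer and complexes proportionally to their
#' ground-state populations, everything else untouched.
#'
#' @param state named concentration vector containing `Ru` and `C`
#' @param pulse a `flash_pulse`
#' @return updated named concentration vector with `RuS`, `CS` populated
#' @export
flash_initialize <- function(state, pulse) {
  ground <- state[["Ru"]] + state[["C"]]
  if (pulse$excited_concentration > ground * (1 + 1e-12)) {
    pl_error("flash pulse exceeds the available ground-state sensitizer",
             "configuration_error")
  }
  if (pulse$excited_concentration == 0 || ground == 0) return(state)
  frac_complex <- state[["C"]] / ground
  exc <- pulse$excited_concentration
  state[["CS"]] <- state[["CS"]] + exc * frac_complex
  state[["C"]] <- state[["C"]] - exc * frac_complex
  state[["RuS"]] <- state[["RuS"]] + exc * (1 - frac_complex)
  state[["Ru"]] <- state[["Ru"]] - exc * (1 - frac_complex)
  state
}

#' Run the direct flash scheme
#'
#' Builds the network, equilibrates the ground-state association, applies
#' the flash, integrates, and evaluates the 450 nm / 610 nm absorbance
#' differences and the emission trace.
#'
#' @param params a `direct_scheme_params`
#' @param pulse a `flash_pulse`
#' @param times time grid, s
#' @param eps extinction set (see [default_extinctions()])
#' @param ... further arguments to [simulate()]
#' @return list: `trajectory`, `a450`, `a610`, `emission` (normalized),
#'   `initial`, `optical`
#' @export
run_direct_scheme <- function(params, pulse, times,
                              eps = default_extinctions(), ...) {
  net <- direct_scheme_network(params)
  eq <- preflash_equilibrium(params$Ka, params$ru_tot, params$lac_tot)
  init <- stats::setNames(numeric(nrow(net$species)), net$species$id)
  init[["Ru"]] <- eq[["ru_free"]]
  init[["L"]] <- eq[["lac_free"]]
  init[["C"]] <- eq[["complex"]]
  init <- flash_initialize(init, pulse)
  ## reference = pre-flash state (before excitation)
  ref <- init
  ref[["Ru"]] <- eq[["ru_free"]]; ref[["C"]] <- eq[["complex"]]
  ref[["RuS"]] <- 0; ref[["CS"]] <- 0
  om <- direct_optical_model(reference = ref, eps = eps)
  traj <- simulate(net, init, times, ...)
  list(trajectory = traj,
       a450 = absorbance_trace(traj, om, 450L),
       a610 = absorbance_trace(traj, om, 610L),
       emission = emission_trace(traj, c("RuS", "CS"), normalize = TRUE),
       initial = init, optical = om)
}

#' Reaction network of the viologen-relay flash scheme
#'
#' Species: `Ru`, `RuS`, `Ru3`, `MV2` (viologen), `MVr` (radical), `L`
#' (oxidized T1), `Lred`. Cage escape is a branching probability on the
#' quench event, not an explicit encounter complex.
#'
#' @param params a `relay_scheme_params`
#' @return a `reaction_network`
#' @export
relay_scheme_network <- function(params) {
  species <- data.frame(
    id = c("Ru", "RuS", "Ru3", "MV2", "MVr", "L", "Lred"),
    role = c("sensitizer ground", "sensitizer excited", "sensitizer oxidized",
             "mediator oxidized", "mediator radical", "enzyme T1 oxidized",
             "enzyme T1 reduced")
  )
  rxn <- list(
    list(id = "decay",  reactants = c(RuS = 1), products = c(Ru = 1), k = params$k0),
    list(id = "q_ce",   reactants = c(RuS = 1, MV2 = 1), products = c(Ru3 = 1, MVr = 1),
         k = params$kq_MV * params$phi_ce),
    list(id = "q_nc",   reactants = c(RuS = 1, MV2 = 1), products = c(Ru = 1, MV2 = 1),
         k = params$kq_MV * (1 - params$phi_ce)),
    list(id = "rec_mv", reactants = c(MVr = 1, Ru3 = 1), products = c(MV2 = 1, Ru = 1),
         k = params$k_rec_MV),
    list(id = "k2",     reactants = c(MVr = 1, L = 1), products = c(MV2 = 1, Lred = 1),
         k = params$k2),
    list(id = "rec_t1", reactants = c(Lred = 1, Ru3 = 1), products = c(L = 1, Ru = 1),
         k = params$k_rec_T1),
    list(id = "ent",    reactants = c(RuS = 1, L = 1), products = c(Ru = 1, L = 1),
         k = params$kq_EnT)
  )
  build_network(species, rxn)
}

#' Run the viologen-relay flash scheme
#'
#' @param params a `relay_scheme_params`
#' @param pulse a `flash_pulse`
#' @param times time grid, s
#' @param eps extinction set
#' @param ... further arguments to [simulate()]
#' @return list: `trajectory`, `a450`, `a610`, `a395`, `emission`
#' @export
run_relay_scheme <- function(params, pulse, times,
                             eps = default_extinctions(), ...) {
  net <- relay_scheme_network(params)
  init <- stats::setNames(numeric(nrow(net$species)), net$species$id)
  init[["Ru"]] <- params$ru_tot - pulse$excited_concentration
  if (init[["Ru"]] < 0) {
    pl_error("flash pulse exceeds the sensitizer total", "configuration_error")
  }
  init[["RuS"]] <- pulse$excited_concentration
  init[["MV2"]] <- params$mv_tot
  init[["L"]] <- params$lac_tot
  ref <- init
  ref[["Ru"]] <- params$ru_tot; ref[["RuS"]] <- 0
  om <- relay_optical_model(reference = ref, eps = eps)
  traj <- simulate(net, init, times, ...)
  list(trajectory = traj,
       a450 = absorbance_trace(traj, om, 450L),
       a610 = absorbance_trace(traj, om, 610L),
       a395 = absorbance_trace(traj, om, 395L),
       emission = emission_trace(traj, "RuS", normalize = TRUE),
       initial = init, optical = om)
}

#' Charge-separated-state yield of a flash experiment
#'
#' Percentage of the flash-excited population surviving as oxidized
#' sensitizer once the excited state has decayed (< 0.1% of its peak).
#'
#' @param traj a `trajectory` from a flash scheme
#' @param pulse the `flash_pulse` used
#' @return percent
#' @export
css_yield <- function(traj, pulse) {
  if (pulse$excited_concentration <= 0) {
    pl_error("undefined yield: zero flash pulse", "undefined_yield_error")
  }
  emitters <- intersect(c("RuS", "CS"), colnames(traj$conc))
  em <- rowSums(traj$conc[, emitters, drop = FALSE])
  if (em[length(em)] > 1e-3 * max(em)) {
    pl_error("trajectory does not extend past excited-state decay",
             "configuration_error")
  }
  ox <- intersect(c("Ru3", "Ccs"), colnames(traj$conc))
  ru3_end <- sum(traj$conc[nrow(traj$conc), ox])
  100 * ru3_end / pulse$excited_concentration
}

#' Escape yield of the charge-separated complex
#'
#' `100 * k_off / (k_off + k_br)`: the competition between dissociation of
#' the charge-separated pair and intra-complex recombination.
#'
#' @param k_off,k_br rates in s^-1, not both zero
#' @return percent
#' @export
branch_yield <- function(k_off, k_br) {
  if (k_off + k_br <= 0) pl_error("undefined yield: k_off + k_br = 0", "undefined_yield_error")
  100 * k_off / (k_off + k_br)
}

#' Radical and T1-reduction yields of a relay flash
#'
#' @param traj a relay-scheme `trajectory`
#' @param pulse the `flash_pulse` used
#' @return named vector: `mv_yield` (% of the pulse appearing as maximal
#'   radical) and `t1_yield` (% of that maximal radical appearing as
#'   maximal reduced T1)
#' @export
relay_yields <- function(traj, pulse) {
  if (pulse$excited_concentration <= 0) {
    pl_error("undefined yield: zero flash pulse", "undefined_yield_error")
  }
  mv_max <- max(species_conc(traj, "MVr"))
  t1_max <- max(species_conc(traj, "Lred"))
  if (mv_max <= 0) {
    return(c(mv_yield = 0, t1_yield = NA_real_))
  }
  c(mv_yield = 100 * mv_max / pulse$excited_concentration,
    t1_yield = 100 * t1_max / mv_max)
}
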