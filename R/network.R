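#' Declarative mass-action reaction networks
#'
#' A reaction network is the executable form of a kinetic scheme: a species
#' list plus elementary reactions of total order one or two with mass-action
#' rate laws. Unimolecular rate constants are in 1/s, bimolecular ones in
#' 1/(M*s). Conserved moieties (linear combinations of species with zero net
#' production, e.g. the total sensitizer pool across ground, excited,
#' oxidized and complexed forms) are either declared or derived automatically
#' from the left null space of the stoichiometry matrix.
#'
#' @param species a character vector of species ids, or a data.frame with
#'   columns `id` and (optionally) `role`. Ids must be unique, non-empty and
#'   free of whitespace.
#' @param reactions a list; each element is a list with elements `id`,
#'   `reactants` (named integer vector, species -> stoichiometric count),
#'   `products` (same) and `k` (nonnegative rate constant).
#' @param conserved_moieties optional named list of named numeric vectors
#'   (species -> coefficient). When omitted, a basis is derived by
#'   null-space analysis.
#' @return an object of class `reaction_network`
#' @examples
#' net <- build_network(c("A", "B"),
#'   list(list(id = "conv", reactants = c(A = 1), products = c(B = 1), k = 1)))
#' net$conserved_moieties
#' @export
build_network <- function(species, reactions, conserved_moieties = NULL) {
  if (is.data.frame(species)) {
    ids <- as.character(species$id)
    roles <- if ("role" %in% names(species)) as.character(species$role) else rep("", length(ids))
  } else {
    ids <- as.character(species)
    roles <- rep("", length(ids))
  }
  if (anyDuplicated(ids)) {
    pl_error("duplicated species ids", "configuration_error")
  }
  if (any(!nzchar(ids)) || any(grepl("\\s", ids))) {
    pl_error("species ids must be non-empty and contain no whitespace",
             "configuration_error")
  }
  ns <- length(ids)
  nr <- length(reactions)
  if (nr == 0L) pl_error("a network needs at least one reaction", "configuration_error")

  S <- matrix(0, nrow = ns, ncol = nr, dimnames = list(ids, NULL))
  rxn_ids <- character(nr)
  k <- numeric(nr)
  i1 <- integer(nr)  # first reactant index
  i2 <- integer(nr)  # second reactant index, 0 for unimolecular

  for (j in seq_len(nr)) {
    rx <- reactions[[j]]
    rxn_ids[j] <- if (!is.null(rx$id)) rx$id else paste0("r", j)
    if (is.null(rx$reactants) || length(rx$reactants) == 0L ||
        is.null(rx$products) || length(rx$products) == 0L) {
      pl_error(sprintf("reaction '%s': reactants and products must be non-empty",
                       rxn_ids[j]), "configuration_error")
    }
    undecl <- setdiff(c(names(rx$reactants), names(rx$products)), ids)
    if (length(undecl)) {
      pl_error(sprintf("reaction '%s' references undeclared species: %s",
                       rxn_ids[j], paste(undecl, collapse = ", ")),
               "configuration_error")
    }
    if (is.null(rx$k) || !is.finite(rx$k) || rx$k < 0) {
      pl_error(sprintf("reaction '%s': rate constant must be finite and >= 0",
                       rxn_ids[j]), "validation_error")
    }
    order <- sum(rx$reactants)
    if (!order %in% c(1, 2)) {
      pl_error(sprintf("reaction '%s' has total reactant order %g; only mass action of order 1 or 2 is supported",
                       rxn_ids[j], order), "unsupported_rate_law_error")
    }
    k[j] <- rx$k
    ridx <- rep(match(names(rx$reactants), ids), times = rx$reactants)
    i1[j] <- ridx[1L]
    i2[j] <- if (order == 2) ridx[2L] else 0L
    for (s in names(rx$reactants)) S[s, j] <- S[s, j] - rx$reactants[[s]]
    for (s in names(rx$products))  S[s, j] <- S[s, j] + rx$products[[s]]
  }
  if (anyDuplicated(rxn_ids)) pl_error("duplicated reaction ids", "configuration_error")
  colnames(S) <- rxn_ids

  if (is.null(conserved_moieties)) {
    conserved_moieties <- derive_moieties(S)
  } else {
    for (nm in names(conserved_moieties)) {
      w <- conserved_moieties[[nm]]
      vec <- stats::setNames(numeric(ns), ids)
      vec[names(w)] <- w
      if (max(abs(drop(vec %*% S))) > 1e-9 * max(1, max(abs(vec)))) {
        pl_error(sprintf("declared moiety '%s' is not conserved by the reactions", nm),
                 "configuration_error")
      }
      conserved_moieties[[nm]] <- vec
    }
  }

  structure(list(
    species = data.frame(id = ids, role = roles, stringsAsFactors = FALSE),
    reactions = reactions,
    reaction_ids = rxn_ids,
    stoichiometry = S,
    k = stats::setNames(k, rxn_ids),
    .i1 = i1, .i2 = i2,
    conserved_moieties = conserved_moieties
  ), class = "reaction_network")
}

## Left null space of the stoichiometry matrix, tidied toward small
## integer coefficients where the basis admits them.
derive_moieties <- function(S) {
  sv <- svd(S, nu = nrow(S), nv = 0)
  tol <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps * 1e2
  null_idx <- which(c(sv$d, rep(0, nrow(S) - length(sv$d))) <= tol)
  if (!length(null_idx)) return(list())
  basis <- sv$u[, null_idx, drop = FALSE]
  out <- list()
  for (j in seq_len(ncol(basis))) {
    w <- basis[, j]
    w[abs(w) < 1e-10] <- 0
    nz <- w[w != 0]
    w <- w / nz[which.max(abs(nz) > 0)][1]  # scale so first nonzero is 1
    ## try to rationalize to small integers
    scaled <- w / min(abs(w[w != 0]))
    if (all(abs(scaled - round(scaled)) < 1e-8)) w <- round(scaled)
    names(w) <- rownames(S)
    out[[paste0("moiety_", j)]] <- w
  }
  out
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reactions, %d conserved moieties\n",
              nrow(x$species), length(x$reaction_ids), length(x$conserved_moieties)))
  invisible(x)
}

#' Test whether a linear combination of species is conserved
#'
#' @param network a `reaction_network`
#' @param weights named numeric vector (species -> coefficient)
#' @return logical
#' @export
is_conserved <- function(network, weights) {
  vec <- stats::setNames(numeric(nrow(network$species)), network$species$id)
  vec[names(weights)] <- weights
  max(abs(drop(vec %*% network$stoichiometry))) < 1e-9 * max(1, max(abs(vec)))
}

#' Simulate a reaction network
#'
#' Deterministic mass-action ODE integration with a stiff-capable solver
#' (lsoda, automatic stiff/non-stiff switching, dense-output interpolation to
#' the requested grid). Negative concentrations from round-off are clipped at
#' reporting, never during integration.
#'
#' @param network a `reaction_network`
#' @param initial named numeric vector of initial concentrations (M) covering
#'   all species (missing species default to 0 only if `allow_missing`)
#' @param times strictly increasing time grid in seconds; must start at the
#'   initial time (typically 0)
#' @param rtol relative tolerance (default 1e-8)
#' @param atol absolute tolerance in M (default 1e-15)
#' @param track_fluxes if TRUE, cumulative time-integrated reaction fluxes
#'   (M) are carried as extra states and returned in `$fluxes`; used for
#'   electron/oxygen bookkeeping ledgers
#' @param check_conservation verify conserved-moiety drift below
#'   `conservation_tol` (relative); integration fails loudly if exceeded
#' @param conservation_tol relative drift tolerance, default 1e-6
#' @return a `trajectory`: list with `time`, `conc` (time x species matrix),
#'   `fluxes` (or NULL), `network` and `solver_report`
#' @export
simulate <- function(network, initial, times, rtol = 1e-8, atol = 1e-15,
                     track_fluxes = FALSE, check_conservation = TRUE,
                     conservation_tol = 1e-6) {
  ids <- network$species$id
  missing <- setdiff(ids, names(initial))
  if (length(missing)) {
    pl_error(paste0("initial state misses species: ", paste(missing, collapse = ", ")),
             "configuration_error")
  }
  if (any(diff(times) <= 0)) pl_error("time grid must be strictly increasing", "configuration_error")
  y0 <- stats::setNames(as.numeric(initial[ids]), ids)
  if (any(y0 < 0)) pl_error("initial concentrations must be >= 0", "configuration_error")

  nr <- length(network$k)
  i1 <- network$.i1; i2 <- network$.i2
  has2 <- i2 > 0L
  kvec <- unname(network$k)
  S <- network$stoichiometry
  ns <- length(ids)

  deriv <- function(t, y, parms) {
    conc <- y[seq_len(ns)]
    rates <- kvec * conc[i1]
    rates[has2] <- rates[has2] * conc[i2[has2]]
    dy <- drop(S %*% rates)
    if (track_fluxes) list(c(dy, rates)) else list(dy)
  }

  y_start <- if (track_fluxes) c(y0, stats::setNames(numeric(nr), paste0("flux_", network$reaction_ids))) else y0
  sol <- deSolve::lsoda(y = y_start, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  diag_state <- attr(sol, "istate")
  if (!is.null(diag_state) && diag_state[1] < 0) {
    t_fail <- sol[nrow(sol), 1]
    pl_error(sprintf("ODE integration failed near t = %g s (lsoda istate %d)",
                     t_fail, diag_state[1]), "integration_error")
  }
  if (nrow(sol) < length(times)) {
    pl_error(sprintf("ODE integration stopped early at t = %g s", sol[nrow(sol), 1]),
             "integration_error")
  }
  conc <- sol[, 1L + seq_len(ns), drop = FALSE]
  conc[conc < 0] <- 0  # clip round-off negatives on output
  rownames(conc) <- NULL
  fluxes <- NULL
  if (track_fluxes) {
    fluxes <- sol[, 1L + ns + seq_len(nr), drop = FALSE]
    colnames(fluxes) <- network$reaction_ids
    rownames(fluxes) <- NULL
  }

  traj <- structure(list(
    time = times, conc = conc, fluxes = fluxes, network = network,
    solver_report = list(rtol = rtol, atol = atol,
                         n_steps = if (!is.null(diag_state)) diag_state[3] else NA_integer_)
  ), class = "trajectory")

  if (check_conservation && length(network$conserved_moieties)) {
    drift <- max_moiety_drift(traj)
    if (is.finite(drift) && drift > conservation_tol) {
      pl_error(sprintf("conserved-moiety drift %.3g exceeds tolerance %.3g",
                       drift, conservation_tol), "integration_error")
    }
  }
  traj
}

#' Maximum relative drift of the conserved moieties over a trajectory
#' @param traj a `trajectory`
#' @return numeric scalar (NaN when all moiety totals are zero)
#' @export
max_moiety_drift <- function(traj) {
  cm <- traj$network$conserved_moieties
  if (!length(cm)) return(0)
  worst <- 0
  for (w in cm) {
    tot <- drop(traj$conc %*% w)
    ref <- abs(tot[1])
    if (ref == 0) {
      scale <- max(abs(traj$conc %*% abs(w)))
      if (scale == 0) next
      worst <- max(worst, max(abs(tot)) / scale)
    } else {
      worst <- max(worst, max(abs(tot - tot[1])) / ref)
    }
  }
  worst
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points (%g to %g s), %d species%s\n",
              length(x$time), min(x$time), max(x$time), ncol(x$conc),
              if (is.null(x$fluxes)) "" else ", flux ledger attached"))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_s = x$time, x$conc, check.names = FALSE)
}

#' Extract one species' concentration series
#' @param traj a `trajectory`
#' @param species species id
#' @return numeric vector
#' @export
species_conc <- function(traj, species) {
  if (!species %in% colnames(traj$conc)) {
    pl_error(paste0("unknown species: ", species), "configuration_error")
  }
  traj$conc[, species]
}

#' Write a trajectory as CSV (columns time_s, then one column per species)
#' @param traj a `trajectory`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a network description from a structured config file
#'
#' Schema: `{species: [{id, role}], reactions: [{id, reactants: {id: n},
#' products: {id: n}, k, units}]}` in JSON or YAML. Rate constants may carry
#' a `units` tag (`"s-1"` or `"M-1s-1"`, informational).
#'
#' @param path JSON (`.json`) or YAML file
#' @return a `reaction_network`
#' @export
load_network_config <- function(path) {
  if (!file.exists(path)) pl_error(paste0("config file not found: ", path), "configuration_error")
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      pl_error("reading JSON configs requires the jsonlite package", "configuration_error")
    }
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = FALSE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      pl_error("reading YAML configs requires the yaml package", "configuration_error")
    }
    yaml::read_yaml(path)
  }
  species <- data.frame(
    id = vapply(spec$species, function(s) s$id, ""),
    role = vapply(spec$species, function(s) if (is.null(s$role)) "" else s$role, ""),
    stringsAsFactors = FALSE
  )
  reactions <- lapply(spec$reactions, function(r) {
    list(id = r$id,
         reactants = unlist(r$reactants),
         products = unlist(r$products),
         k = as.numeric(r$k))
  })
  build_network(species, reactions)
}
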