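#' Synthetic-data generation and parameter-recovery harness
#'
#' Every input the analysis consumes can be generated from known ground
#' truth: flash absorbance/emission traces, continuous-illumination
#' absorbance traces, and oxygen-electrode traces, with additive Gaussian
#' noise and optional linear drift. A fixed seed makes the output
#' bit-identical; replicate seeds derive from the master seed by a simple
#' counter (`seed + replicate index`).
#'
#' @name synthetic_data
NULL

#' Noise model for generated traces
#'
#' @param sigma_abs flash absorbance noise, absorbance units (default
#'   5e-4, the scatter of microsecond transient records)
#' @param sigma_abs_cw steady-state absorbance noise (default 2e-3)
#' @param sigma_o2 oxygen-electrode noise, M (default 1 uM)
#' @param drift linear drift slope per channel unit per second (default 0)
#' @param seed integer seed
#' @return a `noise_model`
#' @export
noise_model <- function(sigma_abs = 5e-4, sigma_abs_cw = 2e-3,
                        sigma_o2 = 1e-6, drift = 0, seed = 1L) {
  stopifnot(sigma_abs >= 0, sigma_abs_cw >= 0, sigma_o2 >= 0)
  structure(list(sigma_abs = sigma_abs, sigma_abs_cw = sigma_abs_cw,
                 sigma_o2 = sigma_o2, drift = drift, seed = as.integer(seed)),
            class = "noise_model")
}

#' Ground truth for one regime
#'
#' @param regime one of `"direct"`, `"relay"`, `"cw"`, `"o2"`
#' @param configs list of experiment configurations; each element is a list
#'   whose fields depend on the regime (see [default_truth()] for worked
#'   defaults): `params`/`pulse`/`times` for flash regimes,
#'   `ladder`/`light`/`relay`/totals/`times` for `cw`,
#'   `aer`/`light`/`relay`/totals/`times` for `o2`. Each element may carry
#'   an `id`.
#' @return a `ground_truth`
#' @export
ground_truth <- function(regime = c("direct", "relay", "cw", "o2"), configs) {
  regime <- match.arg(regime)
  stopifnot(length(configs) >= 1)
  for (i in seq_along(configs)) {
    if (is.null(configs[[i]]$id)) configs[[i]]$id <- paste0(regime, "_", i)
  }
  structure(list(regime = regime, configs = configs), class = "ground_truth")
}

#' Default ground-truth bundles at the study conditions
#'
#' `"direct"`: 15 uM sensitizer + 37 uM enzyme, 9.7 uM flash.
#' `"relay"`: 25 uM sensitizer + 10 mM viologen, 7.8 uM flash, enzyme at
#' 0/16/30 uM (the triplet used for the bimolecular-rate fits).
#' `"cw"`: 30 uM sensitizer and enzyme, 10 mM donor, 50 uM viologen.
#' `"o2"`: 30 uM sensitizer, 1 mM viologen and donor, 250 uM oxygen,
#' 16 uM enzyme.
#'
#' @param regime regime name
#' @return a `ground_truth`
#' @export
default_truth <- function(regime = c("direct", "relay", "cw", "o2")) {
  regime <- match.arg(regime)
  flash_grid <- c(0, 10^seq(-8, -3, length.out = 140))
  switch(regime,
    direct = ground_truth("direct", list(
      list(params = direct_scheme_params(), pulse = flash_pulse(9.7e-6),
           times = flash_grid)
    )),
    relay = ground_truth("relay", lapply(c(0, 16e-6, 30e-6), function(lac) {
      list(params = relay_scheme_params(lac_tot = lac),
           pulse = flash_pulse(7.8e-6), times = flash_grid,
           id = sprintf("lac_%g_uM", lac * 1e6))
    })),
    cw = ground_truth("cw", list(
      list(ladder = ladder_params(), light = illumination_params(),
           relay = relay_scheme_params(kq_EnT = 6.1e9),
           ru_tot = 30e-6, lac_tot = 30e-6, mv_tot = 50e-6,
           times = seq(0, 600, by = 1))
    )),
    o2 = ground_truth("o2", list(
      list(aer = aerobic_params(), light = illumination_params(edta_tot = 1e-3),
           relay = relay_scheme_params(kq_EnT = 6.1e9, ru_tot = 30e-6,
                                       mv_tot = 1e-3),
           lac_tot = 16e-6, times = seq(0, 300, by = 1))
    ))
  )
}

## simulate one config of a regime -> long data.frame(time_s, channel, value)
simulate_config <- function(regime, cfg) {
  if (regime == "direct") {
    run <- run_direct_scheme(cfg$params, cfg$pulse, cfg$times)
    chans <- list(a450 = run$a450, a610 = run$a610, emission = run$emission)
  } else if (regime == "relay") {
    run <- run_relay_scheme(cfg$params, cfg$pulse, cfg$times)
    chans <- list(a450 = run$a450, a610 = run$a610)
  } else if (regime == "cw") {
    run <- run_photoreduction(cfg$ladder, cfg$light, cfg$relay,
                              ru_tot = cfg$ru_tot, lac_tot = cfg$lac_tot,
                              mv_tot = cfg$mv_tot, times = cfg$times)
    chans <- list(a610 = run$a610, a395 = run$a395)
  } else if (regime == "o2") {
    run <- run_aerobic(cfg$aer, cfg$light, cfg$relay, lac_tot = cfg$lac_tot,
                       times = cfg$times)
    chans <- list(o2 = run$o2)
  } else {
    pl_error(paste0("unknown regime: ", regime), "configuration_error")
  }
  df <- do.call(rbind, lapply(names(chans), function(ch) {
    data.frame(time_s = cfg$times, channel = ch, value = chans[[ch]],
               stringsAsFactors = FALSE)
  }))
  attr(df, "run") <- run
  df
}

.channel_sigma <- function(channel, regime, noise) {
  if (channel == "o2") return(noise$sigma_o2)
  if (regime %in% c("cw")) return(noise$sigma_abs_cw)
  noise$sigma_abs
}

#' Generate noisy traces for one ground truth (in memory)
#'
#' @param truth a `ground_truth`
#' @param noise a `noise_model` (sigma 0 returns the deterministic traces)
#' @param seed override of the noise-model seed
#' @return named list of data.frames (time_s, channel, value,
#'   experiment_id), one per configuration
#' @export
generate_traces <- function(truth, noise = noise_model(), seed = noise$seed) {
  set.seed(seed)
  out <- list()
  for (cfg in truth$configs) {
    df <- simulate_config(truth$regime, cfg)
    attr(df, "run") <- NULL
    for (ch in unique(df$channel)) {
      idx <- df$channel == ch
      sg <- .channel_sigma(ch, truth$regime, noise)
      df$value[idx] <- df$value[idx] +
        stats::rnorm(sum(idx), sd = sg) +
        noise$drift * df$time_s[idx]
    }
    df$experiment_id <- cfg$id
    out[[cfg$id]] <- df
  }
  out
}

#' Generate a dataset on disk with a manifest
#'
#' Writes one CSV per configuration (`time_s, channel, value,
#' experiment_id`) plus `manifest.json` recording the regime, seed, noise
#' model, file list and md5 hashes. The manifest fully determines the
#' dataset: regenerating with the same truth and seed is byte-identical.
#'
#' @param truth a `ground_truth`
#' @param noise a `noise_model`
#' @param dir output directory (created if needed)
#' @param seed override of the noise-model seed
#' @return the manifest, invisibly
#' @export
generate_dataset <- function(truth, noise = noise_model(), dir, seed = noise$seed) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  traces <- generate_traces(truth, noise, seed)
  files <- character()
  for (id in names(traces)) {
    path <- file.path(dir, paste0(id, ".csv"))
    utils::write.csv(traces[[id]], path, row.names = FALSE, quote = FALSE)
    files[id] <- path
  }
  manifest <- list(regime = truth$regime, seed = seed,
                   noise = unclass(noise_model(noise$sigma_abs, noise$sigma_abs_cw,
                                               noise$sigma_o2, noise$drift, seed)),
                   files = basename(files),
                   md5 = unname(tools::md5sum(files)))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    saveRDS(manifest, file.path(dir, "manifest.rds"))
  }
  invisible(manifest)
}

## build fit experiments that regenerate a regime's traces from candidate
## parameters, holding everything but `fit_names` at the config values
.recovery_experiments <- function(truth, traces, fit_names, noise) {
  regime <- truth$regime
  lapply(seq_along(truth$configs), function(i) {
    cfg <- truth$configs[[i]]
    obs_df <- traces[[cfg$id]]
    model <- function(p) {
      cfg2 <- cfg
      if (regime %in% c("direct", "relay")) {
        pars <- cfg$params
        for (nm in fit_names) pars[[nm]] <- unname(p[[nm]])
        cfg2$params <- pars
      } else {
        pl_error("recovery harness covers the flash regimes", "configuration_error")
      }
      sim <- simulate_config(regime, cfg2)
      sim$value[match(paste(obs_df$time_s, obs_df$channel),
                      paste(sim$time_s, sim$channel))]
    }
    sig <- vapply(obs_df$channel, .channel_sigma, 0, regime = regime, noise = noise)
    fit_experiment(model, obs_df$value, weights = 1 / pmax(sig, 1e-12),
                   label = cfg$id)
  })
}

#' Generate-and-refit recovery study
#'
#' Repeats generate -> global fit cycles with derived per-replicate seeds
#' (`seed + replicate`) and summarizes bias and root-mean-square error per
#' parameter (percent of truth). Individual fit failures are recorded, not
#' fatal; the summary is flagged when more than 20% of replicates fail.
#'
#' @param truth a `ground_truth` (flash regimes)
#' @param fit_names names of the parameters to recover (fields of the
#'   scheme params)
#' @param noise a `noise_model`
#' @param n_replicates >= 3
#' @param seed master seed
#' @param start_factor multiplicative offset applied to the true values to
#'   form the optimizer start (default 3)
#' @param ... passed to [global_fit()]
#' @return list: `summary` data.frame (parameter, truth, bias_pct,
#'   rmse_pct), `estimates` matrix, `failures`, `flagged`
#' @export
recovery_report <- function(truth, fit_names, noise = noise_model(),
                            n_replicates = 3, seed = 1, start_factor = 3,
                            ...) {
  stopifnot(n_replicates >= 3)
  true_vals <- vapply(fit_names, function(nm) truth$configs[[1]]$params[[nm]], 0)
  est <- matrix(NA_real_, nrow = n_replicates, ncol = length(fit_names),
                dimnames = list(NULL, fit_names))
  failures <- 0L
  for (r in seq_len(n_replicates)) {
    rep_seed <- seed + r
    traces <- generate_traces(truth, noise, seed = rep_seed)
    exps <- .recovery_experiments(truth, traces, fit_names, noise)
    start <- true_vals * start_factor
    fit <- tryCatch(
      global_fit(exps, start = start, lower = true_vals / 100,
                 upper = true_vals * 100, seed = rep_seed, ...),
      error = function(e) NULL
    )
    if (is.null(fit)) { failures <- failures + 1L; next }
    est[r, ] <- fit$par[fit_names]
  }
  ok <- stats::complete.cases(est)
  bias <- 100 * (colMeans(est[ok, , drop = FALSE]) - true_vals) / true_vals
  rmse <- 100 * sqrt(colMeans(sweep(est[ok, , drop = FALSE], 2, true_vals)^2)) /
    true_vals
  list(summary = data.frame(parameter = fit_names, truth = true_vals,
                            bias_pct = unname(bias), rmse_pct = unname(rmse)),
       estimates = est, failures = failures,
       flagged = failures > 0.2 * n_replicates)
}
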