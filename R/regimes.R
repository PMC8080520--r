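#' Unified entry point over the four experimental regimes
#'
#' Thin dispatcher mirroring the regimes as subcommands: given a regime
#' name and one configuration (the same structure [default_truth()] uses),
#' it runs the simulation and returns both the full run object and the
#' long-format trace table (`time_s, channel, value`) used by the CSV
#' dialect of this package.
#'
#' @param regime `"direct"`, `"relay"`, `"cw"` or `"o2"`
#' @param config one configuration list (see [default_truth()])
#' @return list: `run` (regime-specific result) and `traces` (data.frame)
#' @export
run_regime <- function(regime = c("direct", "relay", "cw", "o2"), config) {
  regime <- match.arg(regime)
  df <- simulate_config(regime, config)
  run <- attr(df, "run")
  attr(df, "run") <- NULL
  list(run = run, traces = df)
}
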