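#' Physical constants and unit helpers
#'
#' Internal unit convention: concentrations in mol/L, time in seconds,
#' path lengths in cm, energies in eV, distances in Angstrom unless a
#' function documents otherwise (Forster radii are quoted in nm, as usual
#' in the FRET literature).
#'
#' @name units
#' @keywords internal
NULL

## Boltzmann constant in eV/K and hbar in eV*s (CODATA)
.kB_eV <- 8.617333262e-5
.hbar_eV_s <- 6.582119569e-16

#' Thermal energy k_B*T in eV
#' @param temperature Kelvin
#' @return numeric, eV
#' @export
kBT_eV <- function(temperature = 298) {
  stopifnot(temperature > 0)
  .kB_eV * temperature
}

## unit multipliers to the internal base units
.unit_table <- c(
  "M" = 1, "mM" = 1e-3, "uM" = 1e-6, "nM" = 1e-9,
  "s" = 1, "ms" = 1e-3, "us" = 1e-6, "ns" = 1e-9
)

#' Convert a tagged quantity to base units (molar or seconds)
#'
#' Configuration files may carry concentrations or times with a unit suffix
#' (e.g. `"15 uM"`, `"600 ns"`); this normalizes them to M / s.
#'
#' @param x numeric value, or a string like `"15 uM"`
#' @param unit unit tag when `x` is numeric (default `"M"`/`"s"` base: 1)
#' @return numeric in base units
#' @export
to_base_units <- function(x, unit = NULL) {
  if (is.character(x)) {
    parts <- strsplit(trimws(x), "\\s+")[[1]]
    if (length(parts) != 2L) {
      stop("expected '<value> <unit>', got: ", x, call. = FALSE)
    }
    x <- as.numeric(parts[1L])
    unit <- parts[2L]
  }
  if (is.null(unit)) {
    return(x)
  }
  if (!unit %in% names(.unit_table)) {
    stop("unknown unit tag: ", unit, call. = FALSE)
  }
  x * .unit_table[[unit]]
}

## condition helpers -------------------------------------------------------

pl_error <- function(msg, class) {
  stop(structure(
    class = c(class, "photolaccase_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
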