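#' Physical constants for kinetic and thermodynamic calculations
#'
#' Bundles the universal gas constant and the Planck and Boltzmann constants
#' used throughout the Arrhenius and activation-thermodynamics routines.
#' All values are in SI units.
#'
#' @param gas_constant Universal gas constant R, J/(mol K). Default 8.314.
#' @param planck Planck constant h, J s. Default 6.6262e-34.
#' @param boltzmann Boltzmann constant kB, J/K. Default 1.3806e-23.
#'
#' @return An object of class `"physical_constants"`: a list with elements
#'   `R`, `h_p` and `k_b`.
#'
#' @examples
#' physical_constants()
#' physical_constants(gas_constant = 8.31446)
#' @export
physical_constants <- function(gas_constant = 8.314,
                               planck = 6.6262e-34,
                               boltzmann = 1.3806e-23) {
  if (!is.numeric(gas_constant) || length(gas_constant) != 1L ||
      !is.finite(gas_constant) || gas_constant <= 0)
    stop("'gas_constant' must be a single positive number")
  if (!is.numeric(planck) || length(planck) != 1L ||
      !is.finite(planck) || planck <= 0)
    stop("'planck' must be a single positive number")
  if (!is.numeric(boltzmann) || length(boltzmann) != 1L ||
      !is.finite(boltzmann) || boltzmann <= 0)
    stop("'boltzmann' must be a single positive number")
  structure(list(R = gas_constant, h_p = planck, k_b = boltzmann),
            class = "physical_constants")
}

#' Map storage temperatures to the Kelvin convention in use
#'
#' Storage-trial temperatures are commonly reported as Celsius-derived values
#' ending in .15 K (e.g. 288.15 K = 15 degrees C). Published spreadsheet
#' analyses in the food-stability literature frequently tabulate these as
#' whole Kelvin (288, 303, ...) and carry the truncation through every
#' downstream formula. `kelvin_mode = "integer"` reproduces that convention
#' (it rounds T - 0.15 to the nearest integer); `"exact"` uses the
#' temperatures as given and is the scientifically preferable default.
#'
#' @param temperature Numeric vector of absolute temperatures (K), all > 0.
#' @param kelvin_mode `"exact"` (use as given) or `"integer"`
#'   (compatibility mode, see Details).
#'
#' @return Numeric vector of effective temperatures (K).
#' @examples
#' effective_kelvin(293.15, "integer")  # 293
#' effective_kelvin(293.15, "exact")    # 293.15
#' @export
effective_kelvin <- function(temperature, kelvin_mode = c("exact", "integer")) {
  kelvin_mode <- match.arg(kelvin_mode)
  if (!is.numeric(temperature) || length(temperature) == 0L ||
      any(!is.finite(temperature)) || any(temperature <= 0))
    stop("temperatures must be finite positive Kelvin values")
  if (kelvin_mode == "integer") round(temperature - 0.15) else temperature
}

# internal: validate and normalise a constants argument
.check_constants <- function(constants) {
  if (inherits(constants, "physical_constants")) return(constants)
  if (is.list(constants) && all(c("R", "h_p", "k_b") %in% names(constants)))
    return(physical_constants(constants$R, constants$h_p, constants$k_b))
  stop("'constants' must be created by physical_constants()")
}

# internal: R-squared of a simple linear regression, as the squared Pearson
# correlation; 0 for a response with no variance (avoids summary.lm's
# perfect-fit warnings on noiseless data)
.ols_r2 <- function(x, y) {
  if (sum((y - mean(y))^2) == 0 || sum((x - mean(x))^2) == 0) return(0)
  min(1, stats::cor(x, y)^2)
}
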