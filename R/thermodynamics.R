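#' Gibbs free energy of activation
#'
#' Eyring-type free energy of activation from a first-order rate constant:
#' `dG = -R T ln(k h / (kB T))`, reported in kJ/mol.
#'
#' The ratio `k h / (kB T)` is dimensionless only if k is expressed in 1/s.
#' The food-stability literature routinely enters k in 1/day, which shifts
#' every dG by `R T ln(86400)` (about 27 kJ/mol at these temperatures) and
#' yields the familiar 75-84 kJ/mol range for lipid oxidation; since the
#' shift is common to all samples and temperatures, comparative conclusions
#' are unaffected. `time_unit = "day"` (default) follows that convention;
#' `"second"` divides k by 86400 first.
#'
#' @param k First-order rate constant in 1/day, > 0.
#' @param temperature Temperature (K), > 0.
#' @param constants A [physical_constants()] object.
#' @param kelvin_mode Temperature convention, see [effective_kelvin()].
#' @param time_unit Unit in which k enters the Eyring ratio: `"day"`
#'   (literature-compatibility default) or `"second"`.
#' @return Gibbs free energy of activation, kJ/mol. Positive values indicate
#'   a non-spontaneous (endergonic) activation step.
#' @examples
#' gibbs_free_energy(0.1487, 288.15, kelvin_mode = "integer")  # 75.014
#' @export
gibbs_free_energy <- function(k, temperature,
                              constants = physical_constants(),
                              kelvin_mode = c("exact", "integer"),
                              time_unit = c("day", "second")) {
  kelvin_mode <- match.arg(kelvin_mode)
  time_unit <- match.arg(time_unit)
  constants <- .check_constants(constants)
  if (any(!is.finite(k)) || any(k <= 0)) stop("'k' must be positive")
  t_eff <- effective_kelvin(temperature, kelvin_mode)
  k_use <- if (time_unit == "second") k / 86400 else k
  -constants$R * t_eff * log(k_use * constants$h_p /
                               (constants$k_b * t_eff)) / 1000
}

#' Enthalpy of activation
#'
#' `dH = Ea - R T`, reported in kJ/mol. Decreases linearly in T with slope
#' -R/1000 kJ/(mol K) at fixed activation energy.
#'
#' @param ea Activation energy, J/mol.
#' @param temperature Temperature (K), > 0.
#' @param constants A [physical_constants()] object.
#' @param kelvin_mode Temperature convention, see [effective_kelvin()].
#' @return Enthalpy of activation, kJ/mol.
#' @examples
#' enthalpy(11596.4, 288.15, kelvin_mode = "integer")  # 9.202
#' @export
enthalpy <- function(ea, temperature, constants = physical_constants(),
                     kelvin_mode = c("exact", "integer")) {
  kelvin_mode <- match.arg(kelvin_mode)
  constants <- .check_constants(constants)
  if (any(!is.finite(ea))) stop("'ea' must be finite")
  t_eff <- effective_kelvin(temperature, kelvin_mode)
  (ea - constants$R * t_eff) / 1000
}

#' Entropy of activation
#'
#' `dS = (dH - dG) / T`, in J/(K mol), from enthalpy and Gibbs free energy
#' in kJ/mol. The identity `dG = dH - T dS` holds by construction.
#'
#' @param delta_h Enthalpy of activation, kJ/mol.
#' @param delta_g Gibbs free energy of activation, kJ/mol.
#' @param temperature Temperature (K), > 0.
#' @param kelvin_mode Temperature convention, see [effective_kelvin()].
#' @return Entropy of activation, J/(K mol).
#' @examples
#' entropy_activation(8.918, 75.083, 288.15, kelvin_mode = "integer")
#' @export
entropy_activation <- function(delta_h, delta_g, temperature,
                               kelvin_mode = c("exact", "integer")) {
  kelvin_mode <- match.arg(kelvin_mode)
  if (any(!is.finite(delta_h)) || any(!is.finite(delta_g)))
    stop("'delta_h' and 'delta_g' must be finite")
  t_eff <- effective_kelvin(temperature, kelvin_mode)
  1000 * (delta_h - delta_g) / t_eff
}

#' Activation thermodynamics across storage temperatures
#'
#' Computes dG, dH and dS at each storage temperature from the
#' per-temperature first-order rate constants and the Arrhenius activation
#' energy, plus the across-temperature mean and sample standard deviation
#' of dS (the conventional single-number entropy summary, since dS is
#' nearly temperature-invariant when the Arrhenius model holds).
#'
#' @param temperature Storage temperatures (K), >= 2 values.
#' @param k First-order rate constants (1/day), one per temperature.
#' @param ea Activation energy, J/mol.
#' @param constants A [physical_constants()] object.
#' @param kelvin_mode Temperature convention, see [effective_kelvin()].
#' @param time_unit Passed to [gibbs_free_energy()].
#' @return Object of class `"thermo_summary"`: `records` (data.frame with
#'   `temperature_K`, `k`, `delta_g`, `delta_h`, `delta_s`), `mean_delta_s`,
#'   `sd_delta_s`.
#' @examples
#' thermo_table(c(288.15, 303.15, 313.15, 323.15),
#'              c(0.1445, 0.1879, 0.2009, 0.2474),
#'              ea = 11312.0, kelvin_mode = "integer")
#' @export
thermo_table <- function(temperature, k, ea,
                         constants = physical_constants(),
                         kelvin_mode = c("exact", "integer"),
                         time_unit = c("day", "second")) {
  kelvin_mode <- match.arg(kelvin_mode)
  time_unit <- match.arg(time_unit)
  constants <- .check_constants(constants)
  if (length(temperature) != length(k))
    stop("'temperature' and 'k' must have the same length")
  if (length(temperature) < 2L)
    stop("at least 2 temperatures are required for a thermodynamic summary")
  dg <- gibbs_free_energy(k, temperature, constants, kelvin_mode, time_unit)
  dh <- enthalpy(ea, temperature, constants, kelvin_mode)
  ds <- entropy_activation(dh, dg, temperature, kelvin_mode)
  structure(list(records = data.frame(temperature_K = temperature,
                                      k = k, delta_g = dg, delta_h = dh,
                                      delta_s = ds),
                 mean_delta_s = mean(ds),
                 sd_delta_s = sd(ds),
                 ea = ea, kelvin_mode = kelvin_mode,
                 time_unit = time_unit),
            class = "thermo_summary")
}

#' @export
print.thermo_summary <- function(x, digits = 3, ...) {
  cat("Activation thermodynamics (Ea =", format(x$ea / 1000, digits = 6),
      "kJ/mol, k in 1/", x$time_unit, ")\n", sep = "")
  print(cbind(x$records[1:2],
              round(x$records[c("delta_g", "delta_h", "delta_s")], digits)),
        row.names = FALSE)
  cat(sprintf("  mean dS = %.*f +/- %.*f J/(K mol)\n",
              digits, x$mean_delta_s, digits, x$sd_delta_s))
  invisible(x)
}
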