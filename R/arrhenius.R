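#' Fit the Arrhenius law to rate constants across storage temperatures
#'
#' Ordinary least squares of ln k on 1/T, the linearised form of
#' `k = k0 * exp(-Ea / (R T))`. The slope is `-Ea/R` (K) and the intercept
#' is `ln k0`. At least three distinct temperatures are required: with two
#' points the line is trivially exact and the activation energy carries no
#' lack-of-fit information.
#'
#' @param temperature Storage temperatures (K), >= 3 distinct values.
#' @param k Rate constants (1/day for first-order kinetics), all > 0.
#' @param constants A [physical_constants()] object.
#' @param kelvin_mode `"exact"` or `"integer"`; applied to the temperatures
#'   before fitting and inherited by [predict_k()]. See [effective_kelvin()].
#'
#' @return Object of class `"arrhenius_fit"`: `slope` (K), `intercept`
#'   (ln k0), `ea` (J/mol, = -slope * R), `r_squared`, `temperatures`
#'   (effective K used), `kelvin_mode`, `constants`.
#' @examples
#' Tk <- c(288, 303, 313, 323)
#' k <- exp(3.6748 - 1742.1 / Tk)
#' fit_arrhenius(Tk, k)  # recovers slope -1742.1, intercept 3.6748
#' @export
fit_arrhenius <- function(temperature, k, constants = physical_constants(),
                          kelvin_mode = c("exact", "integer")) {
  kelvin_mode <- match.arg(kelvin_mode)
  constants <- .check_constants(constants)
  if (length(temperature) != length(k))
    stop("'temperature' and 'k' must have the same length")
  if (any(!is.finite(k)) || any(k <= 0))
    stop("all rate constants must be positive and finite")
  t_eff <- effective_kelvin(temperature, kelvin_mode)
  if (length(unique(t_eff)) < 3L)
    stop("at least 3 distinct temperatures are required")
  inv_t <- 1 / t_eff
  fit <- lm(log(k) ~ inv_t)
  cf <- coef(fit)
  slope <- unname(cf[2L])
  structure(list(slope = slope,
                 intercept = unname(cf[1L]),
                 ea = -slope * constants$R,
                 r_squared = .ols_r2(inv_t, log(k)),
                 temperatures = t_eff,
                 kelvin_mode = kelvin_mode,
                 constants = constants),
            class = "arrhenius_fit")
}

#' Build an Arrhenius model from known line parameters
#'
#' Constructs an `"arrhenius_fit"` directly from a slope and intercept of
#' ln k vs 1/T — e.g. a regression equation quoted in a published stability
#' study — so that [predict_k()], [activation_energy()] and the downstream
#' shelf-life and thermodynamic routines can be applied to literature values
#' without access to the underlying rate constants.
#'
#' @param slope Slope of ln k vs 1/T (K); negative for positive activation
#'   energy.
#' @param intercept Intercept, ln k0 (k0 in 1/day).
#' @inheritParams fit_arrhenius
#' @return An `"arrhenius_fit"` with `r_squared = NA`.
#' @examples
#' rb <- arrhenius_line(-1742.1, 3.6748, kelvin_mode = "integer")
#' predict_k(rb, 293.15)  # 0.1032 1/day
#' @export
arrhenius_line <- function(slope, intercept,
                           constants = physical_constants(),
                           kelvin_mode = c("exact", "integer")) {
  kelvin_mode <- match.arg(kelvin_mode)
  constants <- .check_constants(constants)
  if (!is.finite(slope) || !is.finite(intercept))
    stop("'slope' and 'intercept' must be finite")
  structure(list(slope = slope, intercept = intercept,
                 ea = -slope * constants$R,
                 r_squared = NA_real_,
                 temperatures = NULL,
                 kelvin_mode = kelvin_mode,
                 constants = constants),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: ln k = %.6g + (%.6g)/T  [kelvin_mode = %s]\n",
              x$intercept, x$slope, x$kelvin_mode))
  cat(sprintf("  Ea = %.4f kJ/mol, k0 = %.4g 1/day", x$ea / 1000,
              exp(x$intercept)))
  if (is.finite(x$r_squared)) cat(sprintf(", R^2 = %.4f", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Activation energy from an Arrhenius slope
#'
#' `Ea = -slope * R`, reported in kJ/mol.
#'
#' @param slope Slope of ln k vs 1/T (K).
#' @param constants A [physical_constants()] object.
#' @return Activation energy, kJ/mol.
#' @examples
#' activation_energy(-1742.1)  # 14.4838
#' @export
activation_energy <- function(slope, constants = physical_constants()) {
  constants <- .check_constants(constants)
  if (any(!is.finite(slope))) stop("'slope' must be finite")
  -slope * constants$R / 1000
}

#' Predict the rate constant at a temperature from an Arrhenius model
#'
#' `k(T) = exp(intercept + slope / T_eff)` with the temperature mapped
#' according to the model's `kelvin_mode`.
#'
#' @param fit An `"arrhenius_fit"`.
#' @param temperature Temperature(s), K, > 0.
#' @return Rate constant(s), 1/day.
#' @examples
#' rb <- arrhenius_line(-1742.1, 3.6748, kelvin_mode = "integer")
#' predict_k(rb, c(293.15, 298.15))
#' @export
predict_k <- function(fit, temperature) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  t_eff <- effective_kelvin(temperature, fit$kelvin_mode)
  exp(fit$intercept + fit$slope / t_eff)
}

#' Q10 temperature coefficient
#'
#' Factor by which the reaction rate increases for a 10 K rise in storage
#' temperature, from the Arrhenius model:
#' `Q10 = exp(10 * Ea / (R * T1 * T2))` with `T2 = T1 + 10`.
#'
#' @param ea Activation energy, J/mol.
#' @param t1,t2 The two comparison temperatures (K); `t2` is expected to be
#'   `t1 + 10` (a warning is issued otherwise). Defaults 303.15 and
#'   313.15 K, the usual intermediate/accelerated pair.
#' @param constants A [physical_constants()] object.
#' @param kelvin_mode Temperature convention, see [effective_kelvin()].
#' @return Q10 (unitless).
#' @examples
#' q10(14483.8, kelvin_mode = "integer")  # 1.2016
#' @export
q10 <- function(ea, t1 = 303.15, t2 = 313.15,
                constants = physical_constants(),
                kelvin_mode = c("exact", "integer")) {
  kelvin_mode <- match.arg(kelvin_mode)
  constants <- .check_constants(constants)
  if (any(!is.finite(ea))) stop("'ea' must be finite")
  if (abs((t2 - t1) - 10) > 1e-8)
    warning("Q10 is conventionally computed for t2 = t1 + 10 K")
  t1e <- effective_kelvin(t1, kelvin_mode)
  t2e <- effective_kelvin(t2, kelvin_mode)
  exp(10 * ea / (constants$R * t1e * t2e))
}
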