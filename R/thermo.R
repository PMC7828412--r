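#' @title Dissolution thermodynamics
#' @description
#' Ideal solubility from fusion properties, activity coefficients, and the
#' apparent dissolution thermodynamics (enthalpy, Gibbs energy, entropy)
#' obtained from a van't Hoff regression of `ln x` against
#' `1/T - 1/Thm`, where `Thm` is the mean harmonic temperature of the
#' study range.
#' @name dissolution-thermodynamics
NULL

# Universal gas constant, J mol^-1 K^-1
GAS_CONSTANT <- 8.314

#' Fusion heat-capacity change
#'
#' Approximates the heat-capacity change on fusion as
#' `dCp = dHfus / Tfus`.
#'
#' @param dHfus Fusion enthalpy (J/mol), > 0.
#' @param Tfus Melting temperature (K), > 0.
#' @return `dCp` in J mol^-1 K^-1.
#' @examples
#' delta_cp(20320, 413.09) # ~49.19
#' @export
delta_cp <- function(dHfus, Tfus) {
  if (any(dHfus <= 0) || any(Tfus <= 0)) {
    stop("`dHfus` and `Tfus` must be strictly positive", call. = FALSE)
  }
  dHfus / Tfus
}

#' Fusion-properties record
#'
#' Bundles the melting temperature and fusion enthalpy with the derived
#' heat-capacity change.
#'
#' @param Tfus Melting temperature (K).
#' @param dHfus Fusion enthalpy (J/mol).
#' @return List with `Tfus`, `dHfus`, `dCp` (= `dHfus/Tfus`).
#' @export
fusion_properties <- function(Tfus, dHfus) {
  list(Tfus = Tfus, dHfus = dHfus, dCp = delta_cp(dHfus, Tfus))
}

#' Ideal mole-fraction solubility
#'
#' Solubility predicted from fusion thermodynamics alone (activity
#' coefficient 1):
#' `ln x_idl = -dHfus (Tfus - T) / (R Tfus T)
#'            + (dCp / R) [ (Tfus - T)/T + ln(T/Tfus) ]`.
#' At `T = Tfus` both terms vanish and `x_idl = 1` (the melt).
#'
#' @param fusion A [fusion_properties()] record.
#' @param temperature Absolute temperature (K), `0 < T <= Tfus`.
#'   Vectorized.
#' @return Ideal mole-fraction solubility, clipped to at most 1.
#' @export
ideal_solubility <- function(fusion, temperature) {
  check_temperature(temperature)
  if (any(temperature > fusion$Tfus)) {
    stop("temperature above the melting temperature is out of the ",
         "model's domain", call. = FALSE)
  }
  Tf <- fusion$Tfus
  lnx <- -fusion$dHfus * (Tf - temperature) /
    (GAS_CONSTANT * Tf * temperature) +
    (fusion$dCp / GAS_CONSTANT) *
      ((Tf - temperature) / temperature + log(temperature / Tf))
  pmin(exp(lnx), 1)
}

#' Activity coefficient
#'
#' `gamma = x_idl / x_e`: the ratio of ideal to experimental mole-fraction
#' solubility. Values near 1 indicate near-ideal solute-solvent
#' interactions; large values indicate a poor solvent.
#'
#' @param x_ideal Ideal mole-fraction solubility, in (0, 1].
#' @param x_exp Experimental mole-fraction solubility, in (0, 1].
#' @return The activity coefficient, vectorized.
#' @export
activity_coefficient <- function(x_ideal, x_exp) {
  if (any(x_ideal <= 0) || any(x_exp <= 0)) {
    stop("solubilities must be strictly positive", call. = FALSE)
  }
  x_ideal / x_exp
}

#' Mean harmonic temperature
#'
#' `Thm = n / sum(1/T_i)`, the reference temperature of the van't Hoff
#' thermodynamic decomposition.
#'
#' @param temperatures Nonempty vector of absolute temperatures (K).
#' @return The harmonic mean (K).
#' @examples
#' harmonic_mean_temperature(seq(298.15, 318.15, by = 5)) # 307.99
#' @export
harmonic_mean_temperature <- function(temperatures) {
  if (length(temperatures) == 0) {
    stop("`temperatures` must be nonempty", call. = FALSE)
  }
  check_temperature(temperatures)
  length(temperatures) / sum(1 / temperatures)
}

#' Apparent dissolution thermodynamics by van't Hoff analysis
#'
#' Regresses `ln x` on `(1/T - 1/Thm)` by ordinary least squares. The
#' slope gives the apparent dissolution enthalpy `dH = -R * slope`; the
#' intercept gives the Gibbs energy at the mean harmonic temperature
#' `dG = -R * Thm * intercept`; the entropy follows from the identity
#' `dS = (dH - dG) / Thm`.
#'
#' @param series Data frame with `temperature` (K) and `x`; at least 3
#'   points.
#' @param thm Mean harmonic temperature (K). Defaults to the harmonic mean
#'   of the series temperatures; pass a fixed value (e.g. 308.15) to
#'   reproduce published tables that round it.
#' @return List with `dH` (J/mol), `dG` (J/mol), `dS` (J/mol/K), `thm`,
#'   `slope`, `intercept`.
#' @export
vanthoff_thermo <- function(series, thm = NULL) {
  series <- check_series(series, 3L, "vanthoff_thermo")
  if (is.null(thm)) thm <- harmonic_mean_temperature(series$temperature)
  if (thm <= 0) stop("`thm` must be positive", call. = FALSE)
  z <- 1 / series$temperature - 1 / thm
  fit <- stats::lm(log(series$x) ~ z)
  intercept <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  dH <- -GAS_CONSTANT * slope
  dG <- -GAS_CONSTANT * thm * intercept
  dS <- (dH - dG) / thm
  list(dH = dH, dG = dG, dS = dS, thm = thm,
       slope = slope, intercept = intercept)
}

#' Enthalpy-entropy compensation analysis
#'
#' Ordinary least-squares regression of the apparent dissolution enthalpy
#' on the Gibbs energy across solvent compositions. A positive slope
#' indicates that dissolution is driven by the same mechanism across the
#' composition range (enthalpy-entropy compensation); the sign of the
#' slope identifies the dominant driving force.
#'
#' @param dH Apparent dissolution enthalpies (J/mol), one per composition.
#' @param dG Apparent Gibbs energies (J/mol), same length, with nonzero
#'   variance.
#' @return List with `slope`, `intercept`, and the underlying `lm` fit.
#' @export
compensation_analysis <- function(dH, dG) {
  if (length(dH) != length(dG) || length(dH) < 2) {
    stop("need >= 2 paired (dH, dG) points", call. = FALSE)
  }
  if (stats::var(dG) == 0) {
    stop("`dG` has zero variance; the compensation slope is undefined",
         call. = FALSE)
  }
  fit <- stats::lm(dH ~ dG)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       fit = fit)
}
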