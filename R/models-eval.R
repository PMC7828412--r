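#' Evaluate the modified Apelblat model
#'
#' Semi-empirical three-parameter correlation of mole-fraction solubility
#' with temperature, `ln x = A + B/T + C ln T`. With `C = 0` it reduces to
#' the van't Hoff model.
#'
#' @param params List or named vector with elements `A` (dimensionless),
#'   `B` (K), `C` (dimensionless).
#' @param temperature Absolute temperature (K), > 0. Vectorized.
#'
#' @return `ln x`, the natural log of mole-fraction solubility.
#' @examples
#' exp(eval_apelblat(list(A = -374.54, B = 14006.70, C = 55.25), 298.15))
#' @export
eval_apelblat <- function(params, temperature) {
  p <- as.list(params)
  check_temperature(temperature)
  p$A + p$B / temperature + p$C * log(temperature)
}

#' Evaluate the van't Hoff model
#'
#' Two-parameter linear correlation of `ln x` with reciprocal temperature,
#' `ln x = a + b/T`.
#'
#' @param params List or named vector with `a` (intercept, dimensionless)
#'   and `b` (slope, K).
#' @param temperature Absolute temperature (K), > 0. Vectorized.
#'
#' @return `ln x`.
#' @examples
#' exp(eval_vanthoff(list(a = -2.72, b = -2997.05), 298.15))
#' @export
eval_vanthoff <- function(params, temperature) {
  p <- as.list(params)
  check_temperature(temperature)
  p$a + p$b / temperature
}

#' Evaluate the Buchowski-Ksiazaczak lambda-h model
#'
#' The lambda-h model describes solid-liquid equilibrium through the
#' implicit relation `ln(1 + lambda (1 - x) / x) = lambda h (1/T - 1/Tm)`.
#' This function returns the closed-form inversion
#' `x = lambda / (exp(lambda h (1/T - 1/Tm)) - 1 + lambda)`,
#' which satisfies the implicit relation identically. At `T = Tm` the
#' solute melts and `x = 1`.
#'
#' @param params List or named vector with `lambda` (> 0, dimensionless),
#'   `h` (K), and `Tm` (melting temperature, K).
#' @param temperature Absolute temperature (K), `0 < T <= Tm`. Vectorized.
#'
#' @return Mole-fraction solubility `x` (linear scale, not log).
#' @export
eval_bkm <- function(params, temperature) {
  p <- as.list(params)
  check_temperature(temperature)
  if (p$lambda <= 0) stop("`lambda` must be > 0", call. = FALSE)
  if (p$Tm <= 0) stop("`Tm` must be > 0", call. = FALSE)
  if (any(temperature > p$Tm)) {
    stop("temperature above the melting temperature `Tm` is out of the ",
         "model's domain", call. = FALSE)
  }
  # expm1 keeps precision near the melting point, where the exponent -> 0
  p$lambda /
    (expm1(p$lambda * p$h * (1 / temperature - 1 / p$Tm)) + p$lambda)
}

#' Evaluate the Yalkowsky log-linear mixing rule
#'
#' Log-linear cosolvency model: the log solubility in the mixed solvent is
#' the composition-weighted average of the pure-solvent log solubilities,
#' `ln xm = (1 - w2) ln x1 + w2 ln x2`.
#'
#' @param lnx1 `ln x` in the primary solvent (here water).
#' @param lnx2 `ln x` in the cosolvent (here Transcutol HP).
#' @param w2 Cosolvent fraction in `[0, 1]`.
#'
#' @return `ln xm` in the mixture. Vectorized.
#' @examples
#' eval_yalkowsky(-12.78, -6.19, 0.2)
#' @export
eval_yalkowsky <- function(lnx1, lnx2, w2) {
  if (any(w2 < 0 | w2 > 1)) {
    stop("`w2` must lie in [0, 1]", call. = FALSE)
  }
  (1 - w2) * lnx1 + w2 * lnx2
}

#' Evaluate the Jouyban-Acree van't Hoff model
#'
#' Combined cosolvency model: per-solvent van't Hoff terms plus
#' composition-temperature interaction terms,
#' `ln x = a1 w1 + a2 w1/T + a3 w2 + a4 w2/T
#'        + J0 w1 w2/T + J1 w1 w2 (w1-w2)/T + J2 w1 w2 (w1-w2)^2/T`
#' with `w1 = 1 - w2`.
#'
#' @param params List with `alpha` (numeric length 4, the van't Hoff terms
#'   of the two pure solvents) and `J` (numeric length 3, the interaction
#'   coefficients, K).
#' @param w2 Cosolvent fraction in `[0, 1]`. Vectorized with `temperature`.
#' @param temperature Absolute temperature (K), > 0.
#'
#' @return `ln x` in the mixture.
#' @export
eval_javh <- function(params, w2, temperature) {
  p <- as.list(params)
  check_temperature(temperature)
  if (any(w2 < 0 | w2 > 1)) stop("`w2` must lie in [0, 1]", call. = FALSE)
  stopifnot(length(p$alpha) == 4, length(p$J) == 3)
  X <- javh_design(w2, temperature)
  drop(X %*% c(p$alpha, p$J))
}

# Design matrix of the seven Jouyban-Acree van't Hoff regressors, in the
# order (w1, w1/T, w2, w2/T, w1w2/T, w1w2(w1-w2)/T, w1w2(w1-w2)^2/T).
javh_design <- function(w2, temperature) {
  w1 <- 1 - w2
  cbind(w1 = w1,
        w1_over_T = w1 / temperature,
        w2 = w2,
        w2_over_T = w2 / temperature,
        J0 = w1 * w2 / temperature,
        J1 = w1 * w2 * (w1 - w2) / temperature,
        J2 = w1 * w2 * (w1 - w2)^2 / temperature)
}

check_temperature <- function(temperature) {
  if (!is.numeric(temperature) || any(temperature <= 0)) {
    stop("`temperature` must be positive (Kelvin)", call. = FALSE)
  }
  invisible(temperature)
}
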