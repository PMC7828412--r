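#' Mean relative deviation (signed)
#'
#' `MRD% = 100/N * sum((x_exp - x_cal) / x_exp)`. The deviations are
#' signed, so over- and under-prediction cancel; use [mrd_abs()] for the
#' magnitude-only variant reported in summary tables.
#'
#' @param x_exp Experimental values, all > 0.
#' @param x_cal Calculated (model) values, same length.
#' @return Signed percentage.
#' @export
mrd <- function(x_exp, x_cal) {
  check_paired(x_exp, x_cal)
  if (any(x_exp <= 0)) stop("`x_exp` must be strictly positive", call. = FALSE)
  100 * mean((x_exp - x_cal) / x_exp)
}

#' Mean relative deviation (absolute)
#'
#' `100/N * sum(|x_exp - x_cal| / x_exp)`: mean magnitude of the relative
#' deviation, the variant used when ranking model fits.
#'
#' @inheritParams mrd
#' @return Percentage >= 0.
#' @export
mrd_abs <- function(x_exp, x_cal) {
  check_paired(x_exp, x_cal)
  if (any(x_exp <= 0)) stop("`x_exp` must be strictly positive", call. = FALSE)
  100 * mean(abs(x_exp - x_cal) / x_exp)
}

#' Root-mean-square deviation
#'
#' `RMSD = sqrt(sum((x_exp - x_cal)^2) / N)`, on the linear mole-fraction
#' scale.
#'
#' @inheritParams mrd
#' @return RMSD in mole-fraction units, >= 0.
#' @export
rmsd <- function(x_exp, x_cal) {
  check_paired(x_exp, x_cal)
  sqrt(mean((x_exp - x_cal)^2))
}

check_paired <- function(x_exp, x_cal) {
  if (length(x_exp) != length(x_cal)) {
    stop("`x_exp` and `x_cal` must have equal length", call. = FALSE)
  }
  if (length(x_exp) == 0) stop("inputs must be nonempty", call. = FALSE)
  invisible(NULL)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero, the
#' convention used when comparing computed values against published table
#' cells (base R `round()` rounds ties to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Fit-quality record shared by all model fits: signed and absolute MRD,
# RMSD (linear-x scale), point count and residuals.
fit_quality <- function(x_exp, x_cal) {
  list(mrd_percent = mrd(x_exp, x_cal),
       mrd_abs_percent = mrd_abs(x_exp, x_cal),
       rmsd = rmsd(x_exp, x_cal),
       n_points = length(x_exp),
       residuals = x_exp - x_cal)
}
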