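#' Mole-fraction solubility in a single solvent
#'
#' Converts a gravimetric measurement (mass of dissolved drug and mass of
#' solvent in the saturated solution) to the mole-fraction solubility
#' `x = (mA/MA) / (mA/MA + m1/M1)`.
#'
#' @param mass_drug Mass of dissolved drug (g). Must be >= 0.
#' @param mass_solvent Mass of solvent (g). Must be > 0.
#' @param molar_mass_drug Molar mass of the drug (g/mol). Must be > 0.
#' @param molar_mass_solvent Molar mass of the solvent (g/mol). Must be > 0.
#'
#' @return Mole-fraction solubility, a number in `[0, 1)`. Vectorized over
#'   all arguments.
#' @examples
#' mole_fraction_single(0.56666, 10, 566.66, 18.015)
#' @export
mole_fraction_single <- function(mass_drug, mass_solvent,
                                 molar_mass_drug, molar_mass_solvent) {
  stopifnot(is.numeric(mass_drug), is.numeric(mass_solvent))
  if (any(mass_drug < 0)) {
    stop("`mass_drug` must be non-negative", call. = FALSE)
  }
  if (any(mass_solvent <= 0)) {
    stop("`mass_solvent` must be strictly positive", call. = FALSE)
  }
  if (any(molar_mass_drug <= 0) || any(molar_mass_solvent <= 0)) {
    stop("molar masses must be strictly positive", call. = FALSE)
  }
  n_drug <- mass_drug / molar_mass_drug
  n_solv <- mass_solvent / molar_mass_solvent
  n_drug / (n_drug + n_solv)
}

#' Mole-fraction solubility in a binary solvent mixture
#'
#' Converts a gravimetric measurement in a two-solvent system to the
#' mole-fraction solubility `x = (mA/MA) / (mA/MA + m1/M1 + m2/M2)`.
#' With `mass_solvent2 = 0` this reduces exactly to
#' [mole_fraction_single()].
#'
#' @param mass_drug Mass of dissolved drug (g).
#' @param mass_solvent1,mass_solvent2 Masses of the two solvents (g); at
#'   least one must be > 0.
#' @param molar_mass_drug,molar_mass_solvent1,molar_mass_solvent2 Molar
#'   masses (g/mol), all > 0.
#'
#' @return Mole-fraction solubility in `[0, 1)`. Vectorized.
#' @export
mole_fraction_ternary <- function(mass_drug, mass_solvent1, mass_solvent2,
                                  molar_mass_drug, molar_mass_solvent1,
                                  molar_mass_solvent2) {
  if (any(mass_drug < 0) || any(mass_solvent1 < 0) || any(mass_solvent2 < 0)) {
    stop("masses must be non-negative", call. = FALSE)
  }
  if (any(mass_solvent1 + mass_solvent2 <= 0)) {
    stop("at least one solvent mass must be strictly positive", call. = FALSE)
  }
  if (any(molar_mass_drug <= 0) || any(molar_mass_solvent1 <= 0) ||
      any(molar_mass_solvent2 <= 0)) {
    stop("molar masses must be strictly positive", call. = FALSE)
  }
  n_drug <- mass_drug / molar_mass_drug
  n1 <- mass_solvent1 / molar_mass_solvent1
  n2 <- mass_solvent2 / molar_mass_solvent2
  n_drug / (n_drug + n1 + n2)
}

#' Cosolvent composition fraction of a binary solvent
#'
#' Solute-free composition fraction of the cosolvent,
#' `w2 = m2 / (m1 + m2)`. Computed from masses; note that although the
#' source tables label this quantity a "mole fraction" of cosolvent, the
#' defining formula is a mass ratio, and it is implemented exactly as such.
#' The value is treated throughout as an abstract composition coordinate.
#'
#' @param mass_cosolvent Mass of the cosolvent (g), the `m2` component.
#' @param mass_solvent Mass of the primary solvent (g), the `m1` component.
#'
#' @return Fraction in `[0, 1]`. Vectorized.
#' @export
cosolvent_fraction <- function(mass_cosolvent, mass_solvent) {
  if (any(mass_cosolvent < 0) || any(mass_solvent < 0)) {
    stop("masses must be non-negative", call. = FALSE)
  }
  if (any(mass_cosolvent + mass_solvent <= 0)) {
    stop("total solvent mass must be strictly positive", call. = FALSE)
  }
  mass_cosolvent / (mass_cosolvent + mass_solvent)
}

#' Read a gravimetric solubility CSV
#'
#' Reads a comma-separated, UTF-8 table with header
#' `solvent_id, T_K, m_drug_g, m_solv1_g, m_solv2_g, M_drug, M_solv1,
#' M_solv2` and returns a tibble with the derived cosolvent fraction `w2`
#' and mole-fraction solubility `x` appended.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `solvent_id`, `temperature` (K), `w2`,
#'   `x`.
#' @export
read_gravimetric_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("solvent_id", "T_K", "m_drug_g", "m_solv1_g", "m_solv2_g",
            "M_drug", "M_solv1", "M_solv2")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("gravimetric CSV is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- mole_fraction_ternary(raw$m_drug_g, raw$m_solv1_g, raw$m_solv2_g,
                             raw$M_drug, raw$M_solv1, raw$M_solv2)
  w2 <- ifelse(raw$m_solv2_g == 0 & raw$m_solv1_g > 0, 0,
               cosolvent_fraction(raw$m_solv2_g, raw$m_solv1_g))
  tibble::tibble(solvent_id = raw$solvent_id, temperature = raw$T_K,
                 w2 = w2, x = x)
}

#' Read a direct mole-fraction solubility CSV
#'
#' Reads a table with header `solvent_id, T_K, w2, x_exp` holding
#' precomputed mole-fraction solubilities.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `solvent_id`, `temperature`, `w2`, `x`.
#' @export
read_solubility_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("solvent_id", "T_K", "w2", "x_exp")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("solubility CSV is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(raw$x_exp <= 0 | raw$x_exp > 1)) {
    stop("`x_exp` must lie in (0, 1]", call. = FALSE)
  }
  tibble::tibble(solvent_id = raw$solvent_id, temperature = raw$T_K,
                 w2 = raw$w2, x = raw$x_exp)
}
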