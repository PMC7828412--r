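#' @title Bundled reference parameter tables
#' @description
#' Published model-parameter tables for the c-Met inhibitor ABN401
#' (molar mass 566.66 g/mol) in eleven pure solvents and in the
#' Transcutol HP-water mixture, shipped as plain CSV under
#' `inst/extdata/`. Scale factors that appear in the published column
#' headers (lambda and h are printed scaled) have been folded in, so every
#' value here is on its natural scale: `lambda` dimensionless, `h` in K,
#' `B` and `b` in K.
#' @name reference-tables
NULL

soluterm_extdata <- function(file) {
  system.file("extdata", file, package = "soluterm", mustWork = TRUE)
}

#' Pure-solvent model parameters
#'
#' Modified Apelblat (`A`, `B`, `C`), van't Hoff (`a`, `b`) and lambda-h
#' (`lambda`, `h`) parameters per pure solvent.
#'
#' @return A tibble with one row per solvent.
#' @export
pure_solvent_params <- function() {
  tibble::as_tibble(utils::read.csv(soluterm_extdata("pure_solvent_params.csv"),
                                    stringsAsFactors = FALSE))
}

#' Binary-mixture model parameters
#'
#' Modified Apelblat, van't Hoff and lambda-h parameters per cosolvent
#' fraction `w2` of the Transcutol HP-water mixture.
#'
#' @return A tibble with one row per composition.
#' @export
twm_params <- function() {
  tibble::as_tibble(utils::read.csv(soluterm_extdata("twm_params.csv"),
                                    stringsAsFactors = FALSE))
}

#' Jouyban-Acree van't Hoff parameters
#'
#' The published seven-parameter set for the Transcutol HP-water mixture.
#'
#' @return A list with `alpha` (length 4) and `J` (length 3), directly
#'   usable with [eval_javh()] and [generate_mixture_grid()].
#' @export
javh_reference_params <- function() {
  raw <- utils::read.csv(soluterm_extdata("javh_params.csv"),
                         stringsAsFactors = FALSE)
  v <- stats::setNames(raw$value, raw$parameter)
  list(alpha = unname(v[c("alpha1", "alpha2", "alpha3", "alpha4")]),
       J = unname(v[c("J0", "J1", "J2")]))
}

#' Yalkowsky log-solubility table
#'
#' The published `ln x` grid of the log-linear mixing rule over 11
#' compositions and 5 temperatures.
#'
#' @return A tibble in long format with columns `w2`, `temperature`,
#'   `lnx`.
#' @export
yalkowsky_reference_table <- function() {
  raw <- utils::read.csv(soluterm_extdata("yalkowsky_lnx.csv"),
                         check.names = FALSE, stringsAsFactors = FALSE)
  temps <- as.numeric(sub("^T_", "", names(raw)[-1]))
  long <- do.call(rbind, lapply(seq_along(temps), function(j) {
    data.frame(w2 = raw$w2, temperature = temps[j], lnx = raw[[j + 1]])
  }))
  tibble::as_tibble(long[order(long$w2, long$temperature), ])
}

#' Fusion properties of the drug
#'
#' Melting temperature and fusion enthalpy from differential scanning
#' calorimetry, with the derived heat-capacity change.
#'
#' @return A [fusion_properties()] record.
#' @export
drug_fusion_properties <- function() {
  raw <- utils::read.csv(soluterm_extdata("fusion_properties.csv"),
                         stringsAsFactors = FALSE)
  v <- stats::setNames(raw$value, raw$property)
  fusion_properties(Tfus = v[["Tfus"]], dHfus = v[["dHfus"]])
}
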