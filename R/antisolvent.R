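#' Select a cosolvent composition for anti-solvent precipitation
#'
#' Liquid anti-solvent precipitation works by injecting a concentrated
#' drug-in-solvent solution into a miscible anti-solvent, driving
#' supersaturation and nucleation. The design rule keeps the solvent share
#' of the final mixture small (the solvent-to-anti-solvent ratio should be
#' below about 0.2) and favors the composition with the lowest predicted
#' equilibrium solubility, which maximizes supersaturation and yields the
#' smallest particles.
#'
#' This function evaluates a fitted Jouyban-Acree van't Hoff model over a
#' composition grid, restricts it to `w2 <= max_solvent_fraction`, and
#' returns the feasible composition with the minimum predicted mole-fraction
#' solubility (ties broken toward smaller `w2`).
#'
#' @param params Jouyban-Acree van't Hoff parameter list (`alpha`, `J`) or
#'   a `soluterm_fit` from [fit_javh()].
#' @param temperature Operating temperature (K).
#' @param max_solvent_fraction Upper bound on the solvent (cosolvent)
#'   fraction `w2`; default 0.2.
#' @param grid Candidate compositions; defaults to `seq(0.1, 1, by = 0.1)`
#'   (w2 = 0 is excluded by default since a drug-free-solvent mixture
#'   cannot carry the drug feed).
#'
#' @return A list with `w2` (selected composition) and `x_pred` (predicted
#'   mole-fraction solubility there).
#' @export
select_antisolvent_composition <- function(params, temperature,
                                           max_solvent_fraction = 0.2,
                                           grid = seq(0.1, 1, by = 0.1)) {
  if (inherits(params, "soluterm_fit")) {
    if (params$model != "javh") {
      stop("composition selection needs a Jouyban-Acree van't Hoff fit",
           call. = FALSE)
    }
    params <- params$params
  }
  if (max_solvent_fraction <= 0 || max_solvent_fraction > 1) {
    stop("`max_solvent_fraction` must lie in (0, 1]", call. = FALSE)
  }
  feasible <- sort(grid[grid <= max_solvent_fraction])
  if (length(feasible) == 0) {
    stop("no grid composition satisfies w2 <= ", max_solvent_fraction,
         call. = FALSE)
  }
  lnx <- eval_javh(params, feasible, temperature)
  # which.min returns the first index on ties; feasible is sorted, so ties
  # break toward the smaller composition
  i <- which.min(lnx)
  list(w2 = feasible[i], x_pred = exp(lnx[i]))
}
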