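#' @title Synthetic solubility data
#' @description
#' Generators that emulate the measurement design of an equilibrium
#' solubility study: a 5-point temperature series per solvent
#' (298.15-318.15 K), an 11-point composition grid for the binary mixture
#' (w2 = 0, 0.1, ..., 1), triplicate measurements averaged arithmetically
#' on the linear-x scale, and multiplicative log-normal noise on x
#' (equivalently additive Gaussian noise on ln x) whose scale is set by a
#' coefficient of variation. Every generator is deterministic given its
#' seed.
#' @name synthetic-solubility
NULL

# One noisy replicate-averaged observation per model prediction. Noise is
# log-normal with E[x] inflated by the usual cv relation, sd(ln x) =
# sqrt(log(1 + cv^2)). Values above 1 (impossible mole fractions) are
# resampled, up to `max_retries` per value.
noisy_observations <- function(pred, noise_cv, replicates, max_retries = 100L) {
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  if (noise_cv == 0) return(pred)
  sdlog <- sqrt(log(1 + noise_cv^2))
  vapply(pred, function(mu) {
    reps <- numeric(replicates)
    for (r in seq_len(replicates)) {
      for (try in seq_len(max_retries)) {
        val <- mu * exp(stats::rnorm(1, 0, sdlog))
        if (val <= 1) break
        if (try == max_retries) {
          stop("could not draw a mole fraction <= 1 after ", max_retries,
               " retries; the generating curve is too close to 1",
               call. = FALSE)
        }
      }
      reps[r] <- val
    }
    mean(reps)
  }, numeric(1))
}

#' Generate a synthetic temperature series
#'
#' Draws replicate solubility measurements from a single-solvent model
#' (van't Hoff, modified Apelblat, or lambda-h), perturbs them with
#' multiplicative log-normal noise, and averages the replicates
#' arithmetically, mimicking a triplicate static-equilibrium measurement.
#'
#' @param model One of `"vanthoff"`, `"apelblat"`, `"bkm"`.
#' @param params Parameter list matching the model (see [eval_vanthoff()],
#'   [eval_apelblat()], [eval_bkm()]).
#' @param temperatures Measurement temperatures (K); default the 5-point
#'   grid 298.15-318.15 K.
#' @param noise_cv Coefficient of variation of the multiplicative noise on
#'   x; default 0.03.
#' @param seed Integer seed; required so runs are reproducible.
#' @param replicates Replicates averaged per point; default 3.
#' @return A tibble with columns `temperature` and `x`.
#' @export
generate_temperature_series <- function(model, params,
                                        temperatures = seq(298.15, 318.15, by = 5),
                                        noise_cv = 0.03, seed, replicates = 3L) {
  model <- match.arg(model, c("vanthoff", "apelblat", "bkm", "javh"))
  if (model == "javh") {
    stop("the Jouyban-Acree van't Hoff model is composition-dependent; ",
         "use generate_mixture_grid()", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  pred <- switch(model,
    vanthoff = exp(eval_vanthoff(params, temperatures)),
    apelblat = exp(eval_apelblat(params, temperatures)),
    bkm = eval_bkm(params, temperatures))
  x <- withr::with_seed(seed, noisy_observations(pred, noise_cv, replicates))
  tibble::tibble(temperature = temperatures, x = x)
}

#' Generate a synthetic mixture grid
#'
#' Draws a full (composition x temperature) solubility surface from a
#' Jouyban-Acree van't Hoff parameter set with the same noise model as
#' [generate_temperature_series()].
#'
#' @param params Jouyban-Acree van't Hoff parameter list (`alpha`, `J`).
#' @param compositions Cosolvent fractions; default `seq(0, 1, by = 0.1)`
#'   (11 points).
#' @param temperatures Measurement temperatures (K); default the 5-point
#'   grid.
#' @inheritParams generate_temperature_series
#' @return A tibble with columns `w2`, `temperature`, `x`.
#' @export
generate_mixture_grid <- function(params, compositions = seq(0, 1, by = 0.1),
                                  temperatures = seq(298.15, 318.15, by = 5),
                                  noise_cv = 0.03, seed, replicates = 3L) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.null(compositions) || length(compositions) == 0) {
    stop("`compositions` must be a nonempty vector of fractions",
         call. = FALSE)
  }
  grid <- expand.grid(temperature = temperatures, w2 = compositions,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$w2, grid$temperature), ]
  pred <- exp(eval_javh(params, grid$w2, grid$temperature))
  x <- withr::with_seed(seed, noisy_observations(pred, noise_cv, replicates))
  tibble::tibble(w2 = grid$w2, temperature = grid$temperature, x = x)
}
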