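#' @title Model fitting for temperature-dependent solubility
#' @description
#' All fitting functions take a temperature series (a data frame with
#' columns `temperature` in K and `x`, the mole-fraction solubility) or a
#' mixture grid (additionally a `w2` column), minimize residuals in
#' `ln x` by default (the models are linear or near-linear there), and
#' score the fit on the linear-x scale with [mrd()], [mrd_abs()] and
#' [rmsd()]. Setting `objective = "linear"` instead minimizes residuals in
#' x itself via Levenberg-Marquardt, warm-started from the log-scale fit.
#' @name solubility-fitting
NULL

new_soluterm_fit <- function(model, params, x_exp, x_cal, extra = list()) {
  structure(c(list(model = model, params = params,
                   quality = fit_quality(x_exp, x_cal)), extra),
            class = "soluterm_fit")
}

#' @export
print.soluterm_fit <- function(x, ...) {
  cat("<soluterm_fit>", x$model, "model,", x$quality$n_points, "points\n")
  cat("  params:",
      paste(names(unlist(x$params)), signif(unlist(x$params), 6),
            sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  MRD %% (abs) = %.3f, RMSD = %.3e\n",
              x$quality$mrd_abs_percent, x$quality$rmsd))
  invisible(x)
}

#' Predict from a fitted solubility model
#'
#' @param object A fit returned by [fit_vanthoff()], [fit_apelblat()],
#'   [fit_bkm()] or [fit_javh()].
#' @param temperature Temperatures (K) at which to predict.
#' @param w2 Cosolvent fractions; required for the Jouyban-Acree van't
#'   Hoff model, ignored otherwise.
#' @param type `"x"` for mole fraction (default) or `"lnx"` for its log.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.soluterm_fit <- function(object, temperature, w2 = NULL,
                                 type = c("x", "lnx"), ...) {
  type <- match.arg(type)
  lnx <- switch(object$model,
    vanthoff = eval_vanthoff(object$params, temperature),
    apelblat = eval_apelblat(object$params, temperature),
    bkm = log(eval_bkm(object$params, temperature)),
    javh = {
      if (is.null(w2)) stop("`w2` is required for the javh model", call. = FALSE)
      eval_javh(object$params, w2, temperature)
    },
    stop("unknown model: ", object$model, call. = FALSE)
  )
  if (type == "lnx") lnx else exp(lnx)
}

check_series <- function(series, min_points, what) {
  if (!all(c("temperature", "x") %in% names(series))) {
    stop("a temperature series needs `temperature` and `x` columns",
         call. = FALSE)
  }
  if (nrow(series) < min_points) {
    stop(what, " requires at least ", min_points, " points, got ",
         nrow(series), call. = FALSE)
  }
  if (any(series$x <= 0 | series$x > 1)) {
    stop("`x` must lie in (0, 1]", call. = FALSE)
  }
  check_temperature(series$temperature)
  series[order(series$temperature), , drop = FALSE]
}

#' Fit the van't Hoff model
#'
#' Ordinary least squares of `ln x` on `1/T`; the solution is exact (no
#' iteration).
#'
#' @param series Data frame with columns `temperature` (K) and `x`
#'   (mole fraction); at least 3 points.
#' @param objective `"log"` (default) minimizes residuals in `ln x`;
#'   `"linear"` refines by Levenberg-Marquardt on the x scale.
#' @return A `soluterm_fit` with `params$a` (intercept) and `params$b`
#'   (slope, K).
#' @export
fit_vanthoff <- function(series, objective = c("log", "linear")) {
  objective <- match.arg(objective)
  series <- check_series(series, 3L, "fit_vanthoff")
  lnx <- log(series$x)
  invT <- 1 / series$temperature
  fit <- stats::lm(lnx ~ invT)
  params <- list(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]))
  if (objective == "linear") {
    params <- refine_linear_x(
      series, params,
      function(p, T) exp(p[["a"]] + p[["b"]] / T))
  }
  x_cal <- exp(eval_vanthoff(params, series$temperature))
  new_soluterm_fit("vanthoff", params, series$x, x_cal,
                   extra = list(data = series, objective = objective))
}

#' Fit the modified Apelblat model
#'
#' Least-squares fit of `ln x = A + B/T + C ln T`. The model is linear in
#' its parameters on the log scale, so the default fit is an exact
#' QR-based least-squares solution; the warm start for the optional
#' linear-x refinement is this solution.
#'
#' @param series Data frame with `temperature` and `x`; at least 4 points
#'   (3 parameters + 1 degree of freedom).
#' @inheritParams fit_vanthoff
#' @return A `soluterm_fit` with `params$A`, `params$B`, `params$C`.
#' @export
fit_apelblat <- function(series, objective = c("log", "linear")) {
  objective <- match.arg(objective)
  series <- check_series(series, 4L, "fit_apelblat")
  lnx <- log(series$x)
  invT <- 1 / series$temperature
  lnT <- log(series$temperature)
  fit <- stats::lm(lnx ~ invT + lnT)
  cf <- stats::coef(fit)
  params <- list(A = unname(cf[1]), B = unname(cf[2]), C = unname(cf[3]))
  if (objective == "linear") {
    params <- refine_linear_x(
      series, params,
      function(p, T) exp(p[["A"]] + p[["B"]] / T + p[["C"]] * log(T)))
  }
  x_cal <- exp(eval_apelblat(params, series$temperature))
  new_soluterm_fit("apelblat", params, series$x, x_cal,
                   extra = list(data = series, objective = objective))
}

#' Fit the Buchowski-Ksiazaczak lambda-h model
#'
#' Nonlinear least squares of the closed-form lambda-h solubility curve
#' against `ln x`, with the constraint `lambda > 0` enforced by fitting
#' `log(lambda)`. Initialization uses the van't Hoff slope `b`: in the
#' small-lambda regime the model behaves as `ln x ~ ln(lambda) - lambda h
#' (1/T - 1/Tm)`, so starts pair each trial `lambda0` with
#' `h0 = -b / lambda0`; the best converged start (lowest SSE) wins.
#'
#' @param series Data frame with `temperature` and `x`; at least 3 points.
#' @param Tm Melting temperature (K); must exceed every data temperature.
#' @param starts Trial values of `lambda0` for the multi-start search.
#' @inheritParams fit_vanthoff
#' @return A `soluterm_fit` with `params$lambda`, `params$h`, `params$Tm`.
#' @export
fit_bkm <- function(series, Tm, objective = c("log", "linear"),
                    starts = 10^seq(-5, 0, by = 1)) {
  objective <- match.arg(objective)
  series <- check_series(series, 3L, "fit_bkm")
  if (Tm <= max(series$temperature)) {
    stop("`Tm` must exceed the largest data temperature", call. = FALSE)
  }
  lnx <- log(series$x)
  T <- series$temperature
  b <- unname(stats::coef(stats::lm(lnx ~ I(1 / T)))[2])

  best <- NULL
  for (lam0 in starts) {
    h0 <- -b / lam0
    # off-path starts can overflow exp() before LM backtracks; those
    # warnings are expected and the start is simply discarded on error
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        lnx ~ log(exp(loglam) /
                    (exp(exp(loglam) * h * (1 / T - 1 / Tm)) - 1 + exp(loglam))),
        start = list(loglam = log(lam0), h = h0),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) {
    stop("fit_bkm failed to converge from any start; ",
         "tried lambda0 = ", paste(signif(starts, 3), collapse = ", "),
         call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  params <- list(lambda = unname(exp(cf[["loglam"]])), h = unname(cf[["h"]]),
                 Tm = Tm)
  if (objective == "linear") {
    params_t <- refine_linear_x(
      series, list(loglam = log(params$lambda), h = params$h),
      function(p, T) {
        lam <- exp(p[["loglam"]])
        lam / (exp(lam * p[["h"]] * (1 / T - 1 / Tm)) - 1 + lam)
      })
    params <- list(lambda = exp(params_t$loglam), h = params_t$h, Tm = Tm)
  }
  x_cal <- eval_bkm(params, series$temperature)
  new_soluterm_fit("bkm", params, series$x, x_cal,
                   extra = list(data = series, objective = objective))
}

#' Fit the Jouyban-Acree van't Hoff model
#'
#' Multiple linear regression of `ln x` on the seven regressors
#' `w1, w1/T, w2, w2/T, w1w2/T, w1w2(w1-w2)/T, w1w2(w1-w2)^2/T`
#' (no intercept); the solution is an exact linear-algebra solve.
#'
#' @param grid Data frame with columns `w2`, `temperature` (K), `x`; must
#'   span at least 3 distinct compositions and 3 distinct temperatures.
#' @return A `soluterm_fit` with `params$alpha` (length 4) and `params$J`
#'   (length 3).
#' @export
fit_javh <- function(grid) {
  if (!all(c("w2", "temperature", "x") %in% names(grid))) {
    stop("a mixture grid needs `w2`, `temperature` and `x` columns",
         call. = FALSE)
  }
  if (length(unique(grid$w2)) < 3 || length(unique(grid$temperature)) < 3) {
    stop("fit_javh requires >= 3 distinct compositions and temperatures",
         call. = FALSE)
  }
  if (any(grid$x <= 0 | grid$x > 1)) stop("`x` must lie in (0, 1]", call. = FALSE)
  check_temperature(grid$temperature)
  X <- javh_design(grid$w2, grid$temperature)
  if (qr(X)$rank < ncol(X)) {
    stop("degenerate design: the Jouyban-Acree regressors are rank ",
         "deficient on this grid", call. = FALSE)
  }
  lnx <- log(grid$x)
  cf <- stats::coef(stats::lm(lnx ~ 0 + X))
  names(cf) <- colnames(X)
  params <- list(alpha = unname(cf[1:4]), J = unname(cf[5:7]))
  x_cal <- exp(eval_javh(params, grid$w2, grid$temperature))
  new_soluterm_fit("javh", params, grid$x, x_cal, extra = list(data = grid))
}

# Levenberg-Marquardt refinement of a log-scale fit under a linear-x
# least-squares objective. `pred` maps (named parameter vector, T) -> x.
refine_linear_x <- function(series, params, pred) {
  p0 <- unlist(params)
  res <- minpack.lm::nls.lm(
    par = p0,
    fn = function(p) series$x - pred(p, series$temperature),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  as.list(res$par)
}
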