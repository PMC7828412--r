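#' KAT-LSER design matrix
#'
#' Builds the regressor matrix of the Kamlet-Taft linear solvation energy
#' relationship
#' `ln x = c0 + c1 alpha + c2 beta + c3 pi_star + c4 Vs dH^2 / (100 R T)`,
#' one row per solvent: an intercept column, the three solvatochromic
#' descriptors (hydrogen-bond donor acidity `alpha`, acceptor basicity
#' `beta`, dipolarity/polarizability `pi_star`), and the cohesive-energy
#' term built from the Hildebrand solubility parameter `delta_H` and the
#' solute molar volume `Vs`.
#'
#' @param descriptors Data frame with columns `alpha`, `beta`, `pi_star`,
#'   `delta_H` (and optionally `solvent_id`, used for row names).
#' @param vs Solute molar volume term, > 0.
#' @param temperature Absolute temperature (K), > 0.
#' @return Numeric matrix with columns `intercept`, `alpha`, `beta`,
#'   `pi_star`, `cohesive`.
#' @export
kat_design_matrix <- function(descriptors, vs, temperature) {
  if (vs <= 0) stop("`vs` must be > 0", call. = FALSE)
  check_temperature(temperature)
  need <- c("alpha", "beta", "pi_star", "delta_H")
  missing <- setdiff(need, names(descriptors))
  if (length(missing)) {
    stop("descriptor table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(descriptors$delta_H < 0)) {
    stop("`delta_H` must be non-negative", call. = FALSE)
  }
  X <- cbind(intercept = 1,
             alpha = descriptors$alpha,
             beta = descriptors$beta,
             pi_star = descriptors$pi_star,
             cohesive = vs * descriptors$delta_H^2 /
               (100 * GAS_CONSTANT * temperature))
  if (!is.null(descriptors$solvent_id)) rownames(X) <- descriptors$solvent_id
  X
}

#' Fit the KAT-LSER regression
#'
#' Ordinary least squares of `ln x` on a KAT-LSER design matrix (see
#' [kat_design_matrix()]). Reports coefficients with standard errors, R
#' squared, the overall F statistic, the residual sum of squares, and the
#' percentage contribution of each non-intercept term, computed as
#' `|c_i| * mean(|regressor_i|)` normalized to 100% (a standard effect
#' decomposition in the LSER literature).
#'
#' On an interpolating fit (residual sum of squares numerically zero) the
#' F statistic is reported as `Inf`.
#'
#' @param lnx Response vector, `ln` mole-fraction solubility per solvent.
#' @param design Design matrix from [kat_design_matrix()] (first column an
#'   intercept).
#' @return List with `coefficients`, `std_errors`, `r2`, `F`, `rss`,
#'   `contributions` (percent, named by the non-intercept columns), `n`.
#' @export
fit_katlser <- function(lnx, design) {
  n <- length(lnx)
  p <- ncol(design)
  if (nrow(design) != n) {
    stop("`lnx` and `design` disagree on the number of solvents",
         call. = FALSE)
  }
  if (n < p + 1) {
    stop("KAT-LSER needs at least ", p + 1, " solvents (", p,
         " coefficients + 1 degree of freedom), got ", n, call. = FALSE)
  }
  if (qr(design)$rank < p) {
    stop("degenerate design: the KAT-LSER regressors are collinear",
         call. = FALSE)
  }
  fit <- stats::lm(lnx ~ 0 + design)
  cf <- stats::coef(fit)
  names(cf) <- colnames(design)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((lnx - mean(lnx))^2)
  r2 <- 1 - rss / tss
  dof <- n - p
  se <- sqrt(diag(rss / dof * chol2inv(qr.R(qr(design)))))
  names(se) <- colnames(design)
  # F for the regression against the intercept-only model
  Fstat <- if (rss < .Machine$double.eps^0.75 * max(tss, 1)) {
    Inf
  } else {
    ((tss - rss) / (p - 1)) / (rss / dof)
  }
  terms <- colnames(design)[-1]
  weight <- vapply(terms, function(j) {
    abs(cf[[j]]) * mean(abs(design[, j]))
  }, numeric(1))
  contributions <- 100 * weight / sum(weight)
  list(coefficients = cf, std_errors = se, r2 = r2, F = Fstat, rss = rss,
       contributions = contributions, n = n)
}

#' Bundled solvent solvatochromic descriptors
#'
#' Loads the Kamlet-Taft descriptors (`alpha`, `beta`, `pi_star`) and
#' Hildebrand solubility parameters (`delta_H`, MPa^0.5) shipped with the
#' package for the ten common solvents of the study set. The values are
#' literature-typical solvatochromic parameters; the file under
#' `inst/extdata` is plain CSV and can be edited or replaced.
#'
#' @return A tibble with columns `solvent_id`, `alpha`, `beta`, `pi_star`,
#'   `delta_H`.
#' @export
solvent_descriptors <- function() {
  path <- system.file("extdata", "solvent_descriptors.csv",
                      package = "soluterm", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
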