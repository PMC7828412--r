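#' Run the full solubility-analysis pipeline
#'
#' Orchestrates the whole analysis end to end: per-solvent model fits
#' (modified Apelblat, van't Hoff, lambda-h), per-composition fits and the
#' Jouyban-Acree van't Hoff surface for the binary mixture, the Yalkowsky
#' log-linear table, activity coefficients from fusion properties,
#' apparent dissolution thermodynamics with enthalpy-entropy compensation,
#' and the anti-solvent composition selection. Results are written as CSV
#' and JSON (no binary formats) together with a machine-readable
#' provenance record (seed, package version, config checksum), so two runs
#' with the same config and seed produce byte-identical payloads.
#'
#' Stage failures do not abort the run: every stage that can still run is
#' run, partial results are written, and a failure manifest names the
#' failing stage and error.
#'
#' @param config A list. Recognized fields (all optional):
#'   \describe{
#'     \item{pure_csv, mixture_csv}{Paths to solubility CSVs in the
#'       `solvent_id, T_K, w2, x_exp` schema. When omitted, synthetic data
#'       are generated from the bundled reference parameters.}
#'     \item{seed}{Integer seed for synthetic data (default 1).}
#'     \item{noise_cv}{Noise coefficient of variation for synthetic data
#'       (default 0.03).}
#'     \item{replicates}{Replicates averaged per synthetic point
#'       (default 3).}
#'     \item{thm}{`"auto"` (harmonic mean of the data temperatures, the
#'       default) or a fixed numeric value such as 308.15.}
#'     \item{max_solvent_fraction}{Cap for the anti-solvent design rule
#'       (default 0.2).}
#'     \item{design_temperature}{Temperature for the anti-solvent design
#'       (default 298.15 K).}
#'     \item{out_dir}{Output directory (default `"results/pipeline"`).}
#'   }
#'
#' @return Invisibly, a list with every stage's result plus `failures`
#'   (empty when all stages succeeded).
#' @export
run_full_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    pure_csv = NULL, mixture_csv = NULL,
    seed = 1L, noise_cv = 0.03, replicates = 3L,
    thm = "auto", max_solvent_fraction = 0.2,
    design_temperature = 298.15,
    out_dir = "results/pipeline"), config)
  if (!is.numeric(cfg$thm) && !identical(cfg$thm, "auto")) {
    stop("`thm` must be \"auto\" or a positive number", call. = FALSE)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  state <- new.env(parent = emptyenv())
  state$failures <- list()
  run_stage <- function(name, f) {
    tryCatch(f(), error = function(e) {
      state$failures[[name]] <- conditionMessage(e)
      message("stage `", name, "` failed: ", conditionMessage(e))
      NULL
    })
  }
  thm_for <- function(temps) {
    if (identical(cfg$thm, "auto")) harmonic_mean_temperature(temps) else cfg$thm
  }
  write_csv_plain <- function(df, file) {
    utils::write.csv(df, file.path(cfg$out_dir, file), row.names = FALSE)
  }
  write_json_plain <- function(x, file) {
    jsonlite::write_json(x, file.path(cfg$out_dir, file),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  ## -- input data ----------------------------------------------------
  pure <- run_stage("load_pure_data", function() {
    if (!is.null(cfg$pure_csv)) return(read_solubility_csv(cfg$pure_csv))
    ref <- pure_solvent_params()
    out <- lapply(seq_len(nrow(ref)), function(i) {
      s <- generate_temperature_series(
        "vanthoff", list(a = ref$a[i], b = ref$b[i]),
        noise_cv = cfg$noise_cv, seed = cfg$seed + i,
        replicates = cfg$replicates)
      tibble::tibble(solvent_id = ref$solvent_id[i],
                     temperature = s$temperature, w2 = NA_real_, x = s$x)
    })
    dplyr::bind_rows(out)
  })
  mixture <- run_stage("load_mixture_data", function() {
    if (!is.null(cfg$mixture_csv)) return(read_solubility_csv(cfg$mixture_csv))
    g <- generate_mixture_grid(javh_reference_params(),
                               noise_cv = cfg$noise_cv,
                               seed = cfg$seed + 1000L,
                               replicates = cfg$replicates)
    tibble::tibble(solvent_id = "twm", temperature = g$temperature,
                   w2 = g$w2, x = g$x)
  })

  fusion <- drug_fusion_properties()
  Tm <- fusion$Tfus

  ## -- per-solvent model fits ----------------------------------------
  pure_fits <- run_stage("fit_pure_solvents", function() {
    dplyr::bind_rows(lapply(split(pure, pure$solvent_id), function(d) {
      series <- d[, c("temperature", "x")]
      fits <- list(apelblat = fit_apelblat(series),
                   vanthoff = fit_vanthoff(series),
                   bkm = fit_bkm(series, Tm = Tm))
      dplyr::bind_rows(lapply(names(fits), function(m) {
        f <- fits[[m]]
        tibble::tibble(solvent_id = d$solvent_id[1], model = m,
                       params = paste(signif(unlist(f$params), 8),
                                      collapse = ";"),
                       mrd_abs_percent = f$quality$mrd_abs_percent,
                       rmsd = f$quality$rmsd, n = f$quality$n_points)
      }))
    }))
  })

  ## -- per-composition fits and the JAVH surface ---------------------
  mixture_fits <- run_stage("fit_mixture_compositions", function() {
    dplyr::bind_rows(lapply(split(mixture, mixture$w2), function(d) {
      series <- d[, c("temperature", "x")]
      fits <- list(apelblat = fit_apelblat(series),
                   vanthoff = fit_vanthoff(series),
                   bkm = fit_bkm(series, Tm = Tm))
      dplyr::bind_rows(lapply(names(fits), function(m) {
        f <- fits[[m]]
        tibble::tibble(w2 = d$w2[1], model = m,
                       params = paste(signif(unlist(f$params), 8),
                                      collapse = ";"),
                       mrd_abs_percent = f$quality$mrd_abs_percent,
                       rmsd = f$quality$rmsd, n = f$quality$n_points)
      }))
    }))
  })
  javh_fit <- run_stage("fit_javh_surface", function() {
    fit_javh(mixture[, c("w2", "temperature", "x")])
  })

  ## -- Yalkowsky log-linear table ------------------------------------
  yalkowsky <- run_stage("yalkowsky_table", function() {
    endpoints <- mixture[mixture$w2 %in% c(0, 1), ]
    if (nrow(endpoints) == 0) {
      stop("mixture data contain no pure-solvent endpoints (w2 = 0, 1)")
    }
    dplyr::bind_rows(lapply(split(mixture, mixture$temperature), function(d) {
      T <- d$temperature[1]
      lnx1 <- log(d$x[d$w2 == 0]); lnx2 <- log(d$x[d$w2 == 1])
      lnx_cal <- eval_yalkowsky(lnx1, lnx2, d$w2)
      tibble::tibble(w2 = d$w2, temperature = T, lnx_yalkowsky = lnx_cal,
                     lnx_exp = log(d$x),
                     mrd_abs_percent = mrd_abs(d$x, exp(lnx_cal)))
    }))
  })

  ## -- ideal solubility and activity coefficients --------------------
  activity <- run_stage("activity_coefficients", function() {
    x_idl <- ideal_solubility(fusion, pure$temperature)
    tibble::tibble(solvent_id = pure$solvent_id,
                   temperature = pure$temperature,
                   x_exp = pure$x, x_ideal = x_idl,
                   gamma = activity_coefficient(x_idl, pure$x))
  })

  ## -- apparent thermodynamics ---------------------------------------
  thermo_pure <- run_stage("thermo_pure", function() {
    dplyr::bind_rows(lapply(split(pure, pure$solvent_id), function(d) {
      th <- vanthoff_thermo(d[, c("temperature", "x")],
                            thm = thm_for(d$temperature))
      tibble::tibble(solvent_id = d$solvent_id[1], dH_J_mol = th$dH,
                     dG_J_mol = th$dG, dS_J_molK = th$dS, Thm_K = th$thm)
    }))
  })
  thermo_mixture <- run_stage("thermo_mixture", function() {
    dplyr::bind_rows(lapply(split(mixture, mixture$w2), function(d) {
      th <- vanthoff_thermo(d[, c("temperature", "x")],
                            thm = thm_for(d$temperature))
      tibble::tibble(w2 = d$w2[1], dH_J_mol = th$dH, dG_J_mol = th$dG,
                     dS_J_molK = th$dS, Thm_K = th$thm)
    }))
  })
  compensation <- run_stage("compensation_analysis", function() {
    comp <- compensation_analysis(thermo_mixture$dH_J_mol,
                                  thermo_mixture$dG_J_mol)
    list(slope = comp$slope, intercept_J_mol = comp$intercept,
         n = nrow(thermo_mixture))
  })

  ## -- anti-solvent design -------------------------------------------
  antisolvent <- run_stage("antisolvent_design", function() {
    sel <- select_antisolvent_composition(
      javh_fit, temperature = cfg$design_temperature,
      max_solvent_fraction = cfg$max_solvent_fraction)
    c(sel, list(temperature_K = cfg$design_temperature,
                max_solvent_fraction = cfg$max_solvent_fraction))
  })

  ## -- write the report bundle ---------------------------------------
  provenance <- list(package = "soluterm",
                     version = as.character(utils::packageVersion("soluterm")),
                     seed = cfg$seed,
                     config = cfg[setdiff(names(cfg), "out_dir")],
                     config_checksum = fnv1a_hash(cfg[setdiff(names(cfg),
                                                              "out_dir")]))
  if (!is.null(pure_fits)) write_csv_plain(pure_fits, "pure_model_fits.csv")
  if (!is.null(mixture_fits)) write_csv_plain(mixture_fits, "mixture_model_fits.csv")
  if (!is.null(javh_fit)) {
    write_json_plain(list(alpha = javh_fit$params$alpha,
                          J = javh_fit$params$J,
                          mrd_abs_percent = javh_fit$quality$mrd_abs_percent,
                          rmsd = javh_fit$quality$rmsd,
                          n = javh_fit$quality$n_points), "javh_fit.json")
  }
  if (!is.null(yalkowsky)) write_csv_plain(yalkowsky, "yalkowsky_table.csv")
  if (!is.null(activity)) write_csv_plain(activity, "activity_coefficients.csv")
  if (!is.null(thermo_pure)) write_csv_plain(thermo_pure, "thermo_pure.csv")
  if (!is.null(thermo_mixture)) write_csv_plain(thermo_mixture, "thermo_mixture.csv")
  if (!is.null(compensation)) write_json_plain(compensation, "compensation.json")
  if (!is.null(antisolvent)) write_json_plain(antisolvent, "antisolvent.json")
  write_json_plain(provenance, "provenance.json")
  write_json_plain(list(ok = length(state$failures) == 0,
                        failures = state$failures), "manifest.json")

  invisible(list(pure_data = pure, mixture_data = mixture,
                 pure_fits = pure_fits, mixture_fits = mixture_fits,
                 javh_fit = javh_fit, yalkowsky = yalkowsky,
                 activity = activity, thermo_pure = thermo_pure,
                 thermo_mixture = thermo_mixture,
                 compensation = compensation, antisolvent = antisolvent,
                 provenance = provenance, failures = state$failures))
}

# Tiny polynomial rolling checksum over the deparsed config; enough to
# tell two configurations apart in a provenance record.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
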