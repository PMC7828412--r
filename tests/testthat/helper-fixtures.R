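# Shared fixtures: reference parameter sets and small builders used across
# the test files. Everything is built in code; nothing is read from disk
# except the package's own bundled CSVs.

table1_water_apelblat <- list(A = -374.54, B = 14006.70, C = 55.25)
table1_water_vanthoff <- list(a = -2.72, b = -2997.05)
table1_thp_vanthoff   <- list(a = 3.92, b = -3010.37)
table1_water_bkm      <- list(lambda = 3.0e-5, h = 8.15e7, Tm = 413.09)
table1_thp_bkm        <- list(lambda = 2.587e-2, h = 1.0647e5, Tm = 413.09)

study_temperatures <- seq(298.15, 318.15, by = 5)

# noiseless series straight from a model curve
series_from_vanthoff <- function(params, temps = study_temperatures) {
  tibble::tibble(temperature = temps, x = exp(eval_vanthoff(params, temps)))
}
series_from_apelblat <- function(params, temps = study_temperatures) {
  tibble::tibble(temperature = temps, x = exp(eval_apelblat(params, temps)))
}
series_from_bkm <- function(params, temps = study_temperatures) {
  tibble::tibble(temperature = temps, x = eval_bkm(params, temps))
}

# independent lambda-h oracle: solve the implicit equation for x by
# bisection instead of using the closed form under test
bkm_root_oracle <- function(lambda, h, Tm, temperature) {
  target <- lambda * h * (1 / temperature - 1 / Tm)
  f <- function(x) log(1 + lambda * (1 - x) / x) - target
  stats::uniroot(f, c(1e-300, 1), tol = 1e-15)$root
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), .Machine$double.eps)),
            tol)
}
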