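test_that("Apelblat evaluation matches published and high-precision values", {
  # with C = 0 the model collapses to van't Hoff at every temperature
  T <- seq(280, 330, by = 2.5)
  expect_equal(eval_apelblat(list(A = -2.72, B = -2997.05, C = 0), T),
               eval_vanthoff(table1_water_vanthoff, T))
  # water parameters reproduce the published lowest solubility 2.8e-6
  x <- exp(eval_apelblat(table1_water_apelblat, 298.15))
  expect_equal(signif(x, 2), 2.8e-6)
  # Transcutol HP parameters at 308.15 K, frozen from 50-digit arithmetic
  expect_equal(eval_apelblat(list(A = 456.50, B = -23707.90, C = -67.25),
                             308.15),
               -5.818186410077828, tolerance = 1e-12)
  expect_error(eval_apelblat(table1_water_apelblat, -1), "positive")
})

test_that("van't Hoff evaluation matches published and hand-computed values", {
  expect_equal(signif(exp(eval_vanthoff(table1_water_vanthoff, 298.15)), 2),
               2.8e-6)
  # b = 0 removes the temperature dependence
  expect_equal(eval_vanthoff(list(a = -5, b = 0), c(280, 300, 320)),
               rep(-5, 3))
  # hand arithmetic: 3.92 - 3010.37/298.15
  expect_equal(eval_vanthoff(table1_thp_vanthoff, 298.15),
               -6.176830454469227, tolerance = 1e-12)
})

test_that("lambda-h closed form inverts the implicit equation", {
  p <- table1_water_bkm
  # melt limit
  expect_equal(eval_bkm(p, p$Tm), 1)
  expect_error(eval_bkm(p, p$Tm + 1), "melting")
  # against an independent bisection root-finder on the implicit equation
  x <- eval_bkm(p, 298.15)
  expect_equal(x, bkm_root_oracle(p$lambda, p$h, p$Tm, 298.15),
               tolerance = 1e-9)
  expect_equal(signif(x, 3), 3.41e-6)
  # defining identity over random parameter draws; draws are kept inside
  # the floating-point-representable regime (exponent below ~500, i.e.
  # x above double-precision underflow)
  set.seed(42)
  n_ok <- 0
  while (n_ok < 50) {
    lam <- 10^runif(1, -5, 0.5)
    h <- 10^runif(1, 2, 8)
    Tm <- runif(1, 350, 500)
    T <- runif(1, 250, Tm)
    if (lam * h * (1 / T - 1 / Tm) > 500) next
    xx <- eval_bkm(list(lambda = lam, h = h, Tm = Tm), T)
    resid <- log(1 + lam * (1 - xx) / xx) - lam * h * (1 / T - 1 / Tm)
    expect_lt(abs(resid), 1e-10)
    n_ok <- n_ok + 1
  }
})

test_that("Yalkowsky mixing rule reproduces published table cells and is affine", {
  # golden cells of the published log-linear table (2 d.p.)
  expect_equal(round_half_up(eval_yalkowsky(-12.78, -6.19, 0.2), 2), -11.46)
  expect_equal(round_half_up(eval_yalkowsky(-12.12, -5.58, 0.3), 2), -10.16)
  expect_equal(eval_yalkowsky(-12.78, -6.19, 0), -12.78)
  expect_equal(eval_yalkowsky(-12.78, -6.19, 1), -6.19)
  # affine in w2: midpoint = mean of endpoints, to machine precision
  expect_equal(eval_yalkowsky(-12.78, -6.19, 0.5),
               mean(c(-12.78, -6.19)))
  expect_error(eval_yalkowsky(-12, -6, 1.2), "0, 1")
})

test_that("van't Hoff fit is exact on noiseless data and robust to noise", {
  s <- series_from_vanthoff(table1_water_vanthoff)
  f <- fit_vanthoff(s)
  expect_rel_equal(unlist(f$params), unlist(table1_water_vanthoff), 1e-10)
  expect_lt(f$quality$rmsd, 1e-18)
  expect_error(fit_vanthoff(s[1:2, ]), "at least 3")
  # seeded 2% noise at 5 temperatures: slope recovered within 10%
  sn <- generate_temperature_series("vanthoff", table1_water_vanthoff,
                                    noise_cv = 0.02, seed = 11)
  fn <- fit_vanthoff(sn)
  expect_lt(abs(fn$params$b - table1_water_vanthoff$b) /
              abs(table1_water_vanthoff$b), 0.10)
})

test_that("Apelblat fit recovers generating parameters and nests van't Hoff", {
  s <- series_from_apelblat(table1_water_apelblat)
  f <- fit_apelblat(s)
  expect_rel_equal(unlist(f$params), unlist(table1_water_apelblat), 1e-6)
  # data from a van't Hoff curve: fitted C ~ 0 and RMSD ~ 0
  sv <- series_from_vanthoff(table1_thp_vanthoff)
  fv <- fit_apelblat(sv)
  expect_lt(abs(fv$params$C), 1e-4)
  expect_lt(fv$quality$rmsd, 1e-12)
  expect_error(fit_apelblat(sv[1:3, ]), "at least 4")
  # 1% multiplicative noise: predictions stay within 3% of the true curve
  sn <- generate_temperature_series("apelblat", table1_water_apelblat,
                                    noise_cv = 0.01, seed = 5)
  fn <- fit_apelblat(sn)
  lnx_true <- eval_apelblat(table1_water_apelblat, sn$temperature)
  lnx_fit <- predict(fn, sn$temperature, type = "lnx")
  expect_lt(max(abs(lnx_fit - lnx_true) / abs(lnx_true)), 0.03)
})

test_that("lambda-h fit recovers generating parameters", {
  for (p in list(table1_water_bkm, table1_thp_bkm)) {
    s <- series_from_bkm(p)
    f <- fit_bkm(s, Tm = p$Tm)
    expect_rel_equal(c(f$params$lambda, f$params$h), c(p$lambda, p$h), 1e-4)
  }
  expect_error(fit_bkm(series_from_bkm(table1_thp_bkm)[1:2, ], Tm = 413.09),
               "at least 3")
  expect_error(fit_bkm(series_from_bkm(table1_thp_bkm), Tm = 300), "exceed")
  # small-lambda regime: ln(1 + u) ~ ln(u) when u = lambda(1-x)/x is
  # large, making the curve log-linear in 1/T with slope -lambda*h; use a
  # steep van't Hoff curve so exp(lambda*h*(1/T - 1/Tm)) >> 1 across the
  # whole range and the expansion actually applies
  sv <- series_from_vanthoff(list(a = 11.44, b = -5922.71))
  fv <- fit_bkm(sv, Tm = 413.09)
  expect_lt(abs(fv$params$lambda * fv$params$h - 5922.71) / 5922.71, 0.05)
})

test_that("Jouyban-Acree van't Hoff fit is an exact linear solve", {
  p <- javh_reference_params()
  g <- generate_mixture_grid(p, noise_cv = 0, seed = 1)
  f <- fit_javh(g)
  expect_rel_equal(unlist(f$params), unlist(p), 1e-8)
  # interaction-free surface reduces to the two van't Hoff curves
  p0 <- list(alpha = p$alpha, J = c(0, 0, 0))
  g0 <- generate_mixture_grid(p0, noise_cv = 0, seed = 1)
  f0 <- fit_javh(g0)
  T <- study_temperatures
  expect_equal(predict(f0, T, w2 = rep(0, 5), type = "lnx"),
               eval_vanthoff(list(a = p$alpha[1], b = p$alpha[2]), T),
               tolerance = 1e-8)
  expect_equal(predict(f0, T, w2 = rep(1, 5), type = "lnx"),
               eval_vanthoff(list(a = p$alpha[3], b = p$alpha[4]), T),
               tolerance = 1e-8)
  # degenerate grid: too few distinct compositions
  expect_error(fit_javh(g[g$w2 %in% c(0, 1), ]), ">= 3 distinct")
  # 3% seeded noise on the full 11x5 grid still refits to MRD <= 10%
  gn <- generate_mixture_grid(p, noise_cv = 0.03, seed = 99)
  fn <- fit_javh(gn)
  expect_lt(fn$quality$mrd_abs_percent, 10)
})

test_that("MRD and RMSD follow their defining formulas", {
  expect_equal(mrd(c(1, 2, 3), c(1, 2, 3)), 0)
  # signed deviations cancel
  expect_equal(mrd(c(2, 2), c(1, 3)), 0)
  expect_equal(mrd(c(1, 2, 4), c(1.1, 1.8, 4.4)), 100 / 3 * (-0.1), tolerance = 1e-12)
  expect_equal(mrd_abs(c(1, 2, 4), c(1.1, 1.8, 4.4)), 10, tolerance = 1e-12)
  expect_error(mrd(c(1, 2), c(1, 2, 3)), "equal length")

  expect_equal(rmsd(c(1, 2), c(1, 2)), 0)
  expect_equal(rmsd(c(0, 0), c(3, 4)), 5 / sqrt(2), tolerance = 1e-12)
  expect_equal(rmsd(2, 7), 5)
  expect_error(rmsd(numeric(0), numeric(0)), "nonempty")
})

test_that("fit quality RMSD is zero iff predictions equal observations", {
  s <- series_from_vanthoff(table1_thp_vanthoff)
  # interpolating fit: residuals at rounding level of x itself
  expect_lt(fit_vanthoff(s)$quality$rmsd, 1e-15 * max(s$x) / min(s$x))
  sn <- generate_temperature_series("vanthoff", table1_thp_vanthoff,
                                    noise_cv = 0.05, seed = 3)
  expect_gt(fit_vanthoff(sn)$quality$rmsd, 0)
})

test_that("Apelblat never fits worse in-sample than its nested van't Hoff", {
  for (seed in 1:5) {
    s <- generate_temperature_series("vanthoff", table1_thp_vanthoff,
                                     noise_cv = 0.04, seed = seed)
    fa <- fit_apelblat(s)
    fv <- fit_vanthoff(s)
    # compare on the fitted (log) scale, where both minimize their SSE
    sse_a <- sum((log(s$x) - predict(fa, s$temperature, type = "lnx"))^2)
    sse_v <- sum((log(s$x) - predict(fv, s$temperature, type = "lnx"))^2)
    expect_lte(sse_a, sse_v + 1e-12)
  }
})

test_that("anti-solvent composition selection matches brute-force search", {
  p <- javh_reference_params()
  grid <- seq(0.1, 1, by = 0.1)
  # exhaustive enumeration oracle at the design cap
  lnx_all <- eval_javh(p, grid, 298.15)
  feas <- grid <= 0.2
  expected_w2 <- grid[feas][which.min(lnx_all[feas])]
  sel <- select_antisolvent_composition(p, 298.15,
                                        max_solvent_fraction = 0.2,
                                        grid = grid)
  expect_equal(sel$w2, expected_w2)
  expect_equal(sel$x_pred, exp(min(lnx_all[feas])))
  # the published surface is monotone increasing in w2 here, so the
  # smallest feasible composition wins
  expect_equal(sel$w2, 0.1)
  # cap = 1 returns the global argmin of the grid
  sel_all <- select_antisolvent_composition(p, 298.15,
                                            max_solvent_fraction = 1,
                                            grid = grid)
  expect_equal(sel_all$w2, grid[which.min(lnx_all)])
  expect_error(select_antisolvent_composition(p, 298.15,
                                              max_solvent_fraction = 0.05,
                                              grid = grid),
               "no grid composition")
})
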