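test_that("fusion heat-capacity change reproduces the published worked example", {
  expect_equal(round_half_up(delta_cp(20320, 413.09), 2), 49.19)
  expect_equal(delta_cp(400, 400), 1)
  expect_equal(delta_cp(10000, 400), 25)
  expect_error(delta_cp(-1, 400), "positive")
  fp <- fusion_properties(413.09, 20320)
  expect_equal(fp$dCp, fp$dHfus / fp$Tfus)
})

test_that("ideal solubility hits the melt limit and the worked value", {
  fp <- fusion_properties(413.09, 20320)
  expect_equal(ideal_solubility(fp, fp$Tfus), 1)
  expect_error(ideal_solubility(fp, fp$Tfus + 5), "melting")
  # frozen from 50-digit term-by-term arithmetic
  expect_equal(ideal_solubility(fp, 298.15), 0.145263747, tolerance = 1e-8)
  expect_equal(round(ideal_solubility(fp, 298.15), 4), 0.1453)
  # continuous and increasing up to the melting point
  T <- seq(250, fp$Tfus, length.out = 200)
  expect_true(all(diff(ideal_solubility(fp, T)) > 0))
})

test_that("activity coefficients are the ideal-to-experimental ratio", {
  expect_equal(activity_coefficient(0.1, 0.1), 1)
  expect_equal(round(activity_coefficient(0.1453, 2.08e-3), 1), 69.9)
  expect_error(activity_coefficient(0.1, 0), "positive")
  # gamma < 1 exactly when the experimental solubility exceeds ideal
  expect_lt(activity_coefficient(0.1, 0.2), 1)
  expect_gt(activity_coefficient(0.2, 0.1), 1)
  # gamma's temperature trend follows the competition between the ideal
  # curve and the experimental curve: it decreases when the experimental
  # van't Hoff slope b is steeper (more negative, in 1/T space) than the
  # ideal curve's local slope everywhere in the range, and increases when
  # it is shallower everywhere; Table-1-steep solvents (water, the
  # alcohols, Transcutol HP) fall in the decreasing regime
  fp <- fusion_properties(413.09, 20320)
  pp <- pure_solvent_params()
  lnx_idl <- log(ideal_solubility(fp, study_temperatures))
  idl_slopes <- diff(lnx_idl) / diff(1 / study_temperatures)
  for (i in seq_len(nrow(pp))) {
    x_e <- exp(eval_vanthoff(list(a = pp$a[i], b = pp$b[i]),
                             study_temperatures))
    gam <- activity_coefficient(ideal_solubility(fp, study_temperatures), x_e)
    if (pp$b[i] < min(idl_slopes)) expect_true(all(diff(gam) < 0))
    if (pp$b[i] > max(idl_slopes)) expect_true(all(diff(gam) > 0))
  }
  expect_lt(pp$b[pp$solvent_id == "water"], min(idl_slopes))
  expect_lt(pp$b[pp$solvent_id == "thp"], min(idl_slopes))
})

test_that("harmonic mean temperature follows n / sum(1/T)", {
  expect_equal(harmonic_mean_temperature(rep(300, 4)), 300)
  expect_equal(harmonic_mean_temperature(c(200, 600)), 300)
  # the 5-point study grid averages to 307.99, not the rounded 308.15
  expect_equal(round_half_up(harmonic_mean_temperature(study_temperatures), 2),
               307.99)
  expect_error(harmonic_mean_temperature(numeric(0)), "nonempty")
})

test_that("van't Hoff thermodynamic decomposition matches closed forms", {
  a <- -2.72; b <- -2997.05
  s <- series_from_vanthoff(list(a = a, b = b))
  th <- vanthoff_thermo(s, thm = 308.15)
  # slope and intercept are analytic for data on an exact van't Hoff line
  expect_equal(th$slope, b, tolerance = 1e-9)
  expect_equal(th$intercept, a + b / 308.15, tolerance = 1e-9)
  expect_equal(th$dH, -8.314 * b, tolerance = 1e-9)
  expect_equal(round(th$dH), 24917)
  expect_equal(th$dG, -8.314 * 308.15 * (a + b / 308.15), tolerance = 1e-9)
  expect_equal(round(th$dG), 31886)
  # Gibbs identity holds to machine precision
  expect_equal(th$dG - th$dH + th$thm * th$dS, 0, tolerance = 1e-9)
  # dH = -R b regardless of the reference temperature
  th2 <- vanthoff_thermo(s)
  expect_equal(th2$dH, th$dH, tolerance = 1e-9)
  expect_equal(th2$thm, harmonic_mean_temperature(s$temperature))
  expect_error(vanthoff_thermo(s[1:2, ]), "at least 3")
})

test_that("compensation analysis recovers exact lines and the published sign", {
  # two points define the line exactly
  comp <- compensation_analysis(c(10, 30), c(0, 10))
  expect_equal(comp$slope, 2)
  expect_equal(comp$intercept, 10)
  # exact synthetic relation dH = 1.5 dG + 10
  dG <- seq(20000, 35000, length.out = 8)
  comp2 <- compensation_analysis(1.5 * dG + 10, dG)
  expect_equal(comp2$slope, 1.5, tolerance = 1e-10)
  expect_error(compensation_analysis(c(1, 2), c(5, 5)), "variance")
  expect_error(compensation_analysis(1, 2), ">= 2")
  # binary-mixture van't Hoff rows give a positive compensation slope
  tw <- twm_params()
  th <- lapply(seq_len(nrow(tw)), function(i) {
    vanthoff_thermo(series_from_vanthoff(list(a = tw$a[i], b = tw$b[i])),
                    thm = 308.15)
  })
  comp3 <- compensation_analysis(vapply(th, `[[`, 0, "dH"),
                                 vapply(th, `[[`, 0, "dG"))
  expect_gt(comp3$slope, 0)
})
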