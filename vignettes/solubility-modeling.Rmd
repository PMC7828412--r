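---
title: "Solubility modeling and dissolution thermodynamics with soluterm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solubility modeling and dissolution thermodynamics with soluterm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soluterm)
```

## The problem

A poorly water-soluble drug candidate (here a c-Met kinase inhibitor,
molar mass 566.66 g/mol) must be formulated so it dissolves fast enough
to be absorbed. The groundwork is a map of its equilibrium solubility:
mole-fraction solubility `x` in a panel of pure solvents and in a binary
cosolvent system (Transcutol HP–water, "TWM") over 298.15–318.15 K.
That map is then mined three ways:

1. **Correlation models** compress each temperature series (and the full
   composition × temperature surface) into a few parameters, allowing
   interpolation and ranking of solvents.
2. **Dissolution thermodynamics** decompose the temperature dependence
   into apparent enthalpy, Gibbs energy and entropy of dissolution,
   telling the formulator whether dissolution is enthalpy- or
   entropy-driven.
3. **Design rules** select the injection composition for liquid
   anti-solvent precipitation, the nanosuspension-manufacturing step:
   drug dissolved in the good solvent (Transcutol HP) is injected into
   the anti-solvent (water), and the composition with the lowest
   equilibrium solubility maximizes supersaturation and nucleation.

`soluterm` implements all of this as a tested package, plus a seeded
synthetic-data generator so every stage can be exercised and validated
without laboratory data. The `analysis/` scripts in the repository walk
the whole chain end to end; `run_full_pipeline()` does the same in one
call.

## Data model and composition arithmetic

Solubility enters either precomputed (`solvent_id, T_K, w2, x_exp`
schema) or gravimetrically, as masses of dissolved drug and solvents
with their molar masses; `mole_fraction_single()` and
`mole_fraction_ternary()` apply

\[
x = \frac{m_A/M_A}{m_A/M_A + m_1/M_1 + m_2/M_2}.
\]

The binary-solvent composition coordinate is `w2 = m2/(m1 + m2)`. The
source tables label `w2` a "mole fraction" of cosolvent, but the
defining formula is a **mass ratio**; we compute it exactly as defined
and treat it as an abstract composition fraction throughout. Masses are
accepted in grams only — no unit inference.

## The five models

With `T` in Kelvin (Celsius is never accepted):

* **van't Hoff (VHM)**: `ln x = a + b/T`. Linear in `1/T`; fit by OLS,
  exact.
* **modified Apelblat (AM)**: `ln x = A + B/T + C ln T`. Although
  traditionally fit by iterative nonlinear regression, the model is
  *linear in its parameters* on the log scale, so the default fit is an
  exact QR least-squares solve. `A` and `C` are strongly collinear over
  a 20 K window; the exact solve sidesteps the convergence issues a
  naive optimizer would have.
* **Buchowski–Ksiazaczak λh (BKM)**:
  `ln(1 + λ(1−x)/x) = λh(1/T − 1/Tm)` with melting temperature `Tm`.
  We use the closed-form inversion
  `x = λ / (exp(λh(1/T − 1/Tm)) − 1 + λ)`, which satisfies the implicit
  equation identically (and gives `x = 1` at `T = Tm`). Fitting is
  genuine nonlinear least squares (Levenberg–Marquardt) with `λ > 0`
  enforced by optimizing `log λ`. Initialization exploits the
  small-λ expansion `ln x ≈ ln λ − λh(1/T − 1/Tm)`: each trial `λ₀` is
  paired with `h₀ = −b/λ₀` from the van't Hoff slope, and the best
  converged start wins. `expm1` keeps the denominator accurate near the
  melting point.
* **Yalkowsky log-linear (YM)**: `ln x_m = w1 ln x1 + w2 ln x2`. A pure
  mixing rule — affine in `w2`, blind to any composition–temperature
  interaction, which is why its deviations are an order of magnitude
  larger than the other models'.
* **Jouyban–Acree van't Hoff (JAVHM)**: the seven-regressor surface
  `ln x = α₁w1 + α₂w1/T + α₃w2 + α₄w2/T + J₀w1w2/T + J₁w1w2(w1−w2)/T +
  J₂w1w2(w1−w2)²/T`. Linear in its parameters; fit by an exact
  no-intercept OLS solve. We store the interaction coefficients as
  `J0, J1, J2`, indexing the sum `Σᵢ Jᵢ(w1−w2)ⁱ` from zero.

**Objective space.** All fits minimize residuals in `ln x`. Solubility
spans three orders of magnitude across this panel, so log-scale
residuals weight every solvent fairly, and all five models are linear or
near-linear there. Fit quality is then reported on the linear-x scale:
`MRD% = 100/N Σ (x_exp − x_cal)/x_exp` (signed, as defined — opposite
deviations cancel) and `mrd_abs()`, the absolute-value variant used to
rank models, plus `RMSD = sqrt(Σ(x_exp−x_cal)²/N)`. Published MRDs are
plausibly absolute; both variants are exposed, and summary tables report
the absolute one. A `objective = "linear"` flag switches any
single-solvent fit to a linear-x least-squares objective
(Levenberg–Marquardt, warm-started from the log fit) for users who want
the alternative convention.

**Reference parameters.** The published parameter tables ship under
`inst/extdata/` as plain CSV with all printed scale factors folded in.
The λ/h columns are printed scaled (`λ·10⁻²`, `h·10⁻³` headers for pure
solvents); we read them as printed value = parameter × scale, giving
e.g. λ = 3.0×10⁻⁵ and h = 8.15×10⁷ K for water — the only reading for
which λh has the magnitude of the van't Hoff slope, as the small-λ
expansion requires.

```{r models}
# water: the published lowest solubility, 2.8e-6 at 298.15 K
signif(exp(eval_vanthoff(list(a = -2.72, b = -2997.05), 298.15)), 2)
# Yalkowsky cell at w2 = 0.2, 298.15 K from the pure-solvent endpoints
round_half_up(eval_yalkowsky(-12.78, -6.19, 0.2), 2)
```

## Dissolution thermodynamics

From fusion properties (`Tfus` = 413.09 K, `ΔHfus` = 20.32 kJ/mol,
measured by DSC) the heat-capacity change is approximated as
`ΔCp = ΔHfus/Tfus` (49.19 J/mol/K) and the ideal solubility as

\[
\ln x_{idl} = -\frac{\Delta H_{fus}(T_{fus}-T)}{R\,T_{fus}\,T}
 + \frac{\Delta C_p}{R}\left[\frac{T_{fus}-T}{T}
 + \ln\frac{T}{T_{fus}}\right],
\]

the standard form whose both terms vanish at `T = Tfus` (so
`x_idl = 1` at the melt). The activity coefficient is
`γ = x_idl / x_e`; `γ ≈ 1` signals near-ideal solute–solvent
interaction (Transcutol HP, γ ≈ 70 is still the panel minimum by far),
γ ≫ 1 a hostile solvent (water, γ in the tens of thousands here).
Whether γ falls or rises with temperature is a competition between the
two curves: γ decreases only where the experimental van't Hoff slope is
steeper (more negative in `1/T`) than the ideal curve's local slope
(about −1800 K over this range) — which holds for water, the alcohols
and Transcutol HP, but not for the shallow-sloped esters/nitriles.

The apparent thermodynamics come from OLS of `ln x` on
`(1/T − 1/T_{hm})`:

\[
\Delta H^\circ_{sol} = -R\,\mathrm{slope},\qquad
\Delta G^\circ_{sol} = -R\,T_{hm}\,\mathrm{intercept},\qquad
\Delta S^\circ_{sol} = (\Delta H^\circ - \Delta G^\circ)/T_{hm},
\]

with `R` fixed at 8.314 J/mol/K. `T_hm` defaults to the computed
harmonic mean of the data temperatures — 307.99 K for the 5-point grid,
although 308.15 K circulates in print — and can be forced to any fixed
value (`vanthoff_thermo(series, thm = 308.15)`) to reproduce published
tables. The Gibbs identity `ΔG = ΔH − T_hm ΔS` holds to machine
precision by construction. `compensation_analysis()` regresses ΔH on ΔG
across mixture compositions; a positive slope (observed here) indicates
enthalpy–entropy compensation with a common dissolution mechanism
across the composition range.

## Solvent-effect (KAT-LSER) regression

`fit_katlser()` regresses `ln x` at fixed temperature on the
Kamlet–Taft solvatochromic descriptors plus a Hildebrand
cohesive-energy term:

\[
\ln x_e = c_0 + c_1\alpha + c_2\beta + c_3\pi^* +
 c_4\frac{V_s\,\delta_H^2}{100\,R\,T}.
\]

Design choices worth noting:

* **Descriptors** ship as an editable CSV of literature-typical values
  (`solvent_descriptors()`); the study's own descriptor appendix is not
  available, so no test pins the regression coefficients to the
  published fit. Transcutol HP has no reliable published descriptors and
  is excluded.
* **Vs** is a user input (default 26.5, the value quoted for this drug
  by Fedors' group-contribution method). The quoted unit (MPa^0.5) is a
  solubility-parameter unit rather than a molar volume, an ambiguity
  that cannot be resolved from the available text; since `Vs` only
  scales one regressor, the choice affects `c₄`'s scale, not the fit.
* **Contributions** per term are `|cᵢ|·mean(|regressorᵢ|)` normalized to
  100% across the four non-intercept terms — standard practice in the
  LSER literature; the published percentages' exact convention is not
  recoverable.
* On an interpolating fit the F statistic is reported as `Inf` rather
  than overflowing.

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested: 5 temperatures (298.15–318.15 K in 5 K steps), 11 compositions
(`w2 = 0, 0.1, …, 1`), triplicate replicates averaged **arithmetically
on the linear-x scale** (matching the measurement protocol), and
multiplicative log-normal noise on `x` — equivalently additive Gaussian
noise on `ln x` with `sd = sqrt(log(1 + cv²))`. Multiplicative noise is
the physical choice when the measured quantity spans three orders of
magnitude; additive noise would drown the water-end values. The default
`noise_cv = 0.03` (3%) is a realistic figure for an HPLC-quantified
equilibrium solubility; per-point uncertainties for this study are not
published. Draws exceeding `x = 1` are rejected and resampled (bounded
retries). Every generator takes a mandatory seed and is deterministic
given it.

```{r generator}
g <- generate_mixture_grid(javh_reference_params(), noise_cv = 0.03,
                           seed = 42)
f <- fit_javh(g)
round(f$quality$mrd_abs_percent, 2) # refit |MRD| in percent
```

What passing tests show — and what they do not: recovery and closure
tests prove the estimators are correct and well-conditioned under the
stated noise model. Real measurements add effects the generator does not
emulate (filtration losses, dilution and calibration error, incomplete
equilibration, polymorphic conversion), so real-data deviations will be
larger and possibly structured; the published ~5–7% MRDs versus our
~1% at 3% noise are consistent with that gap.

## Anti-solvent design

`select_antisolvent_composition()` evaluates a fitted Jouyban–Acree
surface over a composition grid (default `0.1, …, 1`; `w2 = 0` is
excluded because the drug feed must be carried by some solvent),
restricts to `w2 ≤ max_solvent_fraction` (default 0.2, the
solvent-to-anti-solvent design rule), and returns the feasible
composition minimizing predicted solubility, ties toward smaller `w2`.
On the published surface at 298.15 K it selects `w2 = 0.1` — the
composition at which the smallest nanosuspension particles were in fact
obtained.

## Numerical choices and degenerate inputs

* Linear-algebra fits (van't Hoff, Apelblat, JAVHM, KAT-LSER) are exact
  QR solves; rank-deficient designs raise a degenerate-design error
  rather than silently dropping columns.
* The λh fit is multi-start (λ₀ = 10⁻⁵…1); if no start converges the
  error names every start tried. `T > Tm` and `T > Tfus` are
  out-of-domain errors.
* Golden-table comparisons use `round_half_up()` (ties away from zero)
  at the printed number of decimals, since base R's bankers' rounding
  can differ in the last digit.
* The λh identity property is only evaluable while `x` is representable
  in double precision (exponent ≲ 700); the property tests sample inside
  that region.
* Insufficient data (fewer points than parameters + 1) raises an error
  naming the requirement; empty metric inputs, nonpositive `x_exp` in
  MRD, and mismatched lengths all error early.

## Problem sizes

The test suite and the analysis scripts run the study-scale problems
directly: 11 solvents × 5 temperatures, the 11 × 5 mixture grid, 100
seeded refits for the stochastic-recovery check, and 1,000 random
parameter draws for the λh identity. The full suite completes in a few
seconds on one core.

## Known limitations

* Only the stated cosolvency models are implemented — no extended
  Hildebrand, NRTL, UNIQUAC or Wilson, and no preferential-solvation
  (IKBI/QLQC) analysis.
* `ΔCp = ΔHfus/Tfus` is an approximation; no independent heat-capacity
  model is offered.
* The published activity-coefficient table for this drug is internally
  inconsistent with the stated solubilities and fusion properties (its
  values imply γ ≈ 1 where the defining ratio gives γ ≈ 70), so it is
  deliberately not a validation target; our γ values follow the
  defining ratio.
* Molarity/molality conversions and density-based volume fractions are
  out of scope; compositions are the mass-ratio `w2` only.
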