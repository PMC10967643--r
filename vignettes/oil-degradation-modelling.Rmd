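---
title: "Modelling frying-oil degradation: viscosity cascades, ECN and TPC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling frying-oil degradation: viscosity cascades, ECN and TPC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oilcascade)
```

## The problem

Vegetable oil held at frying temperature (around 180 °C) degrades by
hydrolysis, oxidation and polymerisation. Three routine measurements track
this: dynamic viscosity (which rises as polymers form), fatty-acid
composition (polyunsaturates decay, saturates accumulate), and total polar
compounds (TPC, the regulatory disposal criterion — 27% in China, 24–27%
elsewhere). This package ties the three together into a small forecasting
pipeline for rapeseed oil stabilised with the natural antioxidant carnosic
acid (200/400/700 mg/kg; treatments CA-2/CA-4/CA-7) or the synthetic
benchmark TBHQ (200 mg/kg; TB-2), against an unprotected control (C).

## Viscosity–temperature models

Each sweep is viscosity μ (mPa·s) over a 60–110 °C ramp at a fixed shear rate
(the oils are Newtonian, so shear rate is metadata only). Two laws are fitted
by ordinary least squares of ln μ on a transformed temperature:

* **Lioumbas**: $\ln\mu = a + b(\ln T)^2$ with $T$ in °C. `b` (negative)
  controls how fast the oil thins with temperature; `a` sets the scale.
* **Arrhenius**: $\ln\mu = \ln\mu_0 + E_a/(R\,T_K)$ with $T_K = T + 273.15$
  and $R = 8.314$ J/(mol·K); the slope is the flow activation energy.

Both fits report $R^2$ on the log scale they are estimated on, because that
is the scale on which the error is modelled. `compare_models()` prefers the
higher $R^2$, ties going to the Lioumbas model.

**Why Celsius in the Lioumbas law?** The law is empirical and its published
parameter values only make sense with $T$ in °C: with $a = 6.32$,
$b = -0.19$ the Celsius form gives $\mu(60\,°\mathrm{C}) \approx 23$ mPa·s,
the observed magnitude for fresh rapeseed oil, while a Kelvin reading gives
$\approx 0.9$ mPa·s — absurd for any edible oil. The test suite pins this
derivation down.

## The degradation cascade

Fitting the Lioumbas model at each sampling time (0, 8, 16, 24, 32 h) shows
two robust linear relations: `b` decreases linearly in processing time
$t_P$, and `a` is linear in `b` with slopes near −42. `oil_cascade()` chains
them:

$$b(t_P) = s_b t_P + b_0 \quad\rightarrow\quad a(b) = s_a b + a_0
  \quad\rightarrow\quad \mu = \exp(a + b(\ln T)^2)$$

giving viscosity at any (time, temperature). Design points:

* Full-precision per-timepoint fits are propagated through the chain.
  Refitting the trends from parameters rounded to two decimals (as reference
  tables print them) yields visibly different slopes, so the cascade never
  round-trips through printed precision.
* Predictions outside the fitted $t_P$ range are returned but flagged
  (`extrapolated` attribute plus a warning), never silent.
* `parity_analysis()` reports observed − calculated residuals and percent
  deviations. The deviation denominator is the **observed** value, the
  convention of parity plots; it is undefined (an error) at observed zero.
* `fit_b_on_composition()` regresses `b` on ECN and TPC pooled over all
  (treatment × time) conditions — one global plane, reflecting that the
  chemistry, not the antioxidant identity, drives the rheology. The narrow
  ECN range makes this design ill-conditioned, which is why no exact
  coefficient targets are asserted for it.

## Composition metrics

The effective carbon number is
$ECN = \sum_i (P_i/100)(C_i - db_i)$ over the reported fatty acids, with
carbons $C_i$ and double bonds $db_i$ parsed from the shorthand code
(`C18:3n3` → 18 carbons, 3 double bonds; the positional suffix is ignored).
Two conventions matter and are deliberate:

* **No renormalisation.** Printed compositions sum to ~97%, not 100; using
  the percents as printed reproduces 14 of the 15 published ECN cells that
  have a printed composition row to ±0.01, whereas renormalising to 100%
  reproduces none. The one exception (control at 32 h: computed 16.19 vs
  printed 16.23) is an internal inconsistency of the source table, asserted
  as a known deviation in the tests and documented in
  `inst/extdata/README.md`.
* **Rounding** for presentation is half-away-from-zero at two decimals
  (`round_half_up()`), matching the printed tables, not R's half-to-even.

Class totals sum percents by double-bond count (SFA 0, MUFA 1, PUFA ≥ 2);
degradation rates are relative losses in percent.

## TPC trends and the waste point

TPC accumulates approximately linearly in heating time over 0–32 h.
`fit_tpc_trend()` fits the line per treatment ($R^2$ on the original scale;
a zero-residual degenerate fit is defined as $R^2 = 1$) and `waste_point()`
inverts it at the 27% threshold. A fitted intercept already above the
threshold returns a non-positive time flagged `already_exceeded`. Linearity
is an adequate description over this window but has no kinetic basis; do not
extrapolate it far beyond the fitted range.

## Correlation analysis

`pearson_matrix()` computes pairwise Pearson r over one observation per
(treatment × time) condition — 25 in the packaged design — with two-sided
p-values from the t-distribution on $n-2$ degrees of freedom and `*`/`**`
flags at 0.05/0.01. No multiple-testing correction is applied, matching how
such study matrices are conventionally reported; the flags are raw
thresholds. Zero-variance variables get named-NA rows rather than silent
NaNs. Because the pooling unit is a modelling choice (the source study never
states its n), printed correlation strengths are treated as qualitative,
not exact, targets.

## The synthetic-study generator

`generate_study()` produces a full dataset from a `synthetic_config()`:

| parameter | default | rationale |
|---|---|---|
| treatments | 5 rows of `default_treatments()` | the published chain and TPC coefficients per treatment |
| time points | 0, 8, 16, 24, 32 h | the study's sampling plan |
| temperature grid | 60–110 °C by 5 | 11 points across the rheometer ramp |
| `log_noise_sd` | 0.005 | ~0.5% multiplicative viscosity error reproduces Lioumbas R² ≥ 0.998 |
| `tpc_noise_sd` | 0.5% | rapid-tester repeatability (±0.5%) |
| `pufa_decay_rate` | 0.005 /h | yields ~18% PUFA loss over 32 h in the control, as observed |
| `fa_baseline` | fresh rapeseed profile | high-oleic composition summing to ~97% |

Noise is added on ln μ — the fitting scale — which keeps viscosities positive
and makes the error multiplicative, as rheometer error approximately is.
Fatty-acid decay is a first-order surrogate: each PUFA decays as
$\exp(-r\,t_P\,(db-1))$ (linolenate faster than linoleate), and the lost
mass is redistributed onto saturates and monounsaturates proportionally to
their shares — the simplest mass-conserving rule consistent with the
formation of palmitic, stearic and oleic acid from the polyunsaturates. One
RNG stream per study, seeded explicitly and consumed in a fixed
(treatment, time) order, makes datasets bit-reproducible.

What the generator does **not** emulate: triplicate replicates with
instrument-specific error structure, non-linear (late-stage) TPC kinetics,
oxidation-product speciation, trans-isomer formation, or any coupling of the
viscosity noise to composition. Passing recovery tests on synthetic data
therefore demonstrates the statistical machinery, not the chemistry of real
fryers.

## Numerical conventions and degenerate inputs

* All regressions are ordinary least squares (`stats::lm.fit`); independent
  test oracles evaluate the normal equations directly.
* $R^2 = 1 - SS_{res}/SS_{tot}$; when $SS_{tot} = 0$ with zero residuals
  (constant response fitted exactly) $R^2$ is defined as 1.
* Constant regressors raise a classed singular-design error; sweeps need at
  least 3 points, trends at least 3, the composition plane at least 4 with a
  full-rank design.
* Readers canonicalise by grouping and sorting, so results are independent of
  input row order; validation errors cite the offending row.

## Test problem sizes

The suite fits 11-point sweeps, 5-point trends and 25-condition correlation
tables; Monte-Carlo checks use 200 replicate sweeps for bias of `b` and 500
replicates for the $R^2 \ge 0.99$ calibration property. These sizes match
the packaged study design and keep the whole suite in a few seconds.

## Known limitations

* The cascade gives point predictions only; uncertainty is not propagated
  through the chained regressions.
* The published CA-2 TPC trend is reproducible only under a documented
  substitution of its 32 h value (see `inst/extdata/README.md`); the
  packaged table follows the printed values.
* Models are calibrated on one oil, one temperature (180 °C) and 0–32 h;
  transfer to other oils, antioxidant loadings or longer times is untested.
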