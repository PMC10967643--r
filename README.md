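# oilcascade

Modelling the thermal degradation of frying oils from three routine quality
measurements: viscosity–temperature sweeps, fatty-acid composition, and total
polar compounds (TPC). The package targets oil-quality scientists and
quality-control labs who need to forecast when a batch of oil (here, rapeseed
oil stabilised with the natural antioxidant carnosic acid or with TBHQ)
approaches its regulatory waste point during prolonged heating at frying
temperature.

## The models

**Viscosity–temperature.** Each sweep (viscosity μ in mPa·s over 60–110 °C at
fixed shear rate) is fitted with two laws on the log scale:

- Lioumbas: `ln μ = a + b (ln T)²`, with `T` in °C — the empirical law that
  describes vegetable oils over this range almost perfectly (R² ≥ 0.998);
- Arrhenius: `ln μ = ln μ₀ + Ea / (R·T_K)`, `R = 8.314` J/(mol·K) — the
  classical comparison model, giving the flow activation energy `Ea`.

**The degradation cascade.** During heating the Lioumbas curvature `b` drifts
linearly with processing time `t_P` (hours), and the intercept `a` is linear
in `b`. Chaining the two trends through the Lioumbas law yields a forward
model for viscosity at any heating time and temperature:

```
b(t_P) = s_b·t_P + b₀   →   a(b) = s_a·b + a₀   →   μ = exp(a + b (ln T)²)
```

**Composition.** The effective carbon number `ECN = Σ Pᵢ/100 · (Cᵢ − dbᵢ)`
(mass percent, carbons, double bonds per fatty acid) rises as the oil
saturates; degradation rates such as PUFA attrition are
`(initial − final)/initial × 100`.

**TPC and the waste point.** TPC grows linearly in `t_P`; the fitted line's
crossing of the regulatory threshold (27% in China) predicts the disposal
time. A Pearson correlation matrix with t-distribution p-values links all
study variables.

A seeded synthetic-study generator (`generate_study()`) produces complete
datasets with this statistical structure, calibrated to the packaged
reference tables, so every pipeline stage is testable end to end.

## Worked example

```r
library(oilcascade)

# TPC trend and waste point for oil with 700 mg/kg carnosic acid
tpc <- rso_tpc()
ca7 <- tpc[[which(sapply(tpc, attr, "treatment") == "CA-7")]]
trend <- fit_tpc_trend(ca7)
trend
#> Linear trend: TPC [%] = 0.5875 * t_P [h] +6.7  (R^2 = 0.992, n = 5)
waste_point(trend)
#> [1] 34.55319
```

The best-protected oil crosses the 27% TPC disposal threshold only after
~34.6 h of heating at 180 °C, versus ~25.3 h for unprotected oil.

```r
# composition: ECN and PUFA attrition from the packaged tables
profs <- rso_fatty_acids()
ids <- sapply(profs, attr, "sample_id")
compute_ecn(profs[[which(ids == "CA-7-16")]])$rounded
#> [1] 16.2
comp <- composition_summary(profs)
degradation_rate(comp$pufa[comp$sample_id == "C-0"],
                 comp$pufa[comp$sample_id == "C-32"])
#> [1] 18.08...
```

ECN of 16.20 after 16 h, and an 18.08% PUFA loss over 32 h in the
unprotected control (13.84% with 700 mg/kg carnosic acid).

```r
# the degradation cascade on a synthetic control study
study <- generate_study(synthetic_config(seed = 42))
ctrl <- Filter(function(s) attr(s, "treatment") == "C", study$sweeps)
cm <- oil_cascade(ctrl)
cm
#> Viscosity degradation cascade (treatment C)
#>   b(t_P) = -0.0006285 t_P -0.1959   (R^2 = 0.995)
#>   a(b)   = -41.32 b -1.784   (R^2 = 0.999)
#>   fitted over t_P in [0, 32] h; mu = exp(a + b (ln T_C)^2)
predict(cm, t_P = 16, temperature_C = 60)
#> [1] 26.46
```

After 16 h of heating the cascade predicts a viscosity of ~26.5 mPa·s at
60 °C, up from ~23 mPa·s fresh.

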