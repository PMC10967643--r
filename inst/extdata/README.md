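# Packaged reference tables

Measured summary tables from a published thermal-degradation study of
rapeseed oil stabilised with carnosic acid (CA-2/CA-4/CA-7 at 200/400/700
mg/kg) and TBHQ (TB-2 at 200 mg/kg), heated at 180 °C and sampled at
0/8/16/24/32 h. Values are transcribed exactly as printed (triplicate means;
the printed ± dispersions are not carried).

- `rso_fatty_acids.csv` — fatty-acid compositions (mass %) per sample at
  0/16/32 h, long format. Rows sum to ~97%, not 100 (minor species
  unreported); percents are used unrenormalised throughout the package.
- `rso_tpc.csv` — total polar compounds (%) per treatment and time.
- `rso_model_params.csv` — the published per-condition Lioumbas (a, b, R²)
  and Arrhenius (μ0, Ea, R²) viscosity-model parameters. The raw viscosity
  sweeps behind them were not published; these rounded parameters are kept
  for reference and demonstration, not as fitting targets.
- `rso_ecn_reference.csv` — the published effective carbon numbers.
- `rso_fa_class_reference.csv` — the published UFA/MUFA/PUFA class totals.

## Known internal inconsistencies in the source tables

These are properties of the published tables themselves; the fixtures follow
the tables as printed.

1. The published TPC trend for CA-2 (slope 0.8438, intercept 4.9) is only
   reproducible from the TPC table if the CA-2 value at 32 h is 35.5%,
   whereas the table (and the accompanying text) print 32.50%. Refitting the
   printed column gives slope 0.76875, intercept 5.5.
2. The ECN printed for the control at 32 h (16.23) is not derivable from the
   printed control-32h fatty-acid row, which yields 16.19. All other ECN
   cells with a printed FA row agree to ±0.01.
3. The five 0 h fatty-acid rows are identical (same fresh oil), yet the
   printed 0 h ECN row shows 16.13 for four treatments and 16.14 for CA-2;
   the computed value is 16.14. Within rounding noise of the printed
   precision.
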