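Package: oilcascade
Title: Thermal Degradation Modelling of Frying Oils via Viscosity,
    Composition and Polar-Compound Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the thermal degradation of vegetable (rapeseed) frying
    oil stabilised with antioxidants. Fits the empirical Lioumbas
    viscosity-temperature law ln(mu) = a + b (ln T)^2 and the Arrhenius law
    ln(mu) = ln(mu0) + Ea/(R T_K) to viscosity sweeps, chains the fitted
    Lioumbas parameters over processing time into a cascade model that
    predicts viscosity from heating time and temperature, computes effective
    carbon numbers (ECN) and degradation rates from fatty-acid compositions,
    fits total-polar-compound (TPC) trends and regulatory waste points, and
    reports Pearson correlation matrices across the study variables. Includes
    a seeded synthetic-study generator that emulates the statistical
    structure of such experiments, and packaged reference tables from a
    published rapeseed-oil degradation study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
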