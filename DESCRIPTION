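Package: isophys
Title: Statistical-Physics Adsorption Isotherm Models for QCM Binding Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits equilibrium adsorption isotherms with the statistical-physics
    (grand-canonical partition function) family of models: mono-layer and
    double-layer adsorption under ideal-gas or real-gas (van der Waals lateral
    interaction) chemical potentials. Designed for quartz crystal microbalance
    (QCM) measurements of metal-porphyrin complexation: converts injection and
    frequency logs to isotherm curves via the Sauerbrey relation, fits all four
    model forms by multi-start Levenberg-Marquardt least squares, selects the
    descriptive model by AIC with R-squared and RMSE reported alongside,
    computes adsorption energies from the energetic concentration parameters,
    and derives configurational entropy and free-enthalpy curves with
    entropy-peak location. A synthetic-data generator produces isotherms and
    QCM traces with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
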