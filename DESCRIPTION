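Package: acebind
Title: Binding Constants and Thermodynamics from Affinity Capillary
    Electrophoresis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of affinity capillary electrophoresis (ACE) mobility
    data for host-guest binding studies of ionizable analytes with
    cyclodextrins.  Implements a coupled acid-base / 1:1 complexation
    speciation model for the observed electrophoretic mobility as a
    function of pH, temperature and ligand concentrations, with buffer
    viscosity correction from electroosmotic-flow times.  Binding and
    acidity constants are estimated either by a stepwise sequence of
    small nonlinear fits or by a single global multiparameter fit per
    analyte; temperature-linearized pK values are converted to standard
    reaction enthalpies, entropies and Gibbs energies with delta-method
    standard errors.  Includes residual diagnostics (normal versus
    Student-t error models, Kolmogorov-Smirnov tests) and a synthetic-data
    generator that emulates the measurement design for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
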