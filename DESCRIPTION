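Package: oxshelf
Title: Accelerated Shelf-Life Testing and Lipid-Oxidation Kinetics for
    Oxidisable Foods
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for accelerated shelf-life testing (ASLT) of oxidisable
    food products such as fat-based spreads. Computes lipid-oxidation quality
    indices (peroxide value via a hydroperoxide calibration curve,
    para-anisidine value, TOTOX, moisture), fits zero-, first- and
    second-order kinetic models to storage time courses with reaction-order
    selection by R-squared, models the temperature dependence of rate
    constants with the Arrhenius law (activation energy, pre-exponential
    factor, Q10), predicts shelf-life as the time for the index to reach a
    quality limit, and derives Eyring-type activation thermodynamics
    (Gibbs free energy, enthalpy, entropy). A synthetic storage-trial
    generator with Arrhenius-consistent first-order kinetics and
    multiplicative lognormal noise supports validation and parameter-recovery
    studies, and a reference table of published kinetic and thermodynamic
    parameters for six chocolate-spread formulations is included.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
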