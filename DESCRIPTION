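Package: pharmfit
Title: Receptor Pharmacology Curve Fitting and Translational Exposure Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative receptor pharmacology for G-protein-coupled
    receptor agonist programs: four-parameter logistic concentration-response
    fitting, global Black-Leff operational-model fitting with
    transduction-coefficient (log(tau/KA)) ligand-bias analysis, Schild
    regression for surmountable antagonism (dose ratios, pA2, pKB),
    radioligand-binding analyses (one-site saturation, competition with
    Cheng-Prusoff conversion, dissociation kinetics, dpm unit conversion),
    Furchgott-style receptor-depletion efficacy estimation, and the
    unbound-exposure arithmetic (mass-to-molar, free fraction, CSF:plasma
    scaling, Kp,uu, therapeutic index) that links in vitro potency to in vivo
    dosing. Includes seeded synthetic-data generators for every supported
    assay so all analyses are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
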