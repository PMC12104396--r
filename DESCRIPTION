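Package: cyp2c19ddi
Title: CYP2C19 Inhibition Screening, IC50 Estimation and Static-Model DDI Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput fluorometric CYP2C19
    inhibition screens in 96-well plates: percent-inhibition quantification
    against solvent and positive-inhibitor controls, four-parameter-logistic
    IC50 estimation with bootstrap uncertainty, unbound-parameter (IC50,u,
    Ki,u) derivation via the Cheng-Prusoff relation, and the regulatory
    Cmax,u/Ki,u basic static-model drug-drug-interaction risk call. Includes
    a competitive-inhibition kinetic plate simulator with known ground truth,
    fluorescent-standard calibration, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
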