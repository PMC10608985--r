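Package: biomchrom
Title: Biomimetic HPLC Lipophilicity and Plasma-Protein Binding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the chromatographic estimation of drug-candidate
    lipophilicity and plasma-protein binding from biomimetic HPLC systems.
    Fits the Soczewinski-Wachtmeister model (log k versus organic-modifier
    fraction) to isocratic retention data to obtain the extrapolated
    log kw and slope S descriptors on reversed-phase (C-18), immobilized
    artificial membrane (IAM), and cholesterol stationary phases;
    calibrates immobilized-protein (HSA, AGP) columns against reference
    drugs with literature percent plasma-protein binding and converts
    compound retention to binding constants (log K) and percent binding
    via the 101-scaled logistic linearization; runs outlier-aware
    cross-system regressions, correlation matrices, and descriptor summary
    statistics; performs correlation-matrix principal component analysis
    with Varimax rotation of the multi-system descriptor matrix; and
    generates seeded synthetic retention studies for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
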