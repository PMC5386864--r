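Package: teonil
Title: Joint-Linkage QTL Mapping and Kernel Composition Calibration for
    Teosinte Near-Isogenic Line Libraries
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multi-parent
    near-isogenic line (NIL) libraries such as the teosinte introgression
    libraries in the B73 maize background.  Simulates backcross-self
    (e.g. BC4S2) pedigrees on a genetic map with Haldane-model crossovers
    and generates plot-level phenotypes with a known QTL architecture;
    computes entry least-squares means, broad-sense heritability from
    variance components, and phenotypic correlations; maps QTL jointly
    across families by forward stepwise regression with family-nested
    marker effects, permutation-based genome-wide thresholds, per-family
    additive allelic effects, and 1-LOD support intervals.  A chemometrics
    module implements multiplicative scatter correction, Savitzky-Golay
    derivatives, NIPALS PLS1 calibration of NIR spectra, and
    single-predictor NMR calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
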