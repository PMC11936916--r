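Package: cvrflow
Title: Cerebral Blood Flow and Cerebrovascular Reactivity from Phase-Contrast MRI
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies whole-brain cerebral blood flow from velocity-encoded
    (phase-contrast) cine MRI of the internal carotid and vertebral arteries and
    computes cerebrovascular reactivity (CVR) to hypoxic and hypercapnic
    respiratory challenges. Implements background phase correction, per-vessel
    flow quantification over cardiac bins, brain-mass normalisation, temporal
    alignment of continuous end-tidal gas recordings with scan acquisitions, a
    group-model rule reconciling vertebral-artery measurements between two slice
    placements, correction of hypoxic CVR for concomitant end-tidal CO2 changes,
    and test-retest reliability statistics (one-way intraclass correlation,
    variance components, exact Wilcoxon signed-rank tests, random-intercept
    coefficients of determination). A seeded synthetic cohort generator emulates
    the physiological structure of a four-phase gas protocol at flow and image
    fidelity so that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, RNifti, yaml
Suggests: testthat (>= 3.0.0), lme4, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
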