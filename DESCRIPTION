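Package: ufdce
Title: Kinetic Markers from Ultrafast Dynamic Contrast-Enhanced Breast MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise estimation of the two heuristic kinetic markers of
    ultrafast dynamic contrast-enhanced (DCE) breast MRI: maximum slope (MS)
    of the gadolinium concentration uptake curve and bolus arrival time (BAT).
    Provides spoiled gradient-echo (SPGR) signal-to-concentration conversion
    with fixed pre-contrast T1 and relaxivity, a gradient-based backward
    search for the bolus arrival time, ROI aggregation over lesion masks, a
    seeded synthetic-cohort generator that emulates the clustered structure
    of a breast-cancer ultrafast DCE study (multiple lesions per patient,
    subtype-dependent kinetics), and the accompanying statistical layer:
    generalized estimating equations for clustered lesions, two-reader
    intraclass correlation, multivariate logistic modelling, and paired ROC
    comparison by DeLong's test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
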