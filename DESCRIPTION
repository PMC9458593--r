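Package: sriaquant
Title: Digital Quantification of Interstitial Fibrosis in Renal Implantation Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-assisted measurement of the Sirius red-stained
    interstitial area (SRIA) of renal cortex on stained section images,
    with frozen-versus-paraffin method-agreement statistics (Bland-Altman
    limits of agreement with a proportional-bias test, two-way consistency
    average-measures intraclass correlation, quadratic-weighted Cohen's
    kappa), translation of the continuous fibrosis fraction into the
    Remuzzi interstitial-fibrosis grade, and logistic modelling of delayed
    graft function with a univariate screen and variance-inflation-factor
    collinearity checks.  Includes a synthetic-histology generator that
    emits paired frozen/paraffin cortex images with pixel-exact ground
    truth and a synthetic clinical cohort generator, so the whole pipeline
    is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
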