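Package: vasctrack
Title: Longitudinal Quantification of Corneal Vascularization from En-Face Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify corneal vascularization and its response to
    anti-angiogenic treatment from longitudinal en-face angiography images
    (OCT angiography and indocyanine green angiography). Provides motion
    artefact removal and denoising, automated rigid registration of
    follow-up scans with a common overlay region, multiscale Hessian
    vessel enhancement and binarization, vessel density and vessel growth
    density computation with pixelwise change maps, same-session
    repeatability assessment, and Bland-Altman, correlation and paired
    test statistics for between-modality agreement. A ground-truthed
    synthetic study generator simulates suture-induced corneal vascular
    trees that grow toward concentric suture rows and regress under
    simulated treatment, rendered with modality-specific noise, so every
    stage of the pipeline is verifiable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    jsonlite,
    png,
    ggplot2,
    generics,
    igraph,
    EBImage,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
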