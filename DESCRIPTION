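Package: budscale
Title: Shake-Flask Hydrodynamics and Image Quantification for Engineered
    Living Materials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the dependence of engineered-living-material (ELM) size
    on shake-flask culture conditions through a composite hydrodynamic
    predictor, the modified volumetric power P_V,A = d^5 * kLa * (P/V_L),
    built from the modified Newton number power correlation for unbaffled
    flasks and a dimensional orbital-shaker oxygen mass-transfer (kLa)
    correlation.  Provides inverse design of shaking frequency or fill
    volume for a target P_V,A, segmentation-based quantification of
    apparent material size from flask-bottom photographs (top-5-percentile
    mean of calibrated piece areas), a binary-mask overlap statistic for
    matrix-composition staining, unimodal response fitting to extract the
    optimal P_V,A operating window, and seeded synthetic-data generators
    for every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
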