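Package: cortexshape
Title: Membrane Shape and Actin Cortex Mechanics of Reconstituted Liposomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image analysis of actomyosin cortices encapsulated
    in giant unilamellar vesicles (GUVs): particle image velocimetry and
    cumulative compressive strain of the contracting actin network, structure
    tensor orientation fields and nematic order of the cortex, membrane
    contour extraction with circularity, membrane strain and actin polarity
    metrics, angular deformation power spectra with Helfrich-form scaling
    fits, autocorrelation deformation size, Pratt circle-fit local curvature,
    sub-resolution cortex thickness from two-peak radial line scans, and a
    closed-form active-cortex tension model.  A synthetic scene generator
    produces ground-truth two-channel timelapse stacks (membrane and actin)
    so every analysis stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
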