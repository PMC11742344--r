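Package: phycoscan
Title: Hyperspectral Detection and Relative Quantification of Phycocyanin in Lake Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-situ hyperspectral core-scanning analysis of
    sedimentary pigments, centred on the cyanobacterial pigment phycocyanin.
    Provides reflectance calibration against white and dark reference frames,
    continuum removal by upper convex hull, relative absorbance band depth
    (RABD) and band area (RABA) trough indices at 620 nm (phycocyanin) and
    660-675 nm (chlorins), spiking-series normalisation, ordinary
    least-squares calibration models with tenfold cross-validated RMSEP,
    chlorophyll-a spectral-interference diagnostics, downcore index profiles,
    ENVI cube input/output, and a synthetic spiking-experiment generator with
    known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
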