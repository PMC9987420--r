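Package: driftdose
Title: Dosimetric Consequences of Intrafraction Tumor Drift in Lung SBRT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation study of target dose degradation caused by
    intrafraction tumor drift in lung stereotactic body radiotherapy
    (SBRT). Generates digital respiratory lung phantoms (3x3 grid of
    tumor diameters and superior-inferior motion amplitudes, eleven
    breathing phases), composes MIP/AVG CT and GTV/ITV/PTV structures,
    synthesizes a surrogate SBRT dose distribution with the prescription
    isodose (65% or 85% of maximum) on the PTV surface, perturbs the plan
    by rigid isocenter shifts, and quantifies DVH endpoint degradation
    (delta-D99/delta-D95 for ITV and GTV) per shift and as a
    probability-weighted mean over a 3-D normal drift distribution
    (Maxwell radial binning), plus a first-order dose-gradient prediction
    of the boundary dose error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
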