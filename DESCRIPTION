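Package: tipshape
Title: Microtubule Tip Architecture and Tip Protein Stoichiometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of microtubule (MT) end architecture and
    tip-bound protein stoichiometry from three complementary assays.
    Protofilament (PF) flare geometry is measured from ordered 3D contour
    traces (uniform arc-length resampling, quadratic LOESS smoothing,
    discrete inter-segment curvature, flare length, per-end summaries,
    tip-aligned curvature profiles and curvature-length correlation).
    Single-molecule TIRF photometry converts diffraction-limited spot
    intensities into molecule counts against a single-fluorophore lognormal
    calibration. Kymograph trace tables are converted into dynamic
    instability metrics (growth rates, the 15-second pause rule,
    catastrophe frequency, end-state categories, time-weighted rate
    distributions) and FRAP recovery curves. Synthetic-data generators with
    known ground truth exercise every pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
RoxygenNote: 7.3.3
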