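Package: laminaRD
Title: Cortical Column-Based, Depth-Resolved Diffusivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Depth-resolved analysis of diffusion-tensor metrics in the
    cortical gray matter. Builds cortical columns from index-matched pial
    and white/gray-interface surface vertices, samples scalar diffusivity
    maps along each column at 21 equidistant cortical depths, averages the
    profiles within regions of interest and eight 10 percent depth bins,
    screens region-by-depth-bin combinations with directional Welch tests
    under Benjamini-Hochberg false-discovery-rate control, and converts the
    screened combinations into an individualized logistic-regression
    percentile score of similarity to cognitively normal versus dementia
    reference groups. Includes a spherical-shell diffusion MRI phantom and
    cohort simulator, a log-linear diffusion-tensor fitter, and an
    end-to-end pipeline with the secondary analysis variants (single depth
    bin, voxel-based averaging, axial/mean diffusivity, fractional
    anisotropy, cortical thickness).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
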