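Package: mridvc
Title: Digital Volume Correlation for Load-Bearing Musculoskeletal MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subset-based digital volume correlation (DVC) for pairs of 3D MRI
    volumes acquired in reference and loaded states, built around the
    measurement of sub-millimetre meniscal displacement under axial knee
    loading. Provides MRI-like phantom synthesis with known ground-truth
    displacement fields, bone-referenced rigid registration, normalized
    cross-correlation subset matching with tricubic subvoxel refinement,
    mask-restricted directional displacement statistics, and imposed-shift
    measurement-uncertainty assessment. Volumes, masks and displacement
    fields are read and written as NIfTI-1 images and delimited tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
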