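Package: hodomap
Title: Track-Wise Lesion-Deficit Mapping with Automated Lesion Delineation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hodological (track-wise) lesion-symptom mapping in
    stroke cohorts: automated single-case lesion delineation by voxel-wise
    Crawford-Howell outlier statistics against a control reference,
    quantification of white-matter disconnection as the overlap volume
    between binary lesion maps and thresholded probabilistic tract atlases,
    covariate-adjusted per-tract regression of behavioural deficits on
    disconnection with Bonferroni correction, and a simplified mass-univariate
    voxel-wise GLM with permutation-based cluster-extent inference. Includes a
    deterministic scorer for the Birmingham Cognitive Screen complex-figure
    copy task with its global/local decomposition, and a synthetic-cohort
    generator (control volumes, ellipsoidal lesions, tube-like probabilistic
    tracts, behaviour from a known disconnection-to-deficit model) so the
    full pipeline can be exercised end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
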