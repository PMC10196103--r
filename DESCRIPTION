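Package: sellarqst
Title: Multi-Tissue Sellar MRI Segmentation and QST Classification of
    Craniopharyngiomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sagittal magnetic resonance images of the
    sellar region in patients with craniopharyngioma. Implements a
    seven-class tissue label schema with NIfTI input/output, a synthetic
    sellar phantom generator with controllable Q/S/T tumour morphology, Dice
    and classification metrics with a stratified cross-validation harness, a
    34-feature clinical shape/volume/position extractor, a nine-item
    rule-based clinical scale for Q/S/T subtype diagnosis, a 2D
    encoder-decoder segmentation network with a cross-resolution
    feature-swapping layer and deep supervision, and a multimodal
    classification network fusing image-derived and clinical features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
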