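Package: aspectsct
Title: Automated ASPECTS Scoring and Ischemic Lesion Segmentation for
    Non-Contrast Head CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end pipeline for detecting early ischemic change on
    non-contrast head CT and converting it into the Alberta Stroke Program
    Early CT Score (ASPECTS). Builds three-channel mirror-difference inputs
    that exploit left-right brain symmetry, segments hypodense lesions with
    a dual-path (coarse global + full-resolution local) convolutional
    network trained with a combined cross-entropy and Dice loss, registers
    a 20-label middle-cerebral-artery territory atlas to the subject with
    an affine transform, and scores each territory from lesion overlap
    proportions. Includes a synthetic brain-phantom generator for fully
    reproducible cohorts, region-based ROC analysis, and the multi-reader
    statistics battery (intraclass correlation, McNemar, paired t,
    jackknife confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
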