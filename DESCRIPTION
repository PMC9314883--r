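Package: persardose
Title: Personalized Local SAR Dosimetry for Parallel-Transmit MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for subject-specific local specific absorption rate
    (SAR) prediction in ultra-high-field parallel-transmit (PTx) MRI.
    Generates seeded synthetic head phantoms with MR-like intensity bias,
    estimates and removes 7T receive/transmit bias fields from DREAM B1+
    mapping data, segments T1-weighted-like volumes into eight tissue
    classes with a 2.5D multi-decoder convolutional network trained with a
    Dice loss, and computes 10 g-averaged SAR, per-voxel Q-matrices,
    random-RF-shim exposure statistics and safety margins.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
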