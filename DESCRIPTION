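Package: tauwm
Title: White-Matter Tau Pathology Analysis on Simulated AT8 Slide Images
Version: 0.1.0
Authors@R:
    person("tauwm", "Developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for quantifying phosphorylated-tau pathology
    in the white matter of AT8-immunostained slide images across three
    tauopathies (Alzheimer disease, progressive supranuclear palsy, and
    corticobasal degeneration). Provides a synthetic slide generator with
    pixel-perfect ground truth, patch-based fully convolutional region
    segmentation (background / cortex / white matter), UNet-style aggregate
    segmentation with an auxiliary edge-amount loss, per-aggregate morphometry
    (nine size and shape features), random-forest artifact filtering with
    texture features, cohort-level burden and profile statistics,
    multiple-instance disease classification, and embedding-based model
    interpretation. All neural networks are small CPU models implemented on
    top of BLAS matrix products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
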