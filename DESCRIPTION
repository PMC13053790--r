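Package: lvmech
Title: Left-Ventricular Mechanics of Infarction and Epicardial Patch
    Implantation with Collagen Histology Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element simulation of the post-infarction left ventricle
    with a transversely isotropic exponential (Guccione-type) passive law and
    length-dependent active fiber tension. Builds three-layer truncated-ellipsoid
    hexahedral meshes with helical fiber fields, infarct thinning and an
    epicardial patch layer; solves static end-diastolic and end-systolic
    equilibria under follower endocardial pressure; and computes ejection
    fraction, regional fiber strain and strain-reduction comparisons between
    control, infarcted and patch-implanted models. A companion image-analysis
    component quantifies collagen birefringence class ratios, fiber-orientation
    histograms with median-peak normalization, and trichrome fibrosis fractions,
    validated against a ground-truthed synthetic image generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    png,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
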