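Package: pvatscope
Title: Perivascular Adipose Tissue Attenuation Quantification from CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies perivascular adipose tissue (PVAT) attenuation around
    a vessel from a CT volume and a co-registered binary vessel mask. Rings at
    physical millimetre offsets from the vessel surface are built with an
    anisotropic Euclidean distance transform, adipose voxels are selected in a
    Hounsfield-unit window, and two attenuation indices (the close/distant
    difference and ratio) are derived per subject with a volumetric thickness
    quality check. Includes synthetic CT phantom and two-group cohort
    generators with ground truth, the downstream cohort statistics
    (normality-gated group comparisons, univariate logistic screening,
    variance-inflation-factor filtering, multivariate logistic regression,
    ROC analysis with Youden cut-offs), slice-wise fat attenuation rendering,
    and report assembly.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
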