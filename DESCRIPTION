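Package: msanet
Title: Multimodal Regional MRI Group Analysis with Extended Network-Based Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Atlas-based regional analysis of multimodal brain MRI cohorts:
    extraction of regional grey/white matter weighted volumes, diffusion scalars
    (FA, MD), fiber-bundle counts and Pearson functional-connectivity networks
    from parcellated volumes; region-wise two-sample statistics with
    Benjamini-Hochberg FDR control; the extended network-based-statistics
    (extended-NBS) permutation test on connectivity difference networks;
    clinical correlation with quantile-quantile outlier screening; and
    per-region multimodal feature fusion classified by a deterministic linear
    support vector machine under nested leave-one-out cross-validation. A
    seeded synthetic-cohort generator reproduces the statistical structure the
    analysis assumes, so the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Rcpp,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    igraph,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
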