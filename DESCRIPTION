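Package: coexcell
Title: Single-Cell Oncogene Coexpression Subpopulations in Lymphoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies MYC/BCL2/BCL6 coexpression subpopulations within
    CD20-positive B cells from segmented multiplexed-immunofluorescence cell
    tables, computes spatial interaction statistics (pair correlation function,
    k-nearest-neighbour composition deviations), predicts subpopulation extents
    from single-marker scores under a probabilistic independence model, infers
    extents from bulk mRNA by smoothed empirical-CDF quantile mapping, and pools
    unit-increment Cox proportional-hazards effects across cohorts with a
    Paule-Mandel random-effects model. Includes a synthetic cohort generator so
    the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    survival,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
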