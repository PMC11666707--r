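Package: phinet
Title: Inference of Phage-Host Cross-Infection Networks from Mutation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts strain-level phage-bacteria infection phenotypes from
    binary mutation profiles of coevolved phage and host strains. Quantifies
    efficiency of plating (EOP) from plaque assays, binarizes interactions
    into presence-or-absence (POA) and log-transforms positive efficiencies
    (EFF), builds five per-pair feature models (host-only, phage-only,
    linear, nonlinear, mixed) over the mutation profiles, fits
    LASSO-regularized logistic and linear regressions with cross-validated
    penalty selection, validates them with bootstrap out-of-bag resampling
    against Bernoulli and mean null models, and prioritizes putative driver
    mutations by bootstrap feature-importance analysis. Includes a synthetic
    coevolution data generator with planted effects for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
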