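Package: contactImpute
Title: Imputation of Missing 3D Chromatin Contact Maps by Deep Tensor
    Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assembling biosample-by-assay grids of binned
    chromosome conformation contact maps, normalizing them, and imputing
    the missing grid cells. The core model learns embeddings for
    biosamples, assays, genomic bins, and bin-pair distances, and combines
    them through a multilayer perceptron trained with Adam to predict
    normalized contact counts; row-, column- and cross-mean baselines,
    contact-map summaries (contact decay profiles, compartment
    eigenvectors, insulation scores), cross-entity correlation and
    clustering analyses, and a synthetic contact-map grid generator with
    planted compartment, domain and decay structure are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    Rcpp,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ContactGrid-methods.R'
    'ContactMap-methods.R'
    'RcppExports.R'
    'baselines.R'
    'simulate.R'
    'preprocess.R'
    'model.R'
    'features.R'
    'evaluate.R'
    'io.R'
    'cli.R'
    'contactImpute-package.R'
    'utils.R'
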