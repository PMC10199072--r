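Package: npgen
Title: Generation, Curation and Characterization of Natural-Product-Like
    Compound Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A generate-curate-characterize toolkit for natural-product-like
    virtual libraries. Trains a token-level LSTM language model on SMILES of
    known natural products, samples new molecules, curates them (syntactic
    validity, canonical-SMILES/InChI deduplication, structure-quality
    checking with penalty scores, standardization, parent extraction), scores
    natural-product-likeness from atom-centred fragment frequencies, and
    benchmarks the generated library against the training distribution with
    descriptor panels, Kullback-Leibler divergence, held-out recovery and
    2-D chemical-space maps. Molecule-level chemistry is delegated to the
    RDKit toolkit through a bundled batch interface.
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: Python (>= 3.8) with the rdkit package, available as
    "python" on the PATH.
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
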