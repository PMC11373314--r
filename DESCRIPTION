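Package: fraglinkr
Title: Fragment Linking with a Graph Variational Autoencoder and
    Controllable Latent Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for fragment-based molecular design by linker generation.
    A variational autoencoder over molecular graphs encodes a fragment pair
    and builds a linker bond-by-bond under valency constraints, using either
    plain graph convolutions or node-edge co-embedding (CensNet-style)
    layers.  A controllable generation module fits a Gaussian mixture over
    the learned latent space together with per-attribute classifiers
    (drug-likeness, synthetic accessibility, activity) and rejection-samples
    latent seeds whose product of classifier scores survives a Bernoulli
    accept, enriching generated sets for multi-property objectives.  Includes
    a synthetic fragment-linker data generator, a six-metric evaluation
    suite (validity, uniqueness, novelty, synthetic accessibility, ring
    aromaticity, PAINS), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    Matrix,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
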