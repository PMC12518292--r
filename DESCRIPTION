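Package: spectracae
Title: Compositional Autoencoders for Genotype-Environment Disentanglement
    from Plot-Level Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Disentangles genotype, macro-environment, and micro-environment
    signals from plot-level multispectral satellite imagery of replicated
    field trials using a compositional autoencoder: a multilayer
    encoder/decoder pair joined by a fusion layer whose latent space is
    partitioned into a genotype block shared across a genotype's plots, one
    macro-environment block per trial location, and one micro-environment
    block per plot. Training combines a mean-squared reconstruction loss
    with a Pearson correlation penalty that decorrelates the latent blocks.
    Includes a vanilla-autoencoder baseline, thirteen vegetation indices,
    PCA/silhouette disentanglement diagnostics, genotype-grouped
    cross-validated yield prediction with gradient-boosted trees,
    top-fraction rank-overlap and unseen-environment protocols, and a
    seeded synthetic generator of multispectral trial imagery with known
    genotype-by-environment structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
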