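Package: survaug
Title: Cross-Modal Variational Autoencoder Augmentation for Survival Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Data augmentation for discrete-time survival prediction on paired
    tabular omics. Trains variational autoencoders for two modalities (e.g. DNA
    methylation and gene expression), aligns their latent spaces with a
    cross-modal reconstruction loss and, optionally, a least-squares adversarial
    discriminator, imputes missing samples of one modality from the other with
    survival-label carry-over, and oversamples loss-filtered imputations while
    training a 30-interval discrete-time survival network. Includes a synthetic
    paired-omics generator with shared latent factors and right-censored
    outcomes, time-dependent concordance, bootstrap confidence intervals, and
    one-sided Wilcoxon signed-rank model comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
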