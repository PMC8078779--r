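Package: omixaug
Title: GAN-Based Sample Augmentation for Cancer Stage Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting tumour stage (I-IV) from small, imbalanced
    multi-omics cohorts. Genes are ranked by random-forest importance computed
    on binary DNA-mutation profiles and gated by a permutation p-value; the
    matched mRNA expression matrix restricted to the selected genes is
    batch-corrected with ComBat and then expanded with per-stage generative
    adversarial networks whose latent space is drawn from the per-gene mean and
    standard deviation of the training data. Baseline augmenters (per-stage
    Gaussian sampling, SMOTE, denoising-autoencoder expansion), three
    classifiers (1-D convolutional network, multilayer perceptron, random
    forest) and a repeated stratified 70/30 evaluation harness with t-tests,
    PCA diagnostics, subsampling and augmentation-fold sweeps are included,
    together with a synthetic cohort simulator with planted stage signal so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    sva,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
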