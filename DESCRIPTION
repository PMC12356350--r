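Package: ecgfactors
Title: Disentangled Latent Factor Analysis of 12-Lead ECG Median Beats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deep phenotyping of the 12-lead electrocardiogram through
    disentangled representation learning. Provides a synthetic ECG, phenotype
    and genotype generator with known ground truth; median-beat preprocessing
    (R-peak detection, per-sample median, first-order baseline removal, QRS
    sample weighting); a beta variational autoencoder trained on median beats
    with validation-based epoch selection, reconstruction quality control and
    latent factor traversals; association machinery for latent factors
    (Pearson correlation, linear, logistic and Cox proportional hazards
    models, an effective-number-of-independent-tests estimator and Bonferroni
    threshold arithmetic, and an additive-dosage variant scan); and rendering
    of variant effects on ECG morphology through the decoder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    survival,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
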