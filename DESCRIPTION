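Package: foldcvae
Title: Convolutional Variational Autoencoder Clustering of Protein Folding
    Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised deep clustering of protein-folding molecular dynamics
    trajectories. Frames are featurized as binary C-alpha contact maps (8 Angstrom
    cutoff) and compressed by a convolutional variational autoencoder trained with
    a binary cross-entropy reconstruction loss plus a Kullback-Leibler latent
    regularizer. The latent space is characterized with t-SNE projections,
    negative-log-histogram landscape estimates and seeded k-means state
    assignment, and validated against two folding reaction coordinates: RMSD to
    the native structure (Kabsch superposition) and the fraction of native
    contacts Q. Includes a seeded synthetic-trajectory generator with
    folded, partially folded, unfolded and misfolded metastable states so the
    whole pipeline is testable without external simulation data, and supports
    transferring a trained model to independent trajectories of the same system.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    bio3d,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
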