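Package: eegfactors
Title: Latent-Factor Decoding of Multichannel EEG for Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised latent-factor decoding of multichannel EEG with
    autoencoder-like neural networks (a plain autoencoder, a Gaussian-Bernoulli
    restricted Boltzmann machine trained by contrastive divergence, and a
    variational autoencoder), alongside FastICA and PCA baselines. Decoded
    per-sample factor sequences are classified into binary emotional states by
    a many-to-one LSTM under leave-one-subject-out cross-validation. Includes a
    ground-truth linear mixing-model simulator with class-modulated sources, a
    handcrafted EEG feature bank (time-frequency, nonlinear-dynamical and
    hemispheric-asymmetry features), reconstruction and F1 scoring, and a small
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    signal,
    pracma,
    e1071,
    randomForest,
    class
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
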