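# eegfactors

Latent-factor decoding of multichannel EEG for cross-subject emotion
recognition, in R.

Multichannel EEG is modelled as a noisy linear mixture of a small set of
latent source processes, `E ≈ M S`, where `E` is the `n × t`
channels-by-time matrix, `M` an unknown `n × m` mixing matrix and `S` the
`m × t` latent factor activations. The package fits five unsupervised
per-time-sample decoders for `S` — a one-hidden-layer autoencoder (AE), a
Gaussian-Bernoulli restricted Boltzmann machine trained by contrastive
divergence (GRBM, with unrolling into an AE and backprop fine-tuning), a
variational autoencoder maximizing the evidence lower bound

    L(θ, φ; x) = ½ Σⱼ (1 + log σⱼ² − μⱼ² − σⱼ²) + E_q[log p(x | z)],
    z = μ + σ ⊙ ε,  ε ~ N(0, I),

plus FastICA and PCA baselines — and asks whether the decoded factors
carry emotional information: each trial's factor sequence is sampled at a
fixed step (0.25 s), fed to a many-to-one LSTM (LSTM → dense ReLU →
softmax), and scored under leave-one-subject-out cross-validation with
the F1 measure `2PR/(P + R)`. Reconstruction fidelity is scored per
channel by the Pearson correlation between the original and the
encode→decode reconstruction (with a restart-averaged counterpart-matching
protocol for ICA, whose component order is ambiguous).

It is written for researchers in affective computing / computational
neuroscience who want a self-contained, dependency-light reference
implementation whose every stage is testable offline: a ground-truth
mixing-model simulator (distinct per-subject mixing matrices, independent
band-limited/heavy-tailed sources, Gaussian sensor noise, class-dependent
amplitude modulation) stands in for registration-gated public corpora. A
handcrafted-feature bank (9 time-frequency + 9 nonlinear-dynamical
features per channel per rhythm, 14 hemispheric-asymmetry pairs per
rhythm — 2360 dimensions for a 32-channel trial) and six classical
baselines (L1-penalized linear SVM, random forest, k-NN, logistic
regression, naive Bayes, MLP) are included for comparison.

## Worked example

```r
library(eegfactors)

# a synthetic 4-subject study: 10 trials x 30 s each, 8 channels, 3 sources,
# positive trials double the amplitude of source 1
cfg <- synthetic_config(n_subjects = 4, trials_per_subject = 10,
                        trial_seconds = 30, amplitude_ratio = 2,
                        master_seed = 2020)
ds <- make_labeled_dataset(cfg)
ds$recordings[[1]]
#> <Recording> subject s01 trial t01: 8 channels x 3840 samples @ 128 Hz

# z-score per subject, pool time samples, fit a 3-factor VAE
recs <- zscore_by_subject(ds$recordings)
pooled <- do.call(rbind, lapply(recs, function(r) t(r$data)))
vae <- fit_vae(pooled, m = 3, epochs = 10, seed = 1)
vae
#> <VAEModel> n=8 m=3 L=1, 10 epochs, final -ELBO 2.836 (recon 1.627 + KL 1.209)

# how faithfully do 3 latent factors reconstruct 8 channels?
rep <- reconstruction_report(vae, recs)
rep
#> <ReconstructionReport> vae_m3 (m=3): mean r = 0.9126 over 8 channels
round(rep$channels, 3)
#>   ch1   ch2   ch3   ch4   ch5   ch6   ch7   ch8
#> 0.947 0.821 0.973 0.981 0.881 0.961 0.958 0.778

# full pipeline: VAE factors -> 0.25 s sequences -> LSTM, leave-one-subject-out
cv <- loso_cv(ds, decoder = "vae", m = 3,
              decoder_args = list(epochs = 10, batch = 500, lr = 0.003),
              step_seconds = 0.25,
              lstm = lstm_config(lstm_units = 64, dense_units = 32,
                                 batch = 10, epochs = 60, lr = 0.002),
              seed = 1)
cv
#> <CVResult> vae (m=3): mean F1 = 0.9444 over 4 subjects
round(cv$per_subject, 3)
#>   s01   s02   s03   s04
#> 0.889 1.000 1.000 0.889
```

The mean reconstruction r of 0.91 says three latent factors explain most
of the eight-channel signal (they were generated from three sources); the
per-subject F1 around 0.89–1.00 says the class-modulated source survives
decoding, sequence thinning and cross-subject transfer — each held-out
subject is classified by a model that never saw any of their data.

A thin command-line wrapper covers the same stages
(`inst/cli/eegfactors simulate|decode|reconstruct-eval|loso|features`),
writing a run manifest (config, seeds, input checksums) next to every
artifact.

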