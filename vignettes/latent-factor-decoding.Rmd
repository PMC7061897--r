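---
title: "Latent-factor decoding of multichannel EEG: models, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-factor decoding of multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegfactors)
```

## The model

Multichannel EEG is treated as a noisy linear mixture of a small number of
latent source processes: with `E` the `n x t` channels-by-time matrix, `M`
an unknown `n x m` mixing matrix and `S` the `m x t` source activations,

    E ≈ M S,        S ≈ D E,   D ≈ M⁻¹ (pseudo-inverse).

Everything in this package revolves around estimating `S` (the latent
factor sequences) from `E` without labels, and then asking whether those
factors carry emotion-related information. Five decoders share one
interface (`fit_* -> encode -> reconstruct`), all operating on the channel
vector of a single time sample:

* **PCA** — the top-`m` eigenvectors of the channel covariance;
  reconstruction is the orthogonal projection onto the principal subspace.
  A dimension-reduction baseline, not a source model.
* **FastICA** — whitening to `m` dimensions followed by the symmetric
  fixed-point iteration with the logcosh contrast. Identifiability needs
  non-Gaussian or temporally structured sources, which the simulator
  provides by construction. Because ICA leaves component order and sign
  ambiguous, reconstruction quality is scored by the counterpart-matching
  protocol: each original channel is paired with the reconstructed signal
  of highest correlation (duplicates permitted, lowest index on ties), and
  the matched correlations are averaged over independent restarts
  (default 10). A strict one-to-one mode is available.
* **Autoencoder (AE)** — one hidden layer `h = f(W1 x + b1)`, linear
  output `x̂ = W2 h + b2`, untied weights, trained by Adam on mean squared
  reconstruction error. With linear activations its optimum coincides with
  the PCA projection, which the tests exploit as an oracle.
* **Gaussian-Bernoulli RBM (GRBM)** — Gaussian visible units (unit scale;
  inputs are z-scored), binary hidden units, energy
  `E(x, h) = Σᵢ (xᵢ − aᵢ)²/2 − Σⱼ bⱼ hⱼ − Σᵢⱼ xᵢ Wᵢⱼ hⱼ`,
  trained by CD-k (default k = 1, sampled hiddens, mean-field visibles,
  SGD with momentum 0.5). The partition function is never evaluated. After
  CD the model can be unrolled into a symmetric AE (encoder `W1 = Wᵀ`,
  sigmoid; decoder `W2 = W`, linear) and fine-tuned by backpropagation;
  with zero fine-tuning epochs the unrolled AE reproduces the GRBM's
  mean-field reconstruction exactly, which pins the unrolling convention.
* **VAE** — a linear recognition model produces the posterior mean `μ` and
  log-variance per latent dimension; a linear decoder maps a
  reparameterized draw `z = μ + σ ⊙ ε` back to channel space. The
  objective is the evidence lower bound with the Gaussian KL term in
  closed form and a unit-variance Gaussian likelihood, so the
  reconstruction term reduces to a scaled squared error; optimization is
  RMSprop with one Monte-Carlo sample (`L = 1`). At inference the
  encoding is the deterministic `μ` — required for reproducible sequence
  classification.

Downstream, each trial's factor sequence is thinned at equal intervals
(default step 0.25 s, indices `round(k·step·fs)` strictly inside the
trial) and the resulting short sequence is classified many-to-one by an
LSTM: `LSTM(units) -> dense(relu) -> softmax(2)`, dropout on the two fully
connected layers, binary cross-entropy, RMSprop, full backpropagation
through time. Defaults mirror the reference architecture for full-montage
EEG (200 LSTM units, 100 dense, batch 50).

Evaluation is leave-one-subject-out: per fold, the decoder, the factor
standardization and the classifier are fitted on the training subjects
only, and the held-out subject's trials are scored with the F1 measure
(`2PR/(P+R)`), which tolerates the class imbalance that rating-based
binarization produces. Ratings above five are positive, below five
negative; exactly five is excluded by default (the boundary belongs to
neither class; assigning it to the negative class is a config option).

## The synthetic study

Real affective-EEG corpora require registration, so the package carries a
generator that emulates the study design rather than the biophysics: per
subject, a mixing matrix drawn as a shared template plus Gaussian
perturbation (sd 0.1 of the template scale — cross-subject structure with
individual variability, making LOSO nontrivial); independent band-limited
AR(2), noisy-sinusoid and heavy-tailed Laplace sources; additive Gaussian
sensor noise; and a class effect that multiplies one source's amplitude by
a configurable ratio in positive trials. Default study dimensions are
desk-scale: 4 subjects x 10 trials x 30 s at 128 Hz, 8 channels, 3
sources, noise sd 0.1, amplitude ratio 2 — chosen so the full
generate -> decode -> sequence -> LSTM -> LOSO pipeline runs in about a
minute while keeping the recovery problem honest (an oracle classifier on
the true sources reaches F1 ≈ 1, and the LOSO pipeline is expected above
0.8 rather than at 1.0).

What the simulator does *not* emulate: volume-conduction head geometry,
non-stationarity, artifacts, 1/f spectra, or rating noise. Passing tests
therefore demonstrate that the estimators and the pipeline are correct
and leak-free on data obeying the model's own assumptions — not that the
pipeline attains any particular accuracy on real recordings.

## Parameters that matter

| Parameter | Default | Notes |
|---|---|---|
| decoder batch | 500 | per-time-sample training; large corpora |
| decoder epochs | 20 (AE/VAE), 10 (GRBM) | loss plateaus within the cap |
| AE learning rate | 0.01 Adam, 1/t decay 0.1 | decay sharpens the plateau |
| VAE learning rate | 0.003 RMSprop | log-variance clamped to ±10 |
| GRBM lr / momentum | 0.01 / 0.5 | CD-1; sigma fixed at 1 |
| latent count `m` | swept 2..n/2 | headline setting `m = n/2` |
| sequence step | 0.25 s | trial length / step = steps per sequence |
| LSTM units / dense | 200 / 100 | scaled to 64/32 for 3-factor synthetic runs |
| dropout | 0.5 | the rate is unstated upstream; configurable |
| LSTM epochs | cap 100, early stop | patience 8 on <0.1% relative improvement |
| band edges (Hz) | θ 4–8, α 8–13, β 13–30, γ 30–45 | conventional; configurable |
| filter | Butterworth order 4, zero-phase | phase matters for asymmetry features |

## Numerical and design choices

* **Observation unit.** Decoders see one time sample's channel vector;
  temporal context belongs entirely to the LSTM stage. Sample counts in
  the hundreds of thousands per subject only make sense per time point.
* **Normalization.** Each subject's channels are z-scored over that
  subject's own full data, independently of every other subject — no
  cross-subject statistics flow anywhere, so the held-out subject is never
  contaminated. Whether to z-score per trial instead is open upstream; per
  session is the default here.
* **Decoder training data within LOSO.** Pooled training-subject samples
  only. Fitting one decoder per subject is available programmatically but
  pooled-per-fold is the default: it is the only reading that is
  simultaneously leakage-safe and cross-subject.
* **AE activations.** tanh hidden, linear output: z-scored targets are
  unbounded, and a bounded output unit could not reconstruct them.
* **GRBM energy.** The implemented energy is the standard Gaussian-visible
  form, the unique one consistent with the logistic hidden conditional and
  the Gaussian visible conditional; the enumeration tests check the
  conditionals against the Boltzmann distribution directly.
* **L1-SVM.** The objective `Σ hinge + C‖w‖₁` is solved by FISTA on a
  Huber-smoothed hinge (smoothing 0.1, configurable): the proximal step
  yields exact zero patterns and the smoothing can be tightened
  arbitrarily. Note the convention: `C` multiplies the *penalty*, so the
  nonzero-weight count shrinks as `C` grows; sweeps are warm-started from
  the sparse end. Fully converged solutions can still show occasional
  single-step count inversions at the nearly-unpenalized end of the path —
  that is a property of the objective, not of the solver — so sparsity
  sweeps are read in the selective regime.
* **Degenerate inputs.** Constant channels z-score to zeros with a
  warning; constant series yield zero Hjorth/entropy values with warnings
  rather than NaN; every nonlinear-dynamics estimator that fails returns 0
  with a warning so feature vectors stay finite. Pearson correlation of a
  constant series is reported as 0, and F1 with an empty denominator as 0,
  both with warnings.
* **NDS estimator budgets.** The correlation-integral estimators
  (correlation dimension, K2, Lyapunov, approximate entropy) are quadratic
  in series length, so series are evenly thinned to `max_points` (default
  300) before embedding; all estimator parameters (embedding dimension 3,
  tolerance 0.2 sd, Theiler window 10, 20-step divergence horizon, C0
  threshold 5x mean spectral power, 1 s peak-peak windows, 16 histogram
  bins) are arguments, echoed into run manifests. They are declared
  defaults, not values inherited from any reference analysis.
* **Training-dynamics checks** are run at matched capacity (latent count =
  true source count): over-provisioned nonlinear models keep slowly
  refining their fit and never show a crisp plateau, which is a statement
  about the optimization landscape, not a defect of the data.
* **Determinism.** Every fit is bit-reproducible given (data, config,
  seed); all stochastic stages draw from R's RNG seeded explicitly, and
  pipeline manifests record seeds, configs and input checksums.

## Problem sizes used by the test suite

Unit tests run on mixtures of 1–10 k samples; the end-to-end acceptance
checks use the default 4x10x30 s study (40 sequences of 120 steps), a
40 k-sample plateau fixture, and 10-seed repetitions for the stochastic
claims. The whole suite completes in a few minutes on one core.

## Known limitations

* The EDF importer covers continuous 16-bit recordings with a common
  sampling rate; EDF+ annotations and discontinuous files are out of
  scope. Adapters for registration-gated public corpora are deliberately
  not bundled with tests.
* The linear VAE/AE encoders cannot represent nonlinearly mixed sources;
  the simulator is linear by design, so this is consistent in-package but
  a real-data limitation.
* `reconstruction_report` assumes all recordings share one montage.
* The strict counterpart-matching mode is greedy (max-correlation first),
  which recovers the exact permutation whenever each channel's true
  counterpart dominates its row but is not a globally optimal assignment
  in adversarial cases.
* Multiclass (>2) emotional states are not supported; the second of two
  softmax outputs is the positive class by convention.
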