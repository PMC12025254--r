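# duformer

Binary classification of multi-channel EEG with **DU-former**: a
dual-branch temporal–spatial convolution front end, Transformer encoder
blocks using **separable multi-head self-attention** (linear in sequence
length), and a **Gaussian reparameterization** head that models each
segment's feature embedding as a distribution `N(mu, diag(sigma^2))`
rather than a point. The intended use case is pre/post-intervention
discrimination of 16-channel resting EEG (e.g. memory-training studies
comparing sessions T1 vs T5), analysed per frequency band.

The package ships the full experimental stack around the model:

* **Preprocessing**: zero-phase 4th-order Butterworth filtering
  (0.5–50 Hz), ICA-based ocular artifact removal (reference-correlation
  threshold r > 0.8), myogenic suppression by a high-frequency power
  criterion, spherical-spline bad-channel interpolation, decomposition
  into the seven canonical bands (Delta 1–4 … Gamma 30–50 Hz), and 2 s /
  1 s sliding-window epoching into 16 × 2000 segments.
* **Model + training**: the network and its backprop are implemented in
  vectorized base R; Adam with early stopping; ablation switches for the
  attention and reparameterization modules; CNN, EEGNet-style and
  plain-Transformer baselines behind the same interface.
* **Evaluation**: stratified or subject-wise k-fold cross-validation with
  accuracy, precision, recall, F1 and rank AUC; a Mann–Whitney U test
  (exact for small tie-free samples) for behavioral comparisons.
* **Uncertainty**: Monte-Carlo predictive entropy per sample, the
  occurrence-rate histogram, and the fraction of predictions below an
  uncertainty threshold (0.3 by default).
* **Synthetic EEG generator**: labeled 16-channel recordings with
  band-limited oscillations over 1/f background, a controllable
  band-specific class power ratio, and ground-truth ocular/myogenic
  artifacts — so the entire pipeline is testable without human data.
* **I/O**: EDF read/write with the canonical montage, CSV/JSON metric
  tables with config hashes, and a command-line interface
  (`inst/cli/duformer.R`) with subcommands `simulate`, `preprocess`,
  `train`, `evaluate`, `compare`, `ablate`, `uncertainty`, `stats`.

## The model in brief

For a band-filtered segment `X ∈ R^{16×2000}`:

1. Two convolution branches share a 1×25 temporal kernel and a 16×1
   spatial kernel; the large branch (stride s, BatchNorm, ReLU) sets the
   token count T, the small branch (finer stride, ReLU, adaptive max-pool
   to T, LayerNorm) is fused with it by elementwise sum into tokens
   `Z ∈ R^{T×E}`.
2. Two pre-norm encoder blocks apply separable attention
   `SAttn(I, K, V) = σ(V) ⊙ Σ_t softmax_t(I) K_t` per head (context scores
   from a scalar token projection I; one context vector per head; ReLU
   gate σ) and a 2-layer FFN, each with residuals.
3. A mean branch (token conv → average pool → LayerNorm) gives `mu`; a
   variance branch (average pool → LayerNorm → softplus + floor) gives
   `sigma`; training samples `S = mu + eps ⊙ sigma`, `eps ~ N(0, I)`, and a
   linear softmax head classifies S. Loss: cross-entropy +
   `lambda · KL(N(mu, diag sigma²) ‖ N(0, I))`.

Per-sample prediction uncertainty is the normalized entropy
`H(p̄)/log 2 ∈ [0, 1]` of the mean class probabilities over K = 30
stochastic passes.

## Worked example

Simulate a 40-subject study with a doubled Gamma-band power in the "post"
class, preprocess into band segments, cross-validate subject-wise, and
inspect prediction uncertainty:

```r
library(duformer)

cfg  <- synth_config(n_subjects = 40, duration_s = 6,
                     effect_band = "Gamma", effect_ratio = 2, seed = 11)
ds   <- generate_dataset(cfg)                       # 80 recordings
sets <- preprocess_dataset(ds, bands = eeg_bands()[c(1, 7), ])
sets$Gamma
#> <segment_set> band Gamma: 400 segments of 16 channels x 2000 samples (classes: 200/200)

mcfg <- duformer_config(n_filters = 16, embed_dim = 16,
                        stride_large = 10, stride_small = 10)
hyp  <- train_hyper(max_epochs = 20, patience = 4, batch_size = 16,
                    val_strategy = "subject")

cv <- run_cv(sets$Gamma, mcfg, hyp, k = 10, seed = 5, strategy = "subject")
round(cv$mean, 4)
#>  accuracy precision    recall        f1       auc
#>    0.9650    0.9667    0.9700    0.9666    0.9972

cv0 <- run_cv(preprocess_dataset(
  generate_dataset(synth_config(n_subjects = 40, duration_s = 6,
                                effect_band = "Gamma", effect_ratio = 1,
                                seed = 11)),
  bands = eeg_bands()[7, , drop = FALSE])$Gamma,
  mcfg, hyp, k = 10, seed = 5, strategy = "subject")
round(cv0$mean[["accuracy"]], 4)   # no effect -> chance level
#> [1] 0.4775

fit <- train_model(sets$Gamma, mcfg, hyp, seed = 3)
rep <- mc_predict(fit, sets$Gamma, K = 30, seed = 9)
acceptance_rate(rep, 0.3)        # fraction of confident predictions
#> [1] 0.985
```

The effect-band accuracy (0.965) against the null-calibrated 0.4775 shows
the model reads the injected band-power effect rather than noise; on the
off-effect Delta band the same pipeline stays near chance, which
localizes the class signal in frequency.

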