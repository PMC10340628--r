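# pdvoice

Multimodal speech and language biomarkers for Parkinson's disease
screening, in R.

About 90% of people with Parkinson's disease (PD) develop hypokinetic
dysarthria — reduced loudness, monopitch, imprecise articulation — which
makes spontaneous speech a strong digital biomarker; the disease's
cognitive side also leaves weaker traces in language production.
`pdvoice` is a complete, tested pipeline for discriminating PD patients
from healthy controls (HC) from a monologue recording and its
transliteration. It is aimed at speech/clinical-ML researchers who want a
reproducible, leak-free reference implementation of the full multimodal
stack, runnable end to end on a synthetic cohort when clinical data are
unavailable.

## What is inside

**Audio front end** — peak normalization, polyphase downsampling to
8 kHz, segmentation into 500 ms chunks with 250 ms shifts, and 128-band
log-mel spectrograms (128 × 63 per chunk under the default STFT
configuration).

**Speech encoders**

* 1D-CNN + LSTM on raw waveform chunks: conv(16 ch) → maxpool(2) →
  conv(32 ch) → maxpool(2) → 2 × LSTM(64) → softmax head, with the
  convolution `out = bias + Σ_c weight_c ★ input_c` (valid
  cross-correlation) and the standard gated cell
  `c_t = f_t ∗ c_{t−1} + i_t ∗ c̃`, `h_t = o_t ∗ tanh(c_t)`.
* Residual 2D-CNN on mel spectrograms: input conv (16 ch), three stages
  of two residual blocks (`H(x) = F(x) + x`) with 16/32/64 feature maps,
  global average pooling into a 64-d chunk embedding, softmax head.
* A pluggable pretrained-embedder adapter: temporal mean of
  `frame_embeddings(waveform)` (768-d for common transformer speech
  models), shipped with a deterministic stub.

**Language encoders** — from the embedding matrix `M (n × d)` of a
transliteration: (i) four statistical functionals per dimension
(mean, population SD, skewness, raw kurtosis; a `4d` vector) with an
RBF-SVM; (ii) a multi-kernel n-gram CNN with kernels `2×d`, `3×d`, `4×d`
and per-filter max pooling (192-d language embedding by default).

**Fusion** — early (feature concatenation with per-part train-fold
standardization), joint (per-speaker diagonal-covariance GMM supervector
`[μ_1..μ_K | diagΣ_1..diagΣ_K]`, K ∈ {2,4,8}, concatenated before the
text CNN's head and trained end to end), and late (2-D
`[speech_score, language_score]` SVM with cross-fitted training scores).

**Evaluation** — speaker-independent stratified 10-fold cross-validation;
RBF-SVM grid search over C ∈ {0.001…100}, γ ∈ {0.0001…100} by inner
5-fold CV on training folds only; Adam + cross-entropy with early
stopping for the deep models; accuracy / sensitivity (PD recall) /
specificity (HC recall) / F1 reported per fold as mean ± SD; Platt-style
calibrated scores for comparable histograms. Every train-side statistic
records its provenance and the test suite asserts no test-fold speaker
ever feeds a scaler, grid search, GMM or early-stopping decision.

**Synthetic cohort** — a source–filter toy voice with class-dependent
jitter, shimmer and aspiration noise, plus topic-mixture transcripts
whose word counts are class-independent by construction. It exists to
carry a controllable, deliberately strong class effect through the real
pipeline; it is not a dysarthria simulator.

## Worked example

```r
library(pdvoice)

cohort <- gen_cohort(cohort_spec(seed = 1))   # 20 PD + 20 HC, 10 s @ 8 kHz
report <- run_experiment(cohort, "text_functionals_svm", k = 10, seed = 1)
print(report)
#> <cv_report> branch text_functionals_svm: 10-fold speaker-independent CV (seed 1)
#>   accuracy     100.0 +/-  0.0 %
#>   sensitivity  100.0 +/-  0.0 %
#>   specificity  100.0 +/-  0.0 %
#>   f1           100.0 +/-  0.0 %
```

The four numbers are fold-averaged percentages (± SD across the 10
folds): overall accuracy, PD recall, HC recall, and the PD-positive F1.
Perfect separation is expected here — the default synthetic cohort is
constructed with a strong class effect precisely so that a correct
pipeline can recover it; the interesting failure mode this guards against
is leakage or a broken encoder, not a hard classification problem. With
`cohort_spec(audio_effect = 0, text_effect = 0)` the same experiment
collapses to chance.

Other branches: `speech_resnet2d`, `speech_cnn1d_lstm`,
`speech_pretrained_svm`, `text_ngram_cnn`, `fusion_early`,
`fusion_joint`, `fusion_late`. Reports are tibble-friendly:

```r
tidy(report)     # per-fold metrics
glance(report)   # one-row summary
autoplot(report) # per-subject score histogram by class
export_report(report, "out/")  # JSON + CSV
```

A thin CLI over the same functions lives at `inst/cli/pdvoice`
(`simulate`, `featurize`, `evaluate`).

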