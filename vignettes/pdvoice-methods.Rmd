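---
title: "Methods: multimodal speech and language screening for Parkinson's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal speech and language screening for Parkinson's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hypokinetic dysarthria — the motor speech disorder of Parkinson's disease
(PD) — degrades phonation, articulation and prosody in ways that are
measurable from spontaneous speech, while the disease's cognitive,
non-motor side leaves weaker but real traces in language production.
`pdvoice` implements a complete pipeline for discriminating PD patients
from healthy controls (HC) from a monologue recording and its
transliteration: speech encoders, language encoders, three ways of fusing
the two modalities, and a strictly speaker-independent evaluation
protocol. Because clinical corpora of this kind are private, the package
ships a synthetic cohort generator that carries a controllable class
effect through the *real* feature and training code, so every stage is
testable end to end.

## Audio front end

Recordings are peak-normalized and downsampled to 8 kHz (polyphase
resampling; upsampling is refused). Each recording is segmented into
500 ms chunks with 250 ms shifts; a trailing remainder shorter than one
window is dropped so chunks stay homogeneous — at 90 s, or even the 10 s
synthetic default, the loss is negligible. Each 4000-sample chunk becomes
a 128-band log-mel spectrogram. The 128 x 63 shape is fixed by the chunk
length together with the STFT defaults:

* window = FFT length = 512 samples (64 ms), periodic Hann;
* hop = 64 samples, centered frames via reflection padding, giving
  `floor(4000/64) + 1 = 63` frames;
* 128 triangular mel filters spanning 0–4000 Hz;
* natural log with a `1e-10` energy floor.

The window/hop pair is the minimal configuration that realizes the
128 x 63 contract; it is a declared default, not a derived quantity. The
log-mel values are standardized per recording (zero mean, unit variance
over all of the recording's frames) — a per-speaker operation that cannot
leak across folds.

## Speech encoders

**1D-CNN + LSTM.** Two 1D convolutional layers (16 then 32 channels),
each followed by temporal max pooling of width 2, feed two stacked LSTM
layers with 64 cells and a fully connected 2-class softmax head. The
input is the raw 4000-sample chunk: the temporal-domain representation
is the natural counterpart to the spectrogram model. Kernel sizes and
strides of the two convolutions are open hyper-parameters; the defaults
(32/stride 4 and 16/stride 4) shorten the sequence to 60 LSTM steps so
backpropagation through time stays cheap.

**Residual 2D-CNN.** A stem convolution with 16 channels, three stages of
two residual blocks with 16/32/64 feature maps (`H(x) = F(x) + x`;
stages 2 and 3 downsample with stride-2 convolutions and 1 x 1 skip
projections), global average pooling per channel into a 64-dimensional
chunk embedding, and a 2-class head. Batch normalization follows every
convolution and ReLU is used throughout — the canonical residual-network
recipe. The stem uses a 5 x 3 kernel with stride 4 x 2 followed by 2 x 2
max pooling: with 128 x 63 inputs, reducing resolution early cuts the
training cost by roughly an order of magnitude on CPU without touching
any printed architectural quantity (channel widths, block counts, the
64-d embedding). Learned layers use cross-correlation, the framework
convention; the flipped-kernel convolution is implemented separately as
`conv2d_apply()` and the two are tied together by oracle tests.

**Pretrained adapter.** Any embedder exposing
`frame_embeddings(samples, rate) -> T x D` can stand behind this
interface; the recording-level vector is the temporal mean of the frames
(768-d for common transformer speech models). The package ships a
deterministic stub — a fixed random projection of 128-band log-mel
frames — so that the adapter path, fusion and evaluation code are fully
exercised without downloading model weights. The stub is a stand-in by
design: it inherits the spectral information of the mel front end, not
the phonetic structure a real self-supervised model would add.

Chunk scores are averaged per speaker (`speaker_score()`); the speaker is
the unit of decision everywhere.

## Language encoders

Transliterations are lowercased, stripped of punctuation and split on
whitespace. A pluggable word embedder maps the token sequence to the
embedding matrix `M` (one row per token, `d` columns). Context-independent
embedders give identical rows for repeated tokens; out-of-vocabulary
tokens map to deterministic hash-seeded vectors rather than being dropped.
Context-dependent embedders plug in through the same interface (a toy
neighbor-averaging contextual embedder is included as the reference
plugin; word vectors for subword models follow the mean-of-subwords
convention).

Two representations are built from `M`:

* **Statistical functionals** — per dimension: mean, population standard
  deviation (`ddof = 0`, stated so oracles agree), skewness and raw
  (non-excess) kurtosis, stacked as `[means | stds | skews | kurts]` of
  length `4d`, classified with an RBF-SVM. Zero-variance dimensions
  define skewness and kurtosis as 0 to keep degenerate inputs NaN-free.
  Whether the original functionals used raw or excess kurtosis, sample or
  population variance, is unstated in the source; the package picks the
  population/raw convention and documents it.
* **n-gram CNN** — 1-D convolutions over token positions with kernels
  `2 x d`, `3 x d`, `4 x d` (bi-/tri-/four-gram relations), ReLU,
  per-filter max pooling over positions, concatenation into the language
  embedding (default 64 filters per width, so 192 dimensions — the filter
  count is unstated in the source and configurable here), dropout, and a
  softmax head. Inputs shorter than the widest kernel are zero-row
  padded.

## Fusion

* **Early**: the speaker's adapter vector (temporal mean of frames)
  concatenated with the fold-trained language embedding; each part is
  z-scored with training-fold statistics before the SVM, preventing the
  scale of one modality from drowning the other.
* **Joint**: a per-speaker GMM supervector is concatenated with the
  language embedding just before the fully connected layer, and the whole
  text CNN is trained with the supervector as a fixed input — gradients
  reach the n-gram filters, which is the defining property of joint
  fusion and is asserted by a finite-difference test.
* **Late**: the 2-D vector `[speech_score, language_score]` feeds an SVM.
  Training-fold scores are obtained by 3-fold cross-fitting inside the
  training fold, so the fusion SVM is never trained on resubstitution
  scores; test scores come from models trained on the full training fold.

**GMM supervectors.** A diagonal-covariance Gaussian mixture
(K ∈ {2, 4, 8}; default 8) is fitted per speaker to the adapter's frame
embeddings by EM: seeded k-means initialization, variance floor `1e-6`,
at most 200 iterations or a log-likelihood gain below `1e-6`, with
monotonicity of the log-likelihood asserted at every fit. The supervector
stacks component means then diagonal covariances (`2Kd` values);
components are ordered by ascending first mean coordinate (ties by the
second) so the layout is stable across refits. Fitting per speaker — as
opposed to adapting a universal background model — is the simpler reading
of the protocol; UBM–MAP adaptation is a natural extension hook. Which
speech embedding feeds the supervectors is configurable; the
pretrained-adapter frames are the default.

## Evaluation protocol

Speakers are partitioned (never sampled) into 10 stratified folds; fold
sizes differ by at most one and each class is spread as evenly as
possible. Every training-side statistic is computed from training-fold
speakers only:

* feature standardization (`fit_scaler()`/`apply_scaler()`),
* SVM grid search — C ∈ {0.001, …, 100}, γ ∈ {0.0001, …, 100} (42
  pairs) — by inner 5-fold cross-validation on training rows, selecting
  by mean accuracy with ties broken toward smaller C then smaller γ (the
  protocol source does not say how grid search avoided test leakage; the
  inner loop is this package's strictly leak-free choice),
* early stopping, on a validation set carved from training speakers
  (20%, stratified),
* per-speaker GMMs (inherently leak-free).

The provenance of each statistic is recorded in the `cv_report` and
asserted in the test suite. Deep models train with Adam on cross-entropy
for up to 200 epochs with early-stopping patience 40 and dropout/L2
grids {0.2, 0.4, 0.6} and {0.0001, 0.005, 0.001} under the reference
regimen (`train_config()`); experiments on the synthetic cohort collapse
the grids to (0.2, 0.0001) and cap epochs (30 for text models, 6 for the
chunk-level speech models, batch 32, subsampling 6 evenly spaced training
chunks per speaker) — problem sizes chosen so a full 10-fold experiment
runs in minutes on one CPU while test speakers are still scored on all
their chunks. SVM decision values are standardized and mapped through a
Platt-style sigmoid fitted on training decision values, so all branches
emit comparable `[0, 1]` scores; the decision threshold is 0.5 with ties
called PD (PD is the positive class throughout: sensitivity is PD
recall, specificity HC recall).

## The synthetic cohort

The generator emulates the study conditions, not the disease. Defaults:
20 PD / 20 HC speakers, 10 s mono recordings at 8 kHz (clinical
monologues run ~90 s; chunk counts scale linearly and nothing downstream
depends on absolute duration), transliterations of 120 ± 30 words drawn
from a synthetic vocabulary.

*Audio*: a source–filter toy voice — a glottal impulse train (f0 ~
105–135 Hz with slow drift) with per-cycle f0 jitter and amplitude
shimmer plus additive aspiration noise, shaped by two formant-like
resonators (≈500 and ≈1500 Hz). HC baselines are jitter CV 0.01, shimmer
0.05, noise gain 0.02; the PD class adds +0.04/+0.20/+0.10 at
`audio_effect = 1`. These deltas are deliberately larger than clinical
effect sizes: the cohort is *constructed* to be separable so that
end-to-end tests measure whether the pipeline can recover a known signal,
not whether the toy voice mimics dysarthria. `audio_effect = 0` removes
the class difference entirely and is used as the null control (expected
chance-level accuracy).

*Text*: tokens are drawn from a mixture of two topic vocabularies plus
shared filler words; the class label shifts the topic weight by
`text_effect` (λ, default 0.6; HC draws topic A with probability
`0.5 + λ/2`, PD with `0.5 − λ/2`). The token *count* is drawn before any
label-dependent quantity, from a distribution shared by both classes, so
word counts carry no class signal — mirrored by a Mann–Whitney check in
the tests. The toy word embedder places tokens on the unit sphere
clustered around topic centroids, giving both language representations
geometric signal to find.

Passing tests on this cohort demonstrate that the implementation is
correct and leak-free and that the pipeline recovers a constructed class
effect; they say nothing about accuracy on real dysarthric speech, real
transcripts, or real pretrained embedders.

## Numerical choices and degenerate inputs

* All-zero audio: preprocessing skips normalization (no division by
  zero); all-zero mel chunks hit the log floor exactly.
* Embedding dimensions with zero variance: skewness/kurtosis 0.
* GMM variances floored at `1e-6`; k-means degenerate cases fall back to
  a deterministic spread along the first axis.
* SVM decision values are standardized before Platt calibration so
  heavily regularized grid points (margins ~1e-6) still calibrate with
  the correct orientation.
* Early stopping counts *strict* improvements; a frozen validation loss
  stops training after exactly `1 + patience` epochs.
* All randomness flows from explicit seeds (cohort, folds, inner folds,
  initialization, shuffling, dropout); repeated runs are bit-identical.

## Limitations

* The acoustic generator is a toy; no codec simulation, voice-activity
  detection or denoising is attempted, and no ASR is involved.
* The pretrained adapter stub is a fixed random projection, not a learned
  representation; real adapters plug in but are not shipped.
* Severity estimation (regression against clinical motor scores) is out
  of scope; the pipeline is a binary screen.
* Only two modalities and the three stated fusion strategies are
  supported.
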