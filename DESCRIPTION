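Package: pdvoice
Title: Multimodal Speech and Language Biomarkers for Parkinson's Disease Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reusable pipeline for discriminating Parkinson's disease (PD)
    patients from healthy controls (HC) using spontaneous speech and its
    transliterations. Implements an audio front end (peak normalization,
    polyphase resampling to 8 kHz, 500 ms chunking, 128-band log-mel
    spectrograms), three speech encoders (a 1D-CNN+LSTM on raw waveform
    chunks, a residual 2D-CNN on mel spectrograms emitting 64-dimensional
    chunk embeddings, and a pluggable pretrained-embedder adapter with
    temporal mean pooling), two language encoders over word-embedding
    matrices (four statistical functionals with an SVM, and a multi-kernel
    n-gram CNN with kernel widths 2, 3 and 4 spanning the embedding
    dimension), and early, joint and late fusion of the two modalities,
    including per-speaker GMM supervectors of stacked component means and
    diagonal covariances. Evaluation follows a speaker-independent,
    stratified 10-fold cross-validation with leak-free inner model
    selection, RBF-SVM grid search, and an Adam training regimen with
    early stopping. A synthetic cohort generator (source-filter voice
    model with class-dependent jitter, shimmer and aspiration noise;
    topic-mixture transcripts with class-independent word counts) makes
    every stage testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
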