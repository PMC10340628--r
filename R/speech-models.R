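#' Build the 1D-CNN + LSTM speech model
#'
#' Temporal-domain encoder for raw 500 ms waveform chunks: two 1D
#' convolutional layers with 16 and 32 channels, each followed by temporal
#' max pooling with kernel size 2, then two stacked LSTM layers with 64
#' cells, and a fully connected 2-class head on the last hidden state.
#' Kernel sizes and strides of the convolutions are free hyper-parameters
#' (defaults 32/4 and 16/4) chosen to keep the LSTM sequence short.
#'
#' @param cfg Optional list overriding `input_len` (4000), `k1`, `s1`,
#'   `k2`, `s2`, `lstm_cells` (64), `dropout` (0.2).
#' @return An uninitialized `nn_model` of class `cnn1d_lstm`; call
#'   [nn_init()] (done automatically by [train_deep()]) before use.
#' @export
build_cnn1d_lstm <- function(cfg = list()) {
  cfg <- utils::modifyList(list(input_len = 4000L, k1 = 32L, s1 = 4L,
                                k2 = 16L, s2 = 4L, lstm_cells = 64L,
                                dropout = 0.2), cfg)
  layers <- list(
    layer_conv1d(16L, k = cfg$k1, s = cfg$s1),
    layer_relu(),
    layer_maxpool1d(),
    layer_conv1d(32L, k = cfg$k2, s = cfg$s2),
    layer_relu(),
    layer_maxpool1d(),
    layer_lstm(cfg$lstm_cells, return_seq = TRUE),
    layer_lstm(cfg$lstm_cells, return_seq = FALSE),
    layer_dropout(cfg$dropout),
    layer_dense(2L)
  )
  structure(list(layers = layers, input_shape = c(cfg$input_len, 1L),
                 kind = "cnn1d_lstm", cfg = cfg),
            class = c("cnn1d_lstm", "seq_nn", "nn_model"))
}

#' Build the residual 2D-CNN speech encoder
#'
#' Mel-spectrogram encoder: an input convolution with 16 channels (stem,
#' stride 4 x 2 then 2 x 2 max pooling for desk-scale runtimes), three
#' stages of two residual blocks with 16, 32 and 64 feature maps (stages 2
#' and 3 downsample with stride-2 convolutions and 1 x 1 skip
#' projections), global average pooling per channel into a 64-dimensional
#' chunk embedding, and a fully connected 2-class head. Each residual
#' block computes `H(x) = F(x) + x`; zeroing the residual branch leaves
#' the identity mapping.
#'
#' @param cfg Optional list overriding `input_shape` (c(128, 63)),
#'   `stem_kh`/`stem_kw`/`stem_sh`/`stem_sw`, `widths` (c(16, 32, 64)),
#'   `dropout` (0.2).
#' @return An uninitialized `nn_model` of class `resnet2d` whose embedding
#'   (tagged at the pooling layer) has length `widths[3]`.
#' @export
build_resnet2d <- function(cfg = list()) {
  cfg <- utils::modifyList(list(input_shape = c(128L, 63L), stem_kh = 5L,
                                stem_kw = 3L, stem_sh = 4L, stem_sw = 2L,
                                widths = c(16L, 32L, 64L), dropout = 0.2), cfg)
  w <- cfg$widths
  layers <- list(
    layer_conv2d(w[1], kh = cfg$stem_kh, kw = cfg$stem_kw,
                 sh = cfg$stem_sh, sw = cfg$stem_sw),
    layer_bn(),
    layer_relu(),
    layer_maxpool2d(),
    layer_resblock(w[1], stride = 1L),
    layer_resblock(w[1], stride = 1L),
    layer_resblock(w[2], stride = 2L),
    layer_resblock(w[2], stride = 1L),
    layer_resblock(w[3], stride = 2L),
    layer_resblock(w[3], stride = 1L),
    layer_gap2d(tag = "embedding"),
    layer_dropout(cfg$dropout),
    layer_dense(2L)
  )
  structure(list(layers = layers, input_shape = c(cfg$input_shape, 1L),
                 kind = "resnet2d", cfg = cfg,
                 embedding_dim = w[3]),
            class = c("resnet2d", "seq_nn", "nn_model"))
}

#' Layer inventory of a model
#'
#' @param model An `nn_model`.
#' @return A tibble with one row per layer: `layer`, `type`, key size
#'   fields, output shape (after [nn_init()]) and parameter count.
#' @export
nn_layers <- function(model) {
  rows <- purrr::imap(model$layers, function(l, i) {
    tibble::tibble(
      layer = i,
      type = l$type,
      detail = switch(l$type,
        conv2d = sprintf("%dx%d/%dx%d -> %d ch", l$kh, l$kw, l$sh, l$sw, l$out_ch),
        conv1d = sprintf("k%d/s%d -> %d ch", l$k, l$s, l$out_ch),
        lstm = sprintf("%d cells%s", l$hidden, if (l$return_seq) " (seq)" else ""),
        resblock = sprintf("%d ch, stride %d", l$out_ch, l$stride),
        dense = sprintf("-> %d", l$out),
        dropout = sprintf("p=%.2f", l$p),
        ""),
      out_shape = if (is.null(l$out_shape)) NA_character_ else
        paste(l$out_shape, collapse = "x"),
      n_params = length(unlist(l$params, use.names = FALSE))
    )
  })
  dplyr::bind_rows(rows)
}

#' Total parameter count of a model
#'
#' @param model An initialized `nn_model`.
#' @return Integer number of trainable parameters.
#' @export
nn_n_params <- function(model) length(.flat_params(model))

#' Class probabilities for a batch
#'
#' Runs the model in evaluation mode and applies softmax.
#'
#' @param model Initialized `nn_model`.
#' @param x Input batch array (last dimension indexes observations).
#' @return Matrix `2 x N` of class probabilities (row 2 = PD).
#' @export
nn_predict_probs <- function(model, x) {
  r <- nn_forward(model, x, training = FALSE)
  z <- sweep(r$out, 2, apply(r$out, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

#' Chunk embeddings from an encoder
#'
#' @param model Initialized `nn_model` with a layer tagged `"embedding"`.
#' @param x Input batch array.
#' @return Matrix `embedding_dim x N`.
#' @export
nn_embed <- function(model, x) {
  r <- nn_forward(model, x, training = FALSE)
  if (is.null(r$embedding)) stop("model has no embedding-tagged layer")
  r$embedding
}

# ---------------------------------------------------------------------------
# Pretrained-embedder adapter
# ---------------------------------------------------------------------------

#' Deterministic stub pretrained speech embedder
#'
#' Stands behind the pluggable pretrained-embedder interface: any object
#' with fields `name`, `dim` and a `frame_embeddings(samples, rate)`
#' function returning a `T x dim` matrix can be used. The stub projects
#' 128-band log-mel frames through a fixed random matrix seeded once at
#' construction, so repeated calls are bit-identical. Loading a real
#' self-supervised speech model is an optional extension with the same
#' contract.
#'
#' @param dim Embedding dimension (default 768, the dimension of common
#'   transformer speech encoders).
#' @param seed Seed for the fixed projection matrix.
#' @param frame_hop STFT hop in samples for the internal mel front end.
#' @return An object of class `pretrained_embedder`.
#' @export
stub_embedder <- function(dim = 768L, seed = 17L, frame_hop = 256L) {
  n_mels <- 128L
  proj <- local({
    set.seed(seed)
    matrix(stats::rnorm(n_mels * dim, 0, 1 / sqrt(n_mels)), n_mels, dim)
  })
  cfg <- mel_config(n_mels = n_mels, hop = frame_hop)
  structure(list(
    name = sprintf("stub-%d", dim),
    dim = dim,
    frame_embeddings = function(samples, rate) {
      S <- mel_spectrogram(samples, rate, cfg)
      crossprod(unclass(S), proj) # T x dim
    }
  ), class = "pretrained_embedder")
}

#' Recording-level embedding via temporal mean pooling
#'
#' Extracts the embedder's frame embeddings and averages them over time,
#' returning one fixed-dimension vector per recording.
#'
#' @param recording An [audio_recording()].
#' @param embedder A `pretrained_embedder` (e.g. [stub_embedder()]).
#' @return Numeric vector of length `embedder$dim`.
#' @export
pretrained_embed <- function(recording, embedder) {
  stopifnot(inherits(recording, "audio_recording"),
            inherits(embedder, "pretrained_embedder"))
  Fr <- embedder$frame_embeddings(recording$samples, recording$rate)
  if (is.null(dim(Fr)) || nrow(Fr) == 0) stop("embedder returned no frames")
  colMeans(Fr)
}

#' Frame embeddings of a recording
#'
#' @inheritParams pretrained_embed
#' @return A `T x dim` matrix of per-frame embeddings.
#' @export
frame_embeddings <- function(recording, embedder) {
  stopifnot(inherits(recording, "audio_recording"),
            inherits(embedder, "pretrained_embedder"))
  Fr <- embedder$frame_embeddings(recording$samples, recording$rate)
  if (is.null(dim(Fr)) || nrow(Fr) == 0) stop("embedder returned no frames")
  Fr
}

#' Speaker-level score from chunk scores
#'
#' The speech score per subject is the arithmetic mean of the per-chunk
#' decision scores.
#'
#' @param chunk_scores Numeric vector of class-1 probabilities in `[0, 1]`.
#' @return A single score in `[0, 1]`.
#' @export
speaker_score <- function(chunk_scores) {
  if (length(chunk_scores) == 0) stop("no chunk scores for speaker")
  if (any(chunk_scores < 0 | chunk_scores > 1)) {
    stop("chunk scores must lie in [0, 1]")
  }
  mean(chunk_scores)
}
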