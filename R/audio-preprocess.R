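#' Construct an audio recording
#'
#' The basic speech observation: a sampled waveform tied to a speaker
#' identity and a class label.
#'
#' @param samples Numeric amplitude vector (dimensionless).
#' @param rate Sampling frequency in Hz (> 0).
#' @param speaker_id Opaque speaker identifier.
#' @param label `"PD"`, `"HC"`, or `NA` when unknown.
#' @return An object of class `audio_recording` with fields `samples`,
#'   `rate`, `speaker_id`, `label` and `duration_s`.
#' @export
audio_recording <- function(samples, rate, speaker_id = "unknown", label = NA_character_) {
  stopifnot(is.numeric(samples), is.numeric(rate), length(rate) == 1, rate > 0)
  if (!is.na(label)) label <- match.arg(label, c("PD", "HC"))
  structure(
    list(samples = as.numeric(samples), rate = rate,
         speaker_id = as.character(speaker_id), label = label,
         duration_s = length(samples) / rate),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %s [%s]: %.2f s @ %d Hz (%d samples, peak %.3f)\n",
              x$speaker_id, ifelse(is.na(x$label), "?", x$label),
              x$duration_s, as.integer(x$rate), length(x$samples),
              max(abs(x$samples))))
  invisible(x)
}

#' Preprocess a recording: resample and peak-normalize
#'
#' Downsamples the waveform to `target_rate` with a polyphase anti-aliased
#' resampler and rescales so the peak absolute amplitude is 1 (an all-zero
#' waveform is left untouched). Speaker identity and label are preserved.
#' Upsampling is refused: the pipeline operates at or below the source rate.
#'
#' @param recording An [audio_recording()].
#' @param target_rate Target sampling frequency in Hz (default 8000).
#' @return A new `audio_recording` at `target_rate` with peak amplitude 1.
#' @export
preprocess_recording <- function(recording, target_rate = 8000) {
  stopifnot(inherits(recording, "audio_recording"))
  if (length(recording$samples) == 0) stop("empty recording")
  if (target_rate > recording$rate) stop("upsampling not supported")
  x <- recording$samples
  if (target_rate < recording$rate) {
    frac <- .reduce_fraction(target_rate, recording$rate)
    x <- signal::resample(x, frac[1], frac[2])
    n_out <- floor(length(recording$samples) * target_rate / recording$rate)
    x <- .fix_length(x, n_out)
  }
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  audio_recording(x, target_rate, recording$speaker_id, recording$label)
}

.reduce_fraction <- function(p, q) {
  g <- .gcd(p, q)
  c(p / g, q / g)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

.fix_length <- function(x, n) {
  if (length(x) >= n) x[seq_len(n)] else c(x, numeric(n - length(x)))
}

#' Segment a recording into overlapping chunks
#'
#' Slides a `win_ms` window with `shift_ms` hops; the trailing remainder
#' shorter than one window is dropped so all chunks are homogeneous. With
#' the defaults at 8 kHz each chunk has 4000 samples and adjacent chunks
#' share 250 ms of identical samples.
#'
#' @param recording An [audio_recording()].
#' @param win_ms Window length in milliseconds (default 500).
#' @param shift_ms Hop between successive windows in milliseconds (default 250).
#' @return A tibble with one row per chunk: `speaker_id`, `label`, `chunk`
#'   (index), `start_s` (offset in the parent recording) and `samples`
#'   (list-column of numeric vectors).
#' @export
segment_chunks <- function(recording, win_ms = 500, shift_ms = 250) {
  stopifnot(inherits(recording, "audio_recording"))
  W <- round(recording$rate * win_ms / 1000)
  S <- round(recording$rate * shift_ms / 1000)
  L <- length(recording$samples)
  if (L < W) stop("recording shorter than one chunk (", L, " < ", W, " samples)")
  n_chunks <- (L - W) %/% S + 1L
  starts <- (seq_len(n_chunks) - 1L) * S
  tibble::tibble(
    speaker_id = recording$speaker_id,
    label = recording$label,
    chunk = seq_len(n_chunks),
    start_s = starts / recording$rate,
    samples = lapply(starts, function(s0) recording$samples[(s0 + 1):(s0 + W)])
  )
}

#' Mel-spectrogram configuration
#'
#' Defaults realize a 128 x 63 representation for a 500 ms chunk at 8 kHz:
#' a 512-sample (64 ms) Hann window hopped by 64 samples over a
#' reflection-padded ("centered") signal gives `floor(4000/64) + 1 = 63`
#' frames, and 128 triangular mel filters span 0 to Nyquist.
#'
#' @param n_mels Number of mel filters (default 128).
#' @param n_fft FFT length and window length in samples (default 512).
#' @param hop Hop between frames in samples (default 64).
#' @param fmin,fmax Filterbank frequency range in Hz; `fmax = NULL` means
#'   the Nyquist frequency.
#' @param log_floor Linear-energy floor applied before the log (default 1e-10).
#' @param log Apply the natural log after the filterbank (default `TRUE`).
#' @return A list of class `mel_config`.
#' @export
mel_config <- function(n_mels = 128, n_fft = 512, hop = 64,
                       fmin = 0, fmax = NULL, log_floor = 1e-10, log = TRUE) {
  structure(list(n_mels = n_mels, n_fft = n_fft, hop = hop, fmin = fmin,
                 fmax = fmax, log_floor = log_floor, log = log),
            class = "mel_config")
}

#' Triangular mel filterbank
#'
#' Filters are triangles with edges equally spaced on the mel scale
#' (`mel = 2595 log10(1 + f/700)`), evaluated at the FFT bin frequencies.
#'
#' @param n_mels Number of filters.
#' @param n_fft FFT length.
#' @param rate Sampling frequency in Hz.
#' @param fmin,fmax Frequency range in Hz (`fmax = NULL` means Nyquist).
#' @return A `n_mels x (n_fft/2 + 1)` weight matrix.
#' @export
mel_filterbank <- function(n_mels, n_fft, rate, fmin = 0, fmax = NULL) {
  if (is.null(fmax)) fmax <- rate / 2
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2))
  bin_freqs <- (0:(n_fft / 2)) * rate / n_fft
  fb <- matrix(0, n_mels, n_fft / 2 + 1)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (bin_freqs - lo) / (ce - lo)
    down <- (hi - bin_freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Mel-band center frequencies in Hz
#'
#' @inheritParams mel_filterbank
#' @return Numeric vector of length `n_mels`.
#' @export
mel_center_freqs <- function(n_mels, rate, fmin = 0, fmax = NULL) {
  if (is.null(fmax)) fmax <- rate / 2
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2))
  edges[2:(n_mels + 1)]
}

#' Log-mel spectrogram of a chunk
#'
#' STFT (centered via reflection padding, Hann window) followed by the
#' triangular mel filterbank and, by default, a floored natural log. The
#' result is deterministic for fixed input and configuration. For a
#' 4000-sample chunk at 8 kHz under the default [mel_config()] the output
#' is a 128 x 63 matrix.
#'
#' @param samples Numeric chunk waveform, or a single row of the tibble
#'   returned by [segment_chunks()] via its `samples` entry.
#' @param rate Sampling frequency in Hz.
#' @param cfg A [mel_config()].
#' @param expected_samples If non-`NULL`, the chunk length is validated
#'   against this value and a mismatch is an error.
#' @return A matrix of class `mel_spectrogram` (`n_mels` rows, one column
#'   per frame) with attributes `rate`, `hop` and `frame_times` (seconds).
#' @export
mel_spectrogram <- function(samples, rate = 8000, cfg = mel_config(),
                            expected_samples = NULL) {
  if (is.list(samples)) samples <- samples[[1]]
  stopifnot(is.numeric(samples))
  if (!is.null(expected_samples) && length(samples) != expected_samples) {
    stop("chunk length mismatch: expected ", expected_samples,
         " samples, got ", length(samples))
  }
  P <- .stft_power(samples, cfg$n_fft, cfg$hop)
  fb <- mel_filterbank(cfg$n_mels, cfg$n_fft, rate, cfg$fmin, cfg$fmax)
  S <- fb %*% P
  if (cfg$log) S <- log(pmax(S, cfg$log_floor))
  frame_times <- (seq_len(ncol(S)) - 1L) * cfg$hop / rate
  structure(S, class = c("mel_spectrogram", class(S)),
            rate = rate, hop = cfg$hop, frame_times = frame_times)
}

# Power spectrogram: centered frames (reflection padding), periodic Hann.
.stft_power <- function(x, n_fft, hop) {
  half <- n_fft %/% 2
  xp <- c(rev(x[2:(half + 1)]), x, rev(x[(length(x) - half):(length(x) - 1)]))
  n_frames <- floor(length(x) / hop) + 1L
  win <- 0.5 * (1 - cos(2 * pi * (0:(n_fft - 1)) / n_fft))
  idx <- outer(seq_len(n_fft), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(xp[idx], n_fft, n_frames) * win
  spec <- stats::mvfft(frames)[seq_len(half + 1), , drop = FALSE]
  Mod(spec)^2
}

#' Standardize a recording's log-mel chunks
#'
#' Zero mean, unit variance computed over all frames of all chunks of one
#' recording. Statistics come only from that recording, so the transform
#' cannot leak information across speakers or folds.
#'
#' @param mels List of `mel_spectrogram` matrices from one recording.
#' @return The list with each matrix standardized by the recording-level
#'   mean and standard deviation.
#' @export
standardize_mels <- function(mels) {
  stopifnot(length(mels) > 0)
  all_vals <- unlist(lapply(mels, as.numeric))
  mu <- mean(all_vals)
  sdv <- stats::sd(all_vals)
  if (sdv == 0) sdv <- 1
  lapply(mels, function(m) {
    out <- (unclass(m) - mu) / sdv
    attributes(out) <- attributes(m)
    out
  })
}
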