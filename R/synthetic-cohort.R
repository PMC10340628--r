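#' Specification of a synthetic PD/HC cohort
#'
#' Defines the study conditions for the generator: cohort sizes, recording
#' duration and rate, the acoustic class effect (cycle-to-cycle f0 jitter,
#' amplitude shimmer and aspiration-noise gain, all elevated in the PD
#' class), and the language class effect (a topic-mixture shift of weight
#' `text_effect` between two synthetic vocabularies). Transliteration
#' lengths are drawn from a distribution shared by both classes, so word
#' counts carry no class signal.
#'
#' @param n_pd,n_hc Speakers per class (default 20 each).
#' @param duration_s Recording duration in seconds (default 10; clinical
#'   monologues run about 90 s, and nothing downstream depends on the
#'   absolute duration).
#' @param rate Sampling frequency in Hz (default 8000).
#' @param audio_effect Either a scalar scaling the default PD deltas
#'   (jitter +0.04, shimmer +0.20, noise gain +0.10 at 1; 0 = no class
#'   difference) or a list with explicit `jitter`, `shimmer`, `noise`
#'   deltas.
#' @param text_effect Topic-mixture shift lambda in `[0, 1]`; 0 makes the
#'   token distributions identical across classes.
#' @param words_mean,words_sd Transliteration length distribution (shared
#'   across classes).
#' @param seed Cohort seed; every speaker derives a deterministic
#'   sub-seed from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_pd = 20L, n_hc = 20L, duration_s = 10, rate = 8000L,
                        audio_effect = 1, text_effect = 0.6,
                        words_mean = 120, words_sd = 30, seed = 1234L) {
  stopifnot(n_pd >= 1, n_hc >= 1, duration_s >= 1,
            text_effect >= 0, text_effect <= 1)
  if (is.numeric(audio_effect) && length(audio_effect) == 1) {
    audio_effect <- list(jitter = 0.04 * audio_effect,
                         shimmer = 0.20 * audio_effect,
                         noise = 0.10 * audio_effect)
  }
  structure(list(n_pd = as.integer(n_pd), n_hc = as.integer(n_hc),
                 duration_s = duration_s, rate = as.integer(rate),
                 audio_effect = audio_effect, text_effect = text_effect,
                 words_mean = words_mean, words_sd = words_sd,
                 seed = as.integer(seed),
                 base = list(jitter = 0.01, shimmer = 0.05, noise = 0.02),
                 f0_range = c(105, 135)),
            class = "cohort_spec")
}

.speaker_seed <- function(spec, i) {
  as.integer((as.numeric(spec$seed) * 10007 + i * 97) %% 2147483647)
}

# Second-order resonator (formant) filter.
.resonate <- function(x, f, bw, rate) {
  r <- exp(-pi * bw / rate)
  a1 <- 2 * r * cos(2 * pi * f / rate)
  a2 <- -r^2
  as.numeric(stats::filter(x, c(a1, a2), method = "recursive"))
}

#' Generate one synthetic recording
#'
#' Source-filter toy voice: a glottal impulse train with per-cycle f0
#' jitter and amplitude shimmer, plus additive aspiration noise, driven
#' through two resonant (formant-like) filters. PD-labelled speakers
#' receive larger jitter, shimmer and noise per the cohort specification's
#' class deltas.
#' The model is not a dysarthria simulator; it exists to carry a
#' controllable class effect through the real feature pipeline.
#'
#' @param label `"PD"` or `"HC"`.
#' @param spec A [cohort_spec()].
#' @param speaker_seed Integer seed; the waveform is bit-identical across
#'   calls with the same seed.
#' @param speaker_id Identifier attached to the recording.
#' @return An [audio_recording()] with peak amplitude 0.9.
#' @export
gen_recording <- function(label, spec, speaker_seed, speaker_id = "synthetic") {
  label <- match.arg(label, c("PD", "HC"))
  eff <- spec$audio_effect
  base <- spec$base
  jitter <- base$jitter + if (label == "PD") eff$jitter else 0
  shimmer <- base$shimmer + if (label == "PD") eff$shimmer else 0
  noise_gain <- base$noise + if (label == "PD") eff$noise else 0
  samples <- .with_seed(speaker_seed, {
    L <- round(spec$duration_s * spec$rate)
    f0 <- stats::runif(1, spec$f0_range[1], spec$f0_range[2])
    f1 <- stats::rnorm(1, 500, 30)
    f2 <- stats::rnorm(1, 1500, 60)
    drift_phase <- stats::runif(1, 0, 2 * pi)
    src <- numeric(L)
    t <- 1
    while (t <= L) {
      amp <- max(0.1, 1 + shimmer * stats::rnorm(1))
      src[t] <- amp
      f0_t <- f0 * (1 + 0.02 * sin(2 * pi * 0.3 * t / spec$rate + drift_phase))
      period <- (spec$rate / f0_t) * (1 + jitter * stats::rnorm(1))
      t <- t + max(8, round(period))
    }
    src <- src + noise_gain * stats::rnorm(L)
    y <- .resonate(.resonate(src, f1, 80, spec$rate), f2, 120, spec$rate)
    y / max(abs(y)) * 0.9
  })
  audio_recording(samples, spec$rate, speaker_id = speaker_id, label = label)
}

#' Synthetic vocabulary of the cohort generator
#'
#' Two topic vocabularies plus shared filler words. The class effect
#' shifts the topic mixture; filler usage is class-independent.
#'
#' @return A tibble with columns `token` and `topic`.
#' @export
cohort_vocab <- function() {
  tibble::tibble(
    token = c(sprintf("ta%02d", 1:40), sprintf("tb%02d", 1:40),
              sprintf("fw%02d", 1:20)),
    topic = rep(c("topic_a", "topic_b", "filler"), c(40, 40, 20))
  )
}

#' Generate one synthetic transliteration
#'
#' The token count is drawn first, from the class-independent
#' `(words_mean, words_sd)` normal (truncated at 5), so word-count
#' distributions are identical across classes. Tokens are then drawn from
#' a mixture of two topic vocabularies (plus shared filler words at rate
#' 0.2); the class label shifts the topic weight by `text_effect`: HC
#' draws topic A with probability `0.5 + lambda/2`, PD with
#' `0.5 - lambda/2`.
#'
#' @inheritParams gen_recording
#' @return A [transliteration()].
#' @export
gen_transcript <- function(label, spec, speaker_seed, speaker_id = "synthetic") {
  label <- match.arg(label, c("PD", "HC"))
  vocab <- cohort_vocab()
  a_tokens <- vocab$token[vocab$topic == "topic_a"]
  b_tokens <- vocab$token[vocab$topic == "topic_b"]
  f_tokens <- vocab$token[vocab$topic == "filler"]
  lambda <- spec$text_effect
  p_a <- if (label == "HC") 0.5 + lambda / 2 else 0.5 - lambda / 2
  tokens <- .with_seed(speaker_seed + 1L, {
    n <- max(5L, round(stats::rnorm(1, spec$words_mean, spec$words_sd)))
    kind <- stats::runif(n)
    topic_a <- stats::runif(n) < p_a
    vapply(seq_len(n), function(i) {
      if (kind[i] < 0.2) sample(f_tokens, 1)
      else if (topic_a[i]) sample(a_tokens, 1)
      else sample(b_tokens, 1)
    }, character(1))
  })
  transliteration(tokens, speaker_id = speaker_id, label = label)
}

#' Generate a full synthetic cohort
#'
#' One recording and one transliteration per speaker, with aligned labels
#' and deterministic per-speaker seeds derived from the cohort seed.
#' Optionally writes WAV files, transcript text files and a CSV manifest.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir If non-`NULL`, write `wav/`, `txt/` and `manifest.csv`
#'   under this directory.
#' @return A `cohort`: list with `recordings` (named list of
#'   [audio_recording()]), `transcripts` (named list of
#'   [transliteration()]), `manifest` (tibble with `speaker_id`, `label`,
#'   and file paths when written), and `spec`.
#' @export
gen_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- c(sprintf("PD_%03d", seq_len(spec$n_pd)),
           sprintf("HC_%03d", seq_len(spec$n_hc)))
  labels <- rep(c("PD", "HC"), c(spec$n_pd, spec$n_hc))
  recordings <- vector("list", length(ids))
  transcripts <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ss <- .speaker_seed(spec, i)
    recordings[[i]] <- gen_recording(labels[i], spec, ss, speaker_id = ids[i])
    transcripts[[i]] <- gen_transcript(labels[i], spec, ss, speaker_id = ids[i])
  }
  names(recordings) <- ids
  names(transcripts) <- ids
  manifest <- tibble::tibble(speaker_id = ids, label = labels,
                             wav_path = NA_character_,
                             transcript_path = NA_character_)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "wav"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "txt"), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(ids)) {
      wp <- file.path(out_dir, "wav", paste0(ids[i], ".wav"))
      tp <- file.path(out_dir, "txt", paste0(ids[i], ".txt"))
      write_wav(recordings[[i]]$samples, spec$rate, wp)
      writeLines(paste(transcripts[[i]]$tokens, collapse = " "), tp)
      manifest$wav_path[i] <- wp
      manifest$transcript_path[i] <- tp
    }
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  structure(list(recordings = recordings, transcripts = transcripts,
                 manifest = manifest, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d PD + %d HC speakers, %.1f s @ %d Hz\n",
              x$spec$n_pd, x$spec$n_hc, x$spec$duration_s, x$spec$rate))
  invisible(x)
}

#' Deterministic clustered toy word embedder
#'
#' Assigns each token a unit-norm vector generated around a shared topic
#' centroid: tokens from the same topic cluster together, so both the
#' statistical functionals and the n-gram CNN have geometric signal to
#' find. Vectors are seeded by the embedder seed and a per-token hash, so
#' repeated calls return identical vectors.
#'
#' @param vocab A tibble with columns `token` and `topic` (see
#'   [cohort_vocab()]), or a character vector (one shared topic).
#' @param d Embedding dimension (default 8, `>= 2`).
#' @param seed Embedder seed.
#' @return A `word_embedder`.
#' @export
toy_embedder <- function(vocab = cohort_vocab(), d = 8L, seed = 42L) {
  stopifnot(d >= 2)
  if (is.character(vocab)) {
    vocab <- tibble::tibble(token = vocab, topic = "general")
  }
  if (nrow(vocab) == 0) stop("vocabulary must be non-empty")
  topics <- unique(vocab$topic)
  centroids <- lapply(seq_along(topics), function(i) {
    v <- .with_seed(seed + i, stats::rnorm(d))
    v / sqrt(sum(v^2))
  })
  names(centroids) <- topics
  table <- lapply(seq_len(nrow(vocab)), function(i) {
    noise <- .with_seed((.string_hash(vocab$token[i]) + seed) %% 2147483647,
                        stats::rnorm(d))
    noise <- noise / sqrt(sum(noise^2))
    v <- centroids[[vocab$topic[i]]] + 0.6 * noise
    v / sqrt(sum(v^2))
  })
  names(table) <- vocab$token
  table_embedder(table, name = sprintf("toy-d%d", d))
}
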