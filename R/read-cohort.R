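#' Load a cohort from a manifest on disk
#'
#' Reads WAV recordings and plain-text transliterations listed in a
#' manifest (see [read_manifest()]) into the in-memory `cohort` structure
#' used by [run_experiment()].
#'
#' @param manifest_path Path to a CSV or JSON-lines manifest with columns
#'   `speaker_id`, `wav_path`, `transcript_path`, `label`.
#' @param base_dir Directory against which relative paths are resolved
#'   (default: the manifest's directory).
#' @return A `cohort` list with `recordings`, `transcripts`, `manifest`.
#' @export
read_cohort <- function(manifest_path, base_dir = dirname(manifest_path)) {
  man <- read_manifest(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base_dir, p))
  recordings <- list()
  transcripts <- list()
  for (i in seq_len(nrow(man))) {
    wav <- read_wav(resolve(man$wav_path[i]))
    recordings[[man$speaker_id[i]]] <- audio_recording(
      wav$samples, wav$rate, man$speaker_id[i], man$label[i])
    text <- paste(readLines(resolve(man$transcript_path[i]), warn = FALSE),
                  collapse = " ")
    transcripts[[man$speaker_id[i]]] <- transliteration(
      tokenize_text(text), man$speaker_id[i], man$label[i])
  }
  structure(list(recordings = recordings, transcripts = transcripts,
                 manifest = man, spec = NULL),
            class = "cohort")
}
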