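#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader supporting uncompressed PCM 16-bit and IEEE
#' float 32-bit mono files, the two formats the pipeline writes and
#' consumes. Multi-channel files are mixed down by averaging channels.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector in `[-1, 1]`) and `rate`
#'   (sampling frequency in Hz).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little") # overall size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        n_channels = readBin(raw_fmt[3:4], "integer", 1, size = 2,
                             endian = "little", signed = FALSE),
        rate = readBin(raw_fmt[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, size = 2,
                       endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        n <- sz %/% 2L
        x <- readBin(con, "integer", n, size = 2, endian = "little")
        samples <- x / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        n <- sz %/% 4L
        samples <- readBin(con, "double", n, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$audio_format,
             ", ", fmt$bits, " bits); only PCM16 and float32 are readable")
      }
      if (sz %% 2L == 1L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (fmt$n_channels > 1L) {
    samples <- colMeans(matrix(samples, nrow = fmt$n_channels))
  }
  list(samples = samples, rate = fmt$rate)
}

#' Write a mono WAV file
#'
#' Writes samples as mono PCM 16-bit (default) or IEEE float 32-bit.
#' PCM samples are clipped to `[-1, 1]` and quantized with rounding.
#'
#' @param samples Numeric vector of amplitudes, nominally in `[-1, 1]`.
#' @param rate Sampling frequency in Hz.
#' @param path Output path.
#' @param bits Either `16` (PCM) or `32` (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, bits = 16) {
  stopifnot(is.numeric(samples), length(samples) > 0, rate > 0)
  n <- length(samples)
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  audio_format <- if (bits == 16) 1L else 3L
  writeBin(audio_format, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    q <- as.integer(pmax(pmin(round(samples * 32768), 32767), -32768))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest lists one speaker per row with columns `speaker_id`,
#' `wav_path`, `transcript_path` and `label` (`"PD"` or `"HC"`). Both CSV
#' and JSON-lines files are accepted.
#'
#' @param path Path to a `.csv` or `.jsonl`/`.json` manifest.
#' @return A tibble with the four manifest columns.
#' @export
read_manifest <- function(path) {
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    rows <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
    out <- dplyr::bind_rows(rows)
  } else {
    out <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("speaker_id", "wav_path", "transcript_path", "label")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  }
  tibble::as_tibble(out[required])
}

#' Write a dataset manifest as CSV
#'
#' @param manifest A data frame with columns `speaker_id`, `wav_path`,
#'   `transcript_path`, `label`.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}
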