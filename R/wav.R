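# Minimal RIFF/PCM WAV support: mono or multi-channel 16-bit PCM, any rate.
# Only the subset of the format the toolkit emits and consumes is handled;
# compressed or float WAVs are rejected with a clear error.

#' Read a PCM WAV file
#'
#' @param path WAV file path.
#' @return List with `samples` (numeric in `[-1, 1]`, mono: channels are
#'   averaged), `sample_rate` (Hz), `n_channels`, `bits`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("WAV file '%s' does not exist", path),
          class = "somnaudit_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort(sprintf("'%s' is not a RIFF/WAVE file", path),
          class = "somnaudit_io_error")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little"),
        n_channels = readBin(con, "integer", 1, size = 2, endian = "little"),
        sample_rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align = readBin(con, "integer", 1, size = 2, endian = "little"),
        bits = readBin(con, "integer", 1, size = 2, endian = "little")
      )
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(sprintf("'%s': missing fmt or data chunk", path),
          class = "somnaudit_io_error")
  }
  if (fmt$audio_format != 1 || fmt$bits != 16) {
    abort(sprintf("'%s': only 16-bit PCM is supported", path),
          class = "somnaudit_io_error")
  }
  vals <- readBin(data_raw, "integer", n = length(data_raw) / 2,
                  size = 2, signed = TRUE, endian = "little")
  x <- pmax(-1, vals / 32767)   # symmetric with the writer's scaling
  if (fmt$n_channels > 1) {
    m <- matrix(x, nrow = fmt$n_channels)
    x <- colMeans(m)
  }
  list(samples = x, sample_rate = fmt$sample_rate,
       n_channels = fmt$n_channels, bits = fmt$bits)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector in `[-1, 1]`; values outside are clipped.
#' @param path output path (directories created as needed).
#' @param sample_rate sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")               # PCM
  writeBin(1L, con, size = 2, endian = "little")               # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Duration of a WAV file from its header
#'
#' Reads only the header, so it is cheap even for long recordings.
#'
#' @param path WAV file path.
#' @return Duration in seconds.
#' @export
wav_duration <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("WAV file '%s' does not exist", path),
          class = "somnaudit_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort(sprintf("'%s' is not a RIFF/WAVE file", path),
          class = "somnaudit_io_error")
  }
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) {
      abort(sprintf("'%s': missing fmt or data chunk", path),
            class = "somnaudit_io_error")
    }
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little"),
        n_channels = readBin(con, "integer", 1, size = 2, endian = "little"),
        sample_rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align = readBin(con, "integer", 1, size = 2, endian = "little"),
        bits = readBin(con, "integer", 1, size = 2, endian = "little")
      )
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (id == "data") {
      if (is.null(fmt)) {
        abort(sprintf("'%s': data chunk before fmt chunk", path),
              class = "somnaudit_io_error")
      }
      frames <- size / (fmt$n_channels * fmt$bits / 8)
      return(frames / fmt$sample_rate)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
}
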