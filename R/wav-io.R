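# Minimal RIFF WAV codec. Write: 16-bit PCM mono/stereo. Read: PCM 16/24-bit
# and IEEE float32, first channel only. Little-endian throughout.

#' Write a waveform to a RIFF WAV file
#'
#' Samples are expected in [-1, 1]; values outside are clipped. Output is
#' 16-bit PCM.
#'
#' @param samples Numeric vector (mono) of samples in [-1, 1].
#' @param sample_rate Sampling rate in Hz.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0L,
            all(is.finite(samples)), sample_rate > 0)
  pcm <- as.integer(pmax(-32768, pmin(32767, round(samples * 32768))))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")       # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a RIFF WAV file
#'
#' Supports PCM 16- and 24-bit and IEEE float32. Multi-channel files are
#' reduced to their first channel.
#'
#' @param path Path to a WAV file.
#' @return A list with \code{samples} (numeric in [-1, 1]) and
#'   \code{sample_rate} (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) {
    stop("not a RIFF file: ", path, call. = FALSE)
  }
  readBin(con, integer(), size = 4, endian = "little")  # riff size
  if (!identical(readChar(con, 4), "WAVE")) {
    stop("not a WAVE file: ", path, call. = FALSE)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, raw(), n = size)
      fmt <- list(
        format = sum(as.integer(raw[1:2]) * c(1, 256)),
        channels = sum(as.integer(raw[3:4]) * c(1, 256)),
        sample_rate = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (id == "data") {
      data_raw <- readBin(con, raw(), n = size)
    } else {
      readBin(con, raw(), n = size + (size %% 2L))  # skip (chunks are padded)
      next
    }
    if (size %% 2L == 1L) readBin(con, raw(), n = 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("missing fmt or data chunk in ", path, call. = FALSE)
  }
  samples <- switch(
    as.character(fmt$bits),
    "16" = {
      if (fmt$format != 1L) stop("unsupported WAV format code ", fmt$format)
      readBin(data_raw, integer(), n = length(data_raw) %/% 2L,
              size = 2, signed = TRUE, endian = "little") / 32768
    },
    "24" = {
      if (fmt$format != 1L) stop("unsupported WAV format code ", fmt$format)
      n <- length(data_raw) %/% 3L
      b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      ifelse(v >= 8388608, v - 16777216, v) / 8388608
    },
    "32" = {
      if (fmt$format != 3L) stop("only float32 supported at 32 bits")
      readBin(data_raw, numeric(), n = length(data_raw) %/% 4L,
              size = 4, endian = "little")
    },
    stop("unsupported bit depth: ", fmt$bits)
  )
  if (fmt$channels > 1L) {
    samples <- samples[seq(1L, length(samples), by = fmt$channels)]
  }
  list(samples = samples, sample_rate = fmt$sample_rate)
}
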