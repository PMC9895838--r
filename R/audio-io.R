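#' @include utils.R
NULL

#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader for PCM (8/16/24/32-bit integer) and IEEE-float
#' (32/64-bit) encodings. Samples are returned scaled to `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @return List with `samples` (numeric vector for mono, channels-by-samples
#'   matrix otherwise), `rate` (Hz), `channels`, and `bits`.
#' @seealso [writeWave()]
#' @export
readWave <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (riff != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (wave != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1, 2, signed = FALSE,
                         endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, signed = FALSE,
                       endian = "little"))
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      raw <- readBin(con, "raw", sz)
      break
    } else {
      readBin(con, "raw", sz + sz %% 2)     # skip unknown chunk (word-aligned)
    }
  }
  bytes <- fmt$bits / 8
  n <- length(raw) %/% bytes
  x <- if (fmt$format == 3L) {
    readBin(raw, "double", n, size = bytes, endian = "little")
  } else if (fmt$format == 1L) {
    if (fmt$bits == 8) {
      (readBin(raw, "integer", n, size = 1, signed = FALSE) - 128) / 128
    } else if (fmt$bits == 24) {
      m <- matrix(as.integer(raw), nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v[v >= 8388608] <- v[v >= 8388608] - 16777216
      v / 8388608
    } else {
      readBin(raw, "integer", n, size = bytes, endian = "little") /
        2^(fmt$bits - 1)
    }
  } else stop("unsupported WAV encoding (format tag ", fmt$format, ")")
  if (fmt$channels > 1L)
    x <- matrix(x, nrow = fmt$channels)
  list(samples = x, rate = fmt$rate, channels = fmt$channels, bits = fmt$bits)
}

#' Write a WAV file
#'
#' Writes mono or multichannel audio as 16-bit PCM or 32-bit IEEE float.
#'
#' @param samples Numeric vector (mono) or channels-by-samples matrix, values
#'   in `[-1, 1]`.
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (float).
#' @return The path, invisibly.
#' @export
writeWave <- function(samples, rate, path, bits = 16) {
  if (!bits %in% c(16, 32)) stop("bits must be 16 or 32")
  if (is.matrix(samples)) {
    channels <- nrow(samples)
    inter <- as.numeric(samples)          # column-major = interleaved frames
  } else {
    channels <- 1L
    inter <- as.numeric(samples)
  }
  bytes <- bits / 8
  dataSize <- length(inter) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bits == 32) 3 else 1), con, size = 2,
           endian = "little")
  writeBin(as.integer(channels), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * channels * bytes), con, size = 4,
           endian = "little")
  writeBin(as.integer(channels * bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  if (bits == 32) {
    writeBin(inter, con, size = 4, endian = "little")
  } else {
    v <- as.integer(round(pmax(pmin(inter, 1), -1) * 32767))
    writeBin(v, con, size = 2, endian = "little")
  }
  invisible(path)
}
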