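## Minimal RIFF/WAVE reader and writer (PCM 16-bit and IEEE float32).
## The installed stack has no WAV package, and the format is simple enough
## that a faithful little-endian implementation is preferable to a stub.

#' Write a WAV file
#'
#' Writes mono or stereo audio as RIFF/WAVE, either 16-bit PCM (samples
#' clipped to [-1, 1] and scaled by 32767) or 32-bit IEEE float.
#'
#' @param x numeric vector (mono) or matrix with one column per channel,
#'   sample values nominally in [-1, 1].
#' @param path output file.
#' @param sampleRate sampling rate in Hz.
#' @param format "pcm16" or "float32".
#' @return the path, invisibly.
#' @export
writeWav <- function(x, path, sampleRate, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  nch <- ncol(x); n <- nrow(x)
  if (n == 0) stop("no samples to write")
  bytesPerSample <- if (format == "pcm16") 2L else 4L
  audioFormat <- if (format == "pcm16") 1L else 3L
  blockAlign <- nch * bytesPerSample
  dataBytes <- n * blockAlign
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, 4, eos = NULL)
  writeBin(as.integer(36 + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, 4, eos = NULL)
  writeChar("fmt ", con, 4, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audioFormat, con, size = 2, endian = "little")
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate * blockAlign), con, size = 4, endian = "little")
  writeBin(blockAlign, con, size = 2, endian = "little")
  writeBin(8L * bytesPerSample, con, size = 2, endian = "little")
  writeChar("data", con, 4, eos = NULL)
  writeBin(as.integer(dataBytes), con, size = 4, endian = "little")
  interleaved <- as.numeric(t(x))   # frame-major
  if (format == "pcm16") {
    v <- as.integer(round(pmax(-1, pmin(1, interleaved)) * 32767))
    writeBin(v, con, size = 2, endian = "little")
  } else {
    writeBin(interleaved, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Reads PCM 16-bit or IEEE float32 RIFF/WAVE files written by
#' [writeWav()] or other standard tools.
#'
#' @param path WAV file.
#' @return list with `samples` (matrix, one column per channel, PCM scaled
#'   to [-1, 1]), `sampleRate`, and `format`.
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, raw(), n = sz)
      fmt <- list(
        audioFormat = readBin(raw[1:2], integer(), size = 2, endian = "little"),
        nch = readBin(raw[3:4], integer(), size = 2, endian = "little"),
        rate = readBin(raw[5:8], integer(), size = 4, endian = "little"),
        bits = readBin(raw[15:16], integer(), size = 2, endian = "little"))
    } else if (id == "data") {
      dat <- readBin(con, raw(), n = sz)
    } else {
      readBin(con, raw(), n = sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop("missing fmt or data chunk")
  if (fmt$audioFormat == 1 && fmt$bits == 16) {
    v <- readBin(dat, integer(), n = length(dat) / 2, size = 2,
                 signed = TRUE, endian = "little") / 32767
    format <- "pcm16"
  } else if (fmt$audioFormat == 3 && fmt$bits == 32) {
    v <- readBin(dat, numeric(), n = length(dat) / 4, size = 4,
                 endian = "little")
    format <- "float32"
  } else stop("unsupported WAV encoding (format ", fmt$audioFormat,
              ", ", fmt$bits, " bits)")
  list(samples = matrix(v, ncol = fmt$nch, byrow = TRUE),
       sampleRate = fmt$rate, format = format)
}
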