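## Minimal European Data Format (EDF) writer and reader. No EDF package
## exists in the installed R stack; the format (fixed-width ASCII header +
## little-endian int16 data records) is implemented directly. Only what the
## pipeline needs: equal-length records, physical units in microvolts.

edfField <- function(x, width) {
  s <- format(x, scientific = FALSE, trim = TRUE)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)   # left-justified, space padded
}

#' Write single- or multi-channel EEG to EDF
#'
#' Writes samples (microvolts) as EDF with one-second data records.
#' Samples are quantized to 16 bits over `physRange`; the quantization
#' step for the default +/-200 uV range is ~0.006 uV. The final record is
#' zero-padded.
#'
#' @param x numeric vector (one channel) or matrix with one column per
#'   channel, in microvolts.
#' @param path output file.
#' @param sampleRate samples per second per channel (integer).
#' @param labels channel label(s), e.g. "EEG Fpz-A1".
#' @param physRange physical calibration range in uV, length 2.
#' @return the path, invisibly.
#' @export
writeEdf <- function(x, path, sampleRate = 512,
                     labels = "EEG Fpz-A1", physRange = c(-200, 200)) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  ns <- ncol(x)
  if (length(labels) == 1) labels <- rep(labels, ns)
  stopifnot(length(labels) == ns, physRange[1] < physRange[2])
  spr <- as.integer(sampleRate)           # one-second records
  nrec <- as.integer(ceiling(nrow(x) / spr))
  xp <- rbind(x, matrix(0, nrec * spr - nrow(x), ns))
  digMin <- -32768L; digMax <- 32767L
  scale <- (digMax - digMin) / (physRange[2] - physRange[1])
  dig <- round((pmax(pmin(xp, physRange[2]), physRange[1]) - physRange[1]) *
               scale) + digMin
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edfField(s, w), con, w, eos = NULL)
  wr("0", 8)                                   # version
  wr("X X X X", 80)                            # patient id (anonymous)
  wr("Startdate X X X X", 80)                  # recording id
  wr("01.01.20", 8); wr("00.00.00", 8)         # date, time
  wr(256 * (1 + ns), 8)                        # header bytes
  wr("", 44)                                   # reserved
  wr(nrec, 8)
  wr("1", 8)                                   # record duration (s)
  wr(ns, 4)
  for (lab in labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)            # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(physRange[1], 8)
  for (i in seq_len(ns)) wr(physRange[2], 8)
  for (i in seq_len(ns)) wr(digMin, 8)
  for (i in seq_len(ns)) wr(digMax, 8)
  for (i in seq_len(ns)) wr("", 80)            # prefiltering
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)            # reserved
  for (r in seq_len(nrec)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns))
      writeBin(as.integer(dig[rows, ch]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads an EDF file and returns the signal in physical units. For the
#' single-channel pipeline a multi-channel file is an error unless
#' `channel` selects one.
#'
#' @param path EDF file.
#' @param channel channel index to extract when the file has several; NULL
#'   requires a single-channel file.
#' @return list with `samples` (numeric, physical units), `sampleRate`,
#'   `label`, `physDim`, `nRecords`, `nChannels`.
#' @export
readEdf <- function(path, channel = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  headerBytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.null(channel)) {
    if (ns != 1)
      stop("EDF file has ", ns, " channels; this pipeline requires a ",
           "single-channel recording (or pass `channel` to select one)")
    channel <- 1L
  }
  if (channel > ns) stop("channel index out of range")
  labs    <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  dims    <- vapply(seq_len(ns), function(i) rd(8), character(1))
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  digMin  <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  digMax  <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr     <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  seek(con, headerBytes)
  perRec <- sum(spr)
  raw <- readBin(con, integer(), n = nrec * perRec, size = 2,
                 signed = TRUE, endian = "little")
  offs <- c(0, cumsum(spr))
  idx <- unlist(lapply(seq_len(nrec) - 1L, function(r)
    r * perRec + offs[channel] + seq_len(spr[channel])))
  dig <- raw[idx]
  g <- (physMax[channel] - physMin[channel]) / (digMax[channel] - digMin[channel])
  list(samples = (dig - digMin[channel]) * g + physMin[channel],
       sampleRate = spr[channel] / recDur,
       label = labs[channel], physDim = dims[channel],
       nRecords = nrec, nChannels = ns)
}
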