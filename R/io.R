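#' Write a recording to CSV or EDF
#'
#' CSV keeps full double precision (columns `sample_index`, 0-based, and
#' `value_uv`); EDF quantizes to 16 bits over the calibration range (see
#' [writeEdf()]). The format follows the file extension.
#'
#' @param recording [EEGRecording].
#' @param path output path ending in `.csv` or `.edf`.
#' @return the path, invisibly.
#' @export
writeRecording <- function(recording, path) {
  stopifnot(is(recording, "EEGRecording"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- data.frame(sample_index = seq_along(recording@samples) - 1L,
                     value_uv = recording@samples)
    utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
  } else if (ext == "edf") {
    writeEdf(recording@samples, path, sampleRate = recording@sampleRate)
  } else stop("unsupported recording format: .", ext)
  invisible(path)
}

#' Read a recording from CSV or EDF and attach its schedule
#'
#' EDF supplies the sampling rate from its header; when it disagrees with
#' `sampleRate`, reading is refused (no silent resampling) unless
#' `allowRateMismatch = TRUE`, which adopts the header rate with a
#' warning. Multi-channel EDF is an error. CSV must have columns
#' `sample_index` and `value_uv` and carries no rate, so `sampleRate` is
#' taken as given.
#'
#' @param path `.csv` or `.edf` file.
#' @param schedule [StimulusSchedule] for the recording (e.g. from
#'   [readScheduleCsv()]).
#' @param sampleRate expected sampling rate in Hz, default 512.
#' @param preRoll seconds of signal before the first onset, default 0.5.
#' @param allowRateMismatch accept an EDF header rate different from
#'   `sampleRate`.
#' @return [EEGRecording].
#' @export
readRecording <- function(path, schedule, sampleRate = 512, preRoll = 0.5,
                          allowRateMismatch = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path)
    need <- c("sample_index", "value_uv")
    missing <- setdiff(need, names(df))
    if (length(missing))
      stop("recording CSV is missing column(s): ",
           paste(missing, collapse = ", "),
           " (expected sample_index, value_uv)")
    x <- as.numeric(df$value_uv)
    rate <- sampleRate
  } else if (ext == "edf") {
    e <- readEdf(path)
    x <- e$samples
    rate <- e$sampleRate
    if (rate != sampleRate) {
      if (!allowRateMismatch)
        stop("EDF header rate ", rate, " Hz differs from expected ",
             sampleRate, " Hz; refusing to resample ",
             "(pass allowRateMismatch = TRUE to adopt the header rate)")
      warning("adopting EDF header rate ", rate, " Hz")
    }
  } else stop("unsupported recording format: .", ext)
  new("EEGRecording", samples = x, sampleRate = rate, schedule = schedule,
      preRoll = preRoll)
}

#' Write / read per-epoch feature rows as CSV
#'
#' One row per epoch: `trial_id`, `label`, `is_target`, then the 16
#' feature values `f1` .. `f16`.
#'
#' @param x [ERPDataset] or a single [EpochSet].
#' @param path CSV path.
#' @return `writeFeaturesCsv` the path invisibly; `readFeaturesCsv` a
#'   data.frame.
#' @export
writeFeaturesCsv <- function(x, path) {
  tl <- if (is(x, "ERPDataset")) x@trials else list(x)
  rows <- lapply(tl, function(es) {
    f <- featureMatrix(es)
    colnames(f) <- paste0("f", seq_len(ncol(f)))
    cbind(data.frame(trial_id = es@trialId, label = es@label,
                     is_target = es@isTarget), as.data.frame(f))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeaturesCsv
#' @export
readFeaturesCsv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trial_id", "label", "is_target", "f1")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("features CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  df
}
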