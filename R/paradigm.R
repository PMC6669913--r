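#' Spatialization parameters
#'
#' Parameters of the interaural time/level difference (ITD/ILD)
#' spatialization. `headRadius` and `soundSpeed` enter the ITD formula
#' `(r/c) * (theta + sin(theta))` with `theta` the azimuth in radians;
#' defaults are taken verbatim from the paradigm definition (r = 0.9,
#' c = 340.0). `ildGainDb` maps each azimuth to left/right channel gains in
#' dB; lateral positions attenuate the far ear. The ILD values are a
#' plausible default (the paradigm's own were tuned by ear) and fully
#' configurable.
#'
#' @param headRadius head radius parameter r (default 0.9).
#' @param soundSpeed speed of sound c in m/s (default 340.0).
#' @param ildGainDb data.frame with columns `azimuth`, `left_db`,
#'   `right_db` covering azimuths 0, 45, 90, 135, 180.
#' @return list with the three components, class-free.
#' @export
spatializationParams <- function(headRadius = 0.9, soundSpeed = 340.0,
                                 ildGainDb = NULL) {
  stopifnot(headRadius > 0, soundSpeed > 0)
  if (is.null(ildGainDb))
    ildGainDb <- data.frame(
      azimuth  = c(0, 45, 90, 135, 180),
      left_db  = c(0, -3, -6, -9, -20),
      right_db = c(-20, -9, -6, -3, 0))
  stopifnot(all(c("azimuth", "left_db", "right_db") %in% names(ildGainDb)))
  list(headRadius = headRadius, soundSpeed = soundSpeed,
       ildGainDb = ildGainDb)
}

#' Interaural time difference for a source azimuth
#'
#' ITD in seconds for a sound source at `azimuthDeg` degrees (0 = left ear
#' axis, 180 = right): `(r/c) * (theta + sin(theta))` with theta in
#' radians. Strictly increasing in azimuth on [0, 180].
#'
#' @param azimuthDeg azimuth in degrees, in [0, 180].
#' @param params [spatializationParams()] list.
#' @return ITD in seconds (>= 0).
#' @examples
#' computeITD(45)  # ~0.00395 s
#' @export
computeITD <- function(azimuthDeg, params = spatializationParams()) {
  if (any(azimuthDeg < 0 | azimuthDeg > 180))
    stop("azimuthDeg must lie in [0, 180]")
  theta <- azimuthDeg * pi / 180
  (params$headRadius / params$soundSpeed) * (theta + sin(theta))
}

#' Spatialize a mono stimulus into stereo via ITD/ILD
#'
#' Renders a mono sound at one of the five paradigm azimuths. Azimuths 0,
#' 90 and 180 degrees use level differences only; 45 and 135 degrees
#' additionally delay the far ear by `round(ITD * sampleRate)` samples
#' (right ear for 45, left for 135). The output gains both channels by the
#' azimuth's ILD entry. The returned matrix has `length(mono) + delay`
#' rows; the operation is linear in the input amplitude.
#'
#' @param mono numeric vector of mono samples.
#' @param sampleRate sampling rate in Hz.
#' @param azimuthDeg one of 0, 45, 90, 135, 180.
#' @param params [spatializationParams()].
#' @return numeric matrix with columns `left`, `right`.
#' @seealso [normalizeStimuli()] for equalizing peak levels across sounds.
#' @export
spatializeSound <- function(mono, sampleRate, azimuthDeg,
                            params = spatializationParams()) {
  if (length(mono) == 0) stop("empty mono input")
  stopifnot(sampleRate > 0)
  tab <- params$ildGainDb
  row <- match(azimuthDeg, tab$azimuth)
  if (is.na(row)) stop("azimuthDeg must be one of ", paste(tab$azimuth, collapse = ", "))
  gl <- 10^(tab$left_db[row] / 20)
  gr <- 10^(tab$right_db[row] / 20)
  delay <- 0L
  if (azimuthDeg %in% c(45, 135))
    delay <- as.integer(round(computeITD(azimuthDeg, params) * sampleRate))
  pad <- numeric(delay)
  if (azimuthDeg == 45) {        # source center-left: right ear is far
    left  <- c(mono * gl, pad)
    right <- c(pad, mono * gr)
  } else if (azimuthDeg == 135) { # source center-right: left ear is far
    left  <- c(pad, mono * gl)
    right <- c(mono * gr, pad)
  } else {
    left  <- mono * gl
    right <- mono * gr
  }
  cbind(left = left, right = right)
}

#' Equalize peak amplitude across spatialized stimuli
#'
#' Rescales each stereo stimulus so that all share the same peak absolute
#' amplitude (`peak`), the loudness normalization applied to the five
#' stimuli so no sound stands out by volume alone.
#'
#' @param stimuli list of stereo matrices (from [spatializeSound()]).
#' @param peak target peak absolute amplitude (default 0.9).
#' @return list of rescaled matrices.
#' @export
normalizeStimuli <- function(stimuli, peak = 0.9) {
  stopifnot(is.list(stimuli), peak > 0)
  lapply(stimuli, function(s) {
    m <- max(abs(s))
    if (m == 0) stop("cannot normalize an all-zero stimulus")
    s * (peak / m)
  })
}

#' Build a randomized oddball trial schedule
#'
#' One trial = `nSequences` sequences; each sequence is an independent
#' uniform random permutation of the five sound labels, presented at a
#' fixed stimulus-onset asynchrony. With defaults (30 sequences, SOA
#' 0.3 s) a trial has 150 events, 30 of them targets, spanning 45 s.
#' Reproducible for a fixed `seed`.
#'
#' @param targetLabel integer 1..5 (or a name from [soundLabels()]).
#' @param nSequences number of sequences (>= 1), default 30.
#' @param soa stimulus-onset asynchrony in seconds, default 0.3.
#' @param seed optional integer seed; when NULL the current RNG stream is
#'   used.
#' @return [StimulusSchedule].
#' @export
buildTrialSchedule <- function(targetLabel, nSequences = 30L, soa = 0.3,
                               seed = NULL) {
  if (is.character(targetLabel))
    targetLabel <- soundLabels()[[targetLabel]]
  targetLabel <- as.integer(targetLabel)
  stopifnot(targetLabel %in% 1:5, nSequences >= 1, soa > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  nSequences <- as.integer(nSequences)
  labels <- as.integer(unlist(lapply(seq_len(nSequences),
                                     function(i) sample(5L))))
  onsets <- (seq_along(labels) - 1L) * soa
  ev <- data.frame(onset_s = onsets, label = labels,
                   is_target = labels == targetLabel)
  new("StimulusSchedule", events = ev, soa = soa, nSequences = nSequences,
      targetLabel = targetLabel)
}

#' Total span of a schedule in seconds
#'
#' `nEvents * soa`: each event occupies one SOA slot, so a default trial
#' spans 45 s — the selection time T of the information-transfer-rate
#' formula.
#'
#' @param schedule [StimulusSchedule].
#' @export
scheduleSpan <- function(schedule) {
  stopifnot(is(schedule, "StimulusSchedule"))
  nrow(schedule@events) * schedule@soa
}

#' Write / read a schedule as CSV
#'
#' Columns: `onset_s` (stimulus-onset time, seconds), `onset_sample`
#' (0-based sample index at `sampleRate`), `label`, `is_target`.
#'
#' @param schedule [StimulusSchedule].
#' @param path CSV file path.
#' @param sampleRate rate used to derive `onset_sample` (default 512).
#' @return `writeScheduleCsv` the path invisibly; `readScheduleCsv` a
#'   [StimulusSchedule].
#' @export
writeScheduleCsv <- function(schedule, path, sampleRate = 512) {
  stopifnot(is(schedule, "StimulusSchedule"))
  ev <- schedule@events
  out <- data.frame(onset_s = ev$onset_s,
                    onset_sample = as.integer(round(ev$onset_s * sampleRate)),
                    label = ev$label,
                    is_target = ev$is_target)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScheduleCsv
#' @export
readScheduleCsv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("onset_s", "label", "is_target")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("schedule CSV is missing column(s): ", paste(missing, collapse = ", "),
         " (expected onset_s, onset_sample, label, is_target)")
  labels <- as.integer(df$label)
  tgt <- unique(labels[as.logical(df$is_target)])
  if (length(tgt) != 1)
    stop("schedule CSV must flag exactly one label as target")
  soa <- if (nrow(df) > 1) df$onset_s[2] - df$onset_s[1] else 0.3
  new("StimulusSchedule",
      events = data.frame(onset_s = df$onset_s, label = labels,
                          is_target = as.logical(df$is_target)),
      soa = soa, nSequences = as.integer(nrow(df) / 5L),
      targetLabel = tgt)
}
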