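#' StimulusSchedule: timeline of one oddball trial
#'
#' Ordered stimulus events of a single trial: `nSequences` sequences, each a
#' random permutation of the five sound labels, presented with a fixed
#' stimulus-onset asynchrony (`soa`, 300 ms = 150 ms sound + 150 ms silent
#' gap). Exactly one label is the attended target; its events carry
#' `is_target = TRUE`. Onsets are in seconds from the first stimulus onset.
#'
#' @slot events data.frame with columns `onset_s`, `label`, `is_target`,
#'   sorted by onset.
#' @slot soa numeric, stimulus-onset asynchrony in seconds.
#' @slot nSequences integer, number of sequences (30 by default upstream).
#' @slot targetLabel integer in 1..5.
#' @seealso [buildTrialSchedule()]
#' @export
setClass("StimulusSchedule",
  representation(events = "data.frame", soa = "numeric",
                 nSequences = "integer", targetLabel = "integer"))

setValidity("StimulusSchedule", function(object) {
  ev <- object@events
  msgs <- character(0)
  need <- c("onset_s", "label", "is_target")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns", paste(need, collapse = ", ")))
  if (length(object@soa) != 1 || object@soa <= 0)
    msgs <- c(msgs, "soa must be a single positive number")
  if (!(object@targetLabel %in% 1:5))
    msgs <- c(msgs, "targetLabel must be in 1..5")
  if (is.unsorted(ev$onset_s))
    msgs <- c(msgs, "events must be sorted by onset")
  if (nrow(ev) != 5L * object@nSequences)
    msgs <- c(msgs, "expected 5 events per sequence")
  else {
    seqidx <- rep(seq_len(object@nSequences), each = 5L)
    perm <- vapply(split(ev$label, seqidx),
                   function(l) identical(sort(as.integer(l)), 1:5), logical(1))
    if (!all(perm))
      msgs <- c(msgs, "each sequence of 5 events must be a permutation of labels 1..5")
  }
  if (!identical(as.logical(ev$is_target), ev$label == object@targetLabel))
    msgs <- c(msgs, "is_target must hold exactly for events with the target label")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' EEGRecording: continuous single-channel EEG plus its schedule
#'
#' Continuous single-channel EEG in microvolts at a fixed sampling rate,
#' together with the [StimulusSchedule] that generated it. `preRoll` seconds
#' of signal precede the first stimulus onset so that pre-stimulus baseline
#' windows exist; at least one second of signal follows the last onset so
#' the final epoch fits.
#'
#' @slot samples numeric vector, microvolts.
#' @slot sampleRate numeric, Hz (512 at defaults).
#' @slot schedule [StimulusSchedule].
#' @slot preRoll numeric, seconds before the first onset (>= 0.1).
#' @export
setClass("EEGRecording",
  representation(samples = "numeric", sampleRate = "numeric",
                 schedule = "StimulusSchedule", preRoll = "numeric"))

setValidity("EEGRecording", function(object) {
  msgs <- character(0)
  if (length(object@sampleRate) != 1 || object@sampleRate <= 0)
    msgs <- c(msgs, "sampleRate must be positive")
  if (object@preRoll < 0.1)
    msgs <- c(msgs, "preRoll must be >= 0.1 s (baseline window)")
  span <- nrow(object@schedule@events) * object@schedule@soa
  need <- ceiling((object@preRoll + span + 1) * object@sampleRate)
  if (length(object@samples) < need)
    msgs <- c(msgs, sprintf("recording too short: %d samples, need >= %d",
                            length(object@samples), need))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' EpochSet: baseline-corrected epochs of one trial
#'
#' Fixed-length (one second) stimulus-locked epochs extracted from a
#' filtered recording, baseline-corrected by the mean of the 100 ms
#' pre-stimulus window, together with their 16-dimensional downsampled
#' feature vectors, per-epoch sound labels and target flags.
#'
#' @slot epochs numeric matrix, epochs in rows, time points in columns
#'   (512 columns at defaults).
#' @slot features numeric matrix, epochs in rows, 16 block-mean features.
#' @slot label integer vector of sound labels per epoch.
#' @slot isTarget logical vector per epoch.
#' @slot sampleRate numeric, Hz.
#' @slot trialId integer, identifier of the trial within a dataset.
#' @slot targetLabel integer, the attended sound of the trial.
#' @slot baseline numeric vector of the subtracted baseline means.
#' @seealso [extractEpochs()], [grandAverage()]
#' @export
setClass("EpochSet",
  representation(epochs = "matrix", features = "matrix", label = "integer",
                 isTarget = "logical", sampleRate = "numeric",
                 trialId = "integer", targetLabel = "integer",
                 baseline = "numeric"))

setValidity("EpochSet", function(object) {
  n <- nrow(object@epochs)
  msgs <- character(0)
  if (length(object@label) != n || length(object@isTarget) != n)
    msgs <- c(msgs, "label/isTarget length must equal number of epochs")
  if (nrow(object@features) != n)
    msgs <- c(msgs, "features must have one row per epoch")
  if (length(object@baseline) != n)
    msgs <- c(msgs, "baseline must have one value per epoch")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' ERPTemplate: subject-level ERP morphology
#'
#' Two-bump parametric ERP shape used by the simulator: a negative (N200)
#' Gaussian bump constrained to 200-350 ms and a positive (P300-family)
#' Gaussian bump constrained to 350-1000 ms post-onset. Amplitudes are in
#' microvolts, latencies and widths in seconds.
#'
#' @slot negLatency,negAmp,negWidth negative bump center (s), amplitude
#'   (uV, < 0) and Gaussian sd (s).
#' @slot posLatency,posAmp,posWidth positive bump parameters (amplitude > 0).
#' @seealso [erpTemplate()], [templateWaveform()]
#' @export
setClass("ERPTemplate",
  representation(negLatency = "numeric", negAmp = "numeric",
                 negWidth = "numeric", posLatency = "numeric",
                 posAmp = "numeric", posWidth = "numeric"))

setValidity("ERPTemplate", function(object) {
  msgs <- character(0)
  if (object@negLatency < 0.200 || object@negLatency > 0.350)
    msgs <- c(msgs, "negLatency must lie in [0.200, 0.350] s")
  if (object@posLatency < 0.350 || object@posLatency > 1.000)
    msgs <- c(msgs, "posLatency must lie in [0.350, 1.000] s")
  if (!(object@negAmp <= 0))
    msgs <- c(msgs, "negAmp must be <= 0")
  if (!(object@posAmp >= 0))
    msgs <- c(msgs, "posAmp must be >= 0")
  if (object@negWidth <= 0 || object@posWidth <= 0)
    msgs <- c(msgs, "widths must be positive")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' NoiseModel: background EEG noise
#'
#' Additive background noise: a mixture of white noise and 1/f^alpha shaped
#' ("pink") noise, scaled to a total standard deviation `sd` in microvolts.
#' `whiteFraction` is the fraction of total variance carried by the white
#' component.
#'
#' @slot sd numeric, total noise sd in microvolts (>= 0).
#' @slot alpha numeric, spectral exponent of the shaped component (>= 0).
#' @slot whiteFraction numeric in [0, 1].
#' @seealso [noiseModel()]
#' @export
setClass("NoiseModel",
  representation(sd = "numeric", alpha = "numeric", whiteFraction = "numeric"))

setValidity("NoiseModel", function(object) {
  msgs <- character(0)
  if (object@sd < 0) msgs <- c(msgs, "sd must be >= 0")
  if (object@alpha < 0) msgs <- c(msgs, "alpha must be >= 0")
  if (object@whiteFraction < 0 || object@whiteFraction > 1)
    msgs <- c(msgs, "whiteFraction must be in [0, 1]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SWLDAModel: fitted stepwise linear discriminant
#'
#' Result of stepwise feature selection and least-squares fitting: the
#' ordered set of retained feature indices, one weight per retained
#' feature, and the intercept. Scores are `intercept + x[selected] %*%
#' weights`; larger scores are more target-like (targets coded +1,
#' non-targets -1 during fitting).
#'
#' @slot selected integer vector of selected feature column indices.
#' @slot weights numeric vector, one per selected feature.
#' @slot intercept numeric scalar.
#' @slot config list: `pEnter`, `pRemove`, `maxFeatures`, `maxIterations`.
#' @slot trainingMeta list: epoch counts per class and total.
#' @seealso [swldaFit()], [swldaScore()]
#' @export
setClass("SWLDAModel",
  representation(selected = "integer", weights = "numeric",
                 intercept = "numeric", config = "list",
                 trainingMeta = "list"))

setValidity("SWLDAModel", function(object) {
  msgs <- character(0)
  if (length(object@weights) != length(object@selected))
    msgs <- c(msgs, "one weight per selected feature required")
  if (!all(is.finite(object@weights)) || !is.finite(object@intercept))
    msgs <- c(msgs, "weights and intercept must be finite")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' ERPDataset: one simulated or recorded subject
#'
#' The complete offline dataset of one subject: a list of per-trial
#' [EpochSet] objects (15 trials = 3 runs x 5 trials at defaults, each sound
#' targeted once per run), plus the generating template when simulated.
#'
#' @slot trials list of [EpochSet].
#' @slot subjectSeed integer seed that generated the subject (NA if loaded).
#' @slot template [ERPTemplate] used by the generator.
#' @seealso [simulateSubject()], [lotocv()]
#' @export
setClass("ERPDataset",
  representation(trials = "list", subjectSeed = "integer",
                 template = "ERPTemplate"))

setValidity("ERPDataset", function(object) {
  ok <- vapply(object@trials, function(t) is(t, "EpochSet"), logical(1))
  if (!all(ok)) "trials must all be EpochSet objects" else TRUE
})

## ---- accessors ----

#' @rdname accessors
#' @export
setMethod("samples", "EEGRecording", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("sampleRate", "EEGRecording", function(x) x@sampleRate)

#' @rdname accessors
#' @export
setMethod("sampleRate", "EpochSet", function(x) x@sampleRate)

#' @rdname accessors
#' @export
setMethod("scheduleEvents", "StimulusSchedule", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("scheduleEvents", "EEGRecording", function(x) x@schedule@events)

#' @rdname accessors
#' @export
setMethod("targetLabel", "StimulusSchedule", function(x) x@targetLabel)

#' @rdname accessors
#' @export
setMethod("targetLabel", "EpochSet", function(x) x@targetLabel)

#' @rdname accessors
#' @export
setMethod("epochMatrix", "EpochSet", function(x) x@epochs)

#' @rdname accessors
#' @export
setMethod("featureMatrix", "EpochSet", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("epochLabels", "EpochSet", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("epochTargets", "EpochSet", function(x) x@isTarget)

#' @rdname accessors
#' @export
setMethod("selectedFeatures", "SWLDAModel", function(x) x@selected)

#' @rdname accessors
#' @export
setMethod("trials", "ERPDataset", function(x) x@trials)

#' @rdname accessors
#' @export
modelWeights <- function(x) {
  stopifnot(is(x, "SWLDAModel"))
  x@weights
}

#' @rdname accessors
#' @export
modelIntercept <- function(x) {
  stopifnot(is(x, "SWLDAModel"))
  x@intercept
}

## ---- show methods ----

setMethod("show", "StimulusSchedule", function(object) {
  cat(sprintf(
    "StimulusSchedule: %d events (%d sequences x 5 sounds), SOA %.3f s\n",
    nrow(object@events), object@nSequences, object@soa))
  cat(sprintf("  target: %s (label %d), span %.1f s\n",
              names(soundLabels())[object@targetLabel], object@targetLabel,
              nrow(object@events) * object@soa))
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d samples @ %g Hz (%.1f s), pre-roll %.2f s\n",
              length(object@samples), object@sampleRate,
              length(object@samples) / object@sampleRate, object@preRoll))
  cat(sprintf("  range [%.2f, %.2f] uV; %d scheduled events\n",
              min(object@samples), max(object@samples),
              nrow(object@schedule@events)))
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d epochs x %d samples @ %g Hz (%d targets)\n",
              nrow(object@epochs), ncol(object@epochs), object@sampleRate,
              sum(object@isTarget)))
  if (!is.na(object@targetLabel))
    cat(sprintf("  trial %d, target label %d; %d features/epoch\n",
                object@trialId, object@targetLabel, ncol(object@features)))
})

setMethod("show", "ERPTemplate", function(object) {
  cat(sprintf(
    "ERPTemplate: neg %.2f uV @ %d ms (w %d ms), pos %.2f uV @ %d ms (w %d ms)\n",
    object@negAmp, round(object@negLatency * 1000),
    round(object@negWidth * 1000), object@posAmp,
    round(object@posLatency * 1000), round(object@posWidth * 1000)))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: sd %.2f uV, 1/f^%.1f, white fraction %.2f\n",
              object@sd, object@alpha, object@whiteFraction))
})

setMethod("show", "SWLDAModel", function(object) {
  cat(sprintf("SWLDAModel: %d feature(s) selected of %s\n",
              length(object@selected),
              if (is.null(object@trainingMeta$nFeatures)) "?"
              else object@trainingMeta$nFeatures))
  if (length(object@selected))
    cat("  indices:", paste(object@selected, collapse = ", "), "\n")
  cat(sprintf("  intercept %.4g; trained on %s epochs (%s targets)\n",
              object@intercept,
              if (is.null(object@trainingMeta$n)) "?" else object@trainingMeta$n,
              if (is.null(object@trainingMeta$nTarget)) "?"
              else object@trainingMeta$nTarget))
})

setMethod("show", "ERPDataset", function(object) {
  nt <- length(object@trials)
  cat(sprintf("ERPDataset: %d trials", nt))
  if (nt) {
    tgts <- vapply(object@trials, targetLabel, integer(1))
    cat(sprintf(", targets [%s]", paste(tgts, collapse = " ")))
  }
  cat(sprintf(", subject seed %s\n",
              ifelse(is.na(object@subjectSeed), "NA", object@subjectSeed)))
})
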