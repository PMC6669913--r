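#' Power-line notch filter
#'
#' Second-order IIR notch (zeros on the unit circle at f0, poles at radius
#' set by the quality factor), applied zero-phase by default. Attenuation
#' at f0 exceeds 20 dB while the passband outside f0 +/- 5 Hz is left
#' essentially untouched.
#'
#' @param x numeric signal.
#' @param rate sampling rate in Hz; must exceed 2 * f0.
#' @param f0 notch frequency, default 50 Hz.
#' @param Q quality factor (f0 / bandwidth), default 30.
#' @param zeroPhase apply forward-backward (default TRUE).
#' @return filtered signal.
#' @export
notchFilter <- function(x, rate, f0 = 50, Q = 30, zeroPhase = TRUE) {
  if (rate <= 2 * f0)
    stop("sampling rate must exceed twice the notch frequency")
  theta <- 2 * pi * f0 / rate
  r <- 1 - (theta / Q) / 2
  b <- c(1, -2 * cos(theta), 1)
  a <- c(1, -2 * r * cos(theta), r^2)
  b <- b * (sum(a) / sum(b))       # unit gain at DC
  if (zeroPhase) signal::filtfilt(b, a, x) else signal::filter(b, a, x)
}

#' Band-pass filter for ERP epoch extraction
#'
#' Fourth-order Butterworth band-pass with 0.5 and 10 Hz cutoffs, realized
#' as cascaded order-`order` high-pass and low-pass sections (numerically
#' robust at the very small normalized low edge), applied zero-phase by
#' default so ERP latencies are preserved. Each pass is -3 dB at the
#' cutoffs.
#'
#' @param x numeric signal.
#' @param rate sampling rate in Hz.
#' @param low,high cutoff frequencies in Hz, 0 < low < high < rate/2.
#' @param order Butterworth order per section, default 4.
#' @param zeroPhase forward-backward application (default TRUE).
#' @return filtered signal.
#' @export
bandpassFilter <- function(x, rate, low = 0.5, high = 10, order = 4,
                           zeroPhase = TRUE) {
  if (!(low > 0 && low < high && high < rate / 2))
    stop("need 0 < low < high < rate/2")
  hp <- signal::butter(order, low / (rate / 2), type = "high")
  lp <- signal::butter(order, high / (rate / 2), type = "low")
  if (zeroPhase) {
    x <- signal::filtfilt(hp, x)
    signal::filtfilt(lp, x)
  } else {
    x <- signal::filter(hp, x)
    as.numeric(signal::filter(lp, x))
  }
}

#' Artifact screen bounds
#'
#' Raw-amplitude bounds used to reject trials: +40.0 uV upper, -25.0 uV
#' lower.
#'
#' @param upper upper bound in uV.
#' @param lower lower bound in uV.
#' @return list with `upper`, `lower`.
#' @export
artifactScreen <- function(upper = 40.0, lower = -25.0) {
  stopifnot(upper > lower)
  list(upper = upper, lower = lower)
}

#' Screen a raw trial for amplitude artifacts
#'
#' Fails iff any sample exceeds the upper bound or falls below the lower
#' bound. Applied to the raw (pre-filter) trial span; a failing simulated
#' trial is re-recorded upstream.
#'
#' @param x raw samples in uV.
#' @param screen [artifactScreen()] bounds.
#' @return list with `pass` (logical) and `violations` (1-based sample
#'   indices).
#' @export
screenArtifacts <- function(x, screen = artifactScreen()) {
  bad <- which(x > screen$upper | x < screen$lower)
  list(pass = length(bad) == 0L, violations = bad)
}

#' Extract baseline-corrected one-second epochs
#'
#' For every scheduled event, takes the half-open window
#' `[onset, onset + epochLen)` (512 samples at defaults) and subtracts the
#' mean of the 100 ms pre-stimulus window `[onset - baselineLen, onset)`.
#' Events whose epoch would run past the end of the recording are skipped
#' with a warning. Sound labels and target flags are carried over, and
#' 16-dimensional block-mean features are computed for each epoch.
#'
#' @param recording [EEGRecording] (already filtered).
#' @param epochLen epoch length in seconds, default 1.
#' @param baselineLen baseline window length in seconds, default 0.1.
#' @param featureRate rate of the downsampled feature vector, default 16 Hz.
#' @return [EpochSet].
#' @export
extractEpochs <- function(recording, epochLen = 1, baselineLen = 0.1,
                          featureRate = 16) {
  stopifnot(is(recording, "EEGRecording"))
  rate <- recording@sampleRate
  if (recording@preRoll < baselineLen)
    stop("preRoll shorter than the baseline window")
  x <- recording@samples
  ev <- recording@schedule@events
  nEp <- round(epochLen * rate)
  nBl <- floor(baselineLen * rate)
  keep <- logical(nrow(ev))
  epochs <- matrix(NA_real_, nrow(ev), nEp)
  baselines <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    s <- round((recording@preRoll + ev$onset_s[i]) * rate) + 1L
    if (s + nEp - 1L > length(x)) next
    bl <- mean(x[(s - nBl):(s - 1L)])
    epochs[i, ] <- x[s:(s + nEp - 1L)] - bl
    baselines[i] <- bl
    keep[i] <- TRUE
  }
  if (!all(keep))
    warning(sum(!keep), " event(s) skipped: epoch extends past the recording")
  epochs <- epochs[keep, , drop = FALSE]
  factor <- round(rate / featureRate)
  feats <- t(apply(epochs, 1, downsampleEpoch, factor = factor))
  if (nrow(epochs) == 1) feats <- matrix(feats, nrow = 1)
  new("EpochSet", epochs = epochs, features = feats,
      label = as.integer(ev$label[keep]),
      isTarget = as.logical(ev$is_target[keep]), sampleRate = rate,
      trialId = NA_integer_,
      targetLabel = recording@schedule@targetLabel,
      baseline = baselines[keep])
}

#' Downsample an epoch to the feature rate
#'
#' Block-average decimation: feature k is the mean of samples
#' `[factor*k, factor*(k+1))` (0-based), reducing a 512-sample epoch to 16
#' values at the default factor 32. Averaging acts as an anti-alias
#' filter; `method = "decimate"` keeps every factor-th sample instead.
#'
#' @param x numeric epoch; length must be divisible by `factor`.
#' @param factor decimation factor, default 32.
#' @param method "mean" (default) or "decimate".
#' @return numeric vector of `length(x) / factor` values.
#' @export
downsampleEpoch <- function(x, factor = 32, method = c("mean", "decimate")) {
  method <- match.arg(method)
  if (length(x) %% factor != 0)
    stop("epoch length ", length(x), " not divisible by factor ", factor)
  if (method == "mean")
    as.numeric(colMeans(matrix(x, nrow = factor)))
  else
    x[seq(1, length(x), by = factor)]
}

#' Grand-average waveform of a set of epochs
#'
#' Pointwise mean across epochs, computed in the full-rate epoch domain
#' (averaging happens before downsampling). This 30-epoch average per
#' sound label is the unit that gets classified at test time.
#'
#' @param x [EpochSet] or numeric matrix (epochs in rows).
#' @param label optional sound label filter when `x` is an [EpochSet].
#' @return numeric vector, one value per time point.
#' @export
grandAverage <- function(x, label = NULL) {
  m <- if (is(x, "EpochSet")) {
    if (is.null(label)) x@epochs
    else x@epochs[x@label == label, , drop = FALSE]
  } else as.matrix(x)
  if (nrow(m) == 0) stop("no epochs to average")
  colMeans(m)
}

#' Run the fixed preprocessing chain on a recording
#'
#' Pipeline order is fixed: notch (50 Hz) -> band-pass (0.5-10 Hz) ->
#' epoch + baseline -> block-mean downsampling; grand averages, when
#' needed, are formed before downsampling.
#'
#' @param recording [EEGRecording].
#' @param notchHz notch frequency (NULL disables), default 50.
#' @param low,high band-pass cutoffs in Hz.
#' @param order Butterworth order per section.
#' @param epochLen,baselineLen epoch and baseline lengths in seconds.
#' @param zeroPhase zero-phase filtering (default TRUE).
#' @return [EpochSet].
#' @export
preprocessRecording <- function(recording, notchHz = 50, low = 0.5,
                                high = 10, order = 4, epochLen = 1,
                                baselineLen = 0.1, zeroPhase = TRUE) {
  stopifnot(is(recording, "EEGRecording"))
  x <- recording@samples
  if (!is.null(notchHz))
    x <- notchFilter(x, recording@sampleRate, notchHz, zeroPhase = zeroPhase)
  x <- bandpassFilter(x, recording@sampleRate, low, high, order, zeroPhase)
  filtered <- recording
  filtered@samples <- as.numeric(x)
  extractEpochs(filtered, epochLen, baselineLen)
}
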