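#' Construct an ERP template
#'
#' Defaults are the offline grand-average peak statistics the simulator
#' emulates: a negative (N200) peak of -1.35 uV at 281 ms and a positive
#' (P300-family) peak of +1.88 uV at 748 ms. Widths are generator choices:
#' a narrow early bump and a broad late one.
#'
#' @param negLatency,negAmp,negWidth negative bump center (s), amplitude
#'   (uV), Gaussian sd (s).
#' @param posLatency,posAmp,posWidth positive bump parameters.
#' @return [ERPTemplate].
#' @export
erpTemplate <- function(negLatency = 0.281, negAmp = -1.35, negWidth = 0.035,
                        posLatency = 0.748, posAmp = 1.88, posWidth = 0.120) {
  new("ERPTemplate", negLatency = negLatency, negAmp = negAmp,
      negWidth = negWidth, posLatency = posLatency, posAmp = posAmp,
      posWidth = posWidth)
}

#' Evaluate an ERP template as a 1-second waveform
#'
#' Sum of the two Gaussian bumps sampled at `sampleRate` over
#' `[0, duration)`; sample k (0-based) sits at time k/rate. Linear in the
#' amplitudes; all-zero when both amplitudes are zero.
#'
#' @param template [ERPTemplate].
#' @param sampleRate Hz, default 512.
#' @param duration seconds, default 1.
#' @return numeric vector of `sampleRate * duration` values (uV).
#' @export
templateWaveform <- function(template, sampleRate = 512, duration = 1) {
  stopifnot(is(template, "ERPTemplate"))
  validObject(template)
  if (template@negLatency >= duration || template@posLatency >= duration)
    stop("template latencies must fall inside the epoch")
  n <- round(sampleRate * duration)
  t <- (seq_len(n) - 1) / sampleRate
  template@negAmp * exp(-0.5 * ((t - template@negLatency) / template@negWidth)^2) +
    template@posAmp * exp(-0.5 * ((t - template@posLatency) / template@posWidth)^2)
}

#' Draw a subject-level template
#'
#' Subject variability: latencies and amplitudes drawn from normal
#' distributions with the grand-average mean/SD (negative peak 281 +/- 38
#' ms, -1.35 +/- 0.67 uV; positive peak 748 +/- 205 ms, +1.88 +/- 1.71 uV),
#' truncated to the template validity windows and to minimum absolute
#' amplitudes (0.4 / 0.5 uV) so every simulated subject carries a
#' detectable ERP. Uses the current RNG stream.
#'
#' @return [ERPTemplate].
#' @export
drawSubjectTemplate <- function() {
  rtrunc <- function(mean, sd, lo, hi) {
    for (i in 1:1000) {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lo && v <= hi) return(v)
    }
    stop("truncated draw failed")
  }
  erpTemplate(
    negLatency = rtrunc(0.281, 0.038, 0.210, 0.345),
    negAmp     = -rtrunc(1.35, 0.67, 0.40, 3.50),
    posLatency = rtrunc(0.748, 0.205, 0.360, 0.990),
    posAmp     = rtrunc(1.88, 1.71, 0.50, 6.00))
}

#' Construct a background-noise model
#'
#' Default: 4.5 uV total sd, half the variance white and half 1/f-shaped.
#' The level is calibrated so that single epochs are hard to classify while
#' 30-epoch averages are clean, and so that default recordings stay inside
#' the +40.0/-25.0 uV artifact screen with high probability.
#'
#' @param sd total noise standard deviation in uV.
#' @param alpha spectral exponent of the shaped component.
#' @param whiteFraction fraction of variance carried by the white component.
#' @return [NoiseModel].
#' @export
noiseModel <- function(sd = 4.5, alpha = 1, whiteFraction = 0.5) {
  new("NoiseModel", sd = sd, alpha = alpha, whiteFraction = whiteFraction)
}

## 1/f^alpha noise via FFT spectral shaping; unit empirical sd, zero DC.
shapedNoise <- function(n, alpha) {
  z <- stats::fft(stats::rnorm(n))
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1)))  # symmetric freq index
  shape <- c(0, f[-1]^(-alpha / 2))
  x <- Re(stats::fft(z * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate a continuous single-channel EEG recording
#'
#' Background noise (per [noiseModel()]) plus, at every scheduled event
#' onset, the corresponding 1-second template: the target template for
#' target events, `nontargetTemplate` (default: flat zero) otherwise.
#' Because the SOA (0.3 s) is shorter than the epoch (1 s), overlapping
#' contributions sum, exactly as in the real paradigm. Each event's
#' template is scaled by a lognormal amplitude jitter with coefficient of
#' variation `epochJitterCv` (mean 1) to create single-trial variability.
#' Deterministic for a fixed `seed`.
#'
#' @param schedule [StimulusSchedule].
#' @param targetTemplate [ERPTemplate] for target events.
#' @param nontargetTemplate [ERPTemplate] or NULL for a flat non-target
#'   response.
#' @param noise [NoiseModel].
#' @param sampleRate Hz, default 512.
#' @param preRoll seconds of signal before the first onset, default 0.5.
#' @param epochJitterCv per-event amplitude jitter cv (0 disables).
#' @param seed optional integer seed.
#' @return [EEGRecording].
#' @export
simulateRecording <- function(schedule, targetTemplate,
                              nontargetTemplate = NULL,
                              noise = noiseModel(), sampleRate = 512,
                              preRoll = 0.5, epochJitterCv = 0.3,
                              seed = NULL) {
  stopifnot(is(schedule, "StimulusSchedule"), is(targetTemplate, "ERPTemplate"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  span <- scheduleSpan(schedule)
  n <- ceiling((preRoll + span + 1) * sampleRate)
  x <- if (noise@sd > 0) {
    w <- stats::rnorm(n)
    p <- if (noise@whiteFraction < 1) shapedNoise(n, noise@alpha) else 0
    noise@sd * (sqrt(noise@whiteFraction) * w +
                sqrt(1 - noise@whiteFraction) * p)
  } else numeric(n)
  tw <- templateWaveform(targetTemplate, sampleRate)
  ntw <- if (is.null(nontargetTemplate)) numeric(length(tw))
         else templateWaveform(nontargetTemplate, sampleRate)
  nEp <- length(tw)
  if (epochJitterCv > 0) {
    sdlog <- sqrt(log(1 + epochJitterCv^2))
    amps <- stats::rlnorm(nrow(schedule@events), -sdlog^2 / 2, sdlog)
  } else amps <- rep(1, nrow(schedule@events))
  ev <- schedule@events
  for (i in seq_len(nrow(ev))) {
    s <- round((preRoll + ev$onset_s[i]) * sampleRate) + 1L
    contrib <- if (ev$is_target[i]) tw else ntw
    x[s:(s + nEp - 1L)] <- x[s:(s + nEp - 1L)] + amps[i] * contrib
  }
  new("EEGRecording", samples = x, sampleRate = sampleRate,
      schedule = schedule, preRoll = preRoll)
}

#' Inject a short artifact excursion
#'
#' Adds a raised-cosine bump of the given peak amplitude and ~50 ms width
#' at `time_s` (seconds from the start of the recording). Used to exercise
#' the amplitude artifact screen, which default recordings otherwise pass.
#'
#' @param recording [EEGRecording].
#' @param time_s center time of the excursion in seconds.
#' @param amplitude_uv peak amplitude in uV (sign preserved).
#' @param width_s excursion width in seconds, default 0.05.
#' @return modified [EEGRecording].
#' @export
injectArtifact <- function(recording, time_s, amplitude_uv, width_s = 0.05) {
  stopifnot(is(recording, "EEGRecording"))
  rate <- recording@sampleRate
  n <- length(recording@samples)
  if (time_s < 0 || time_s > n / rate) stop("time_s outside the recording")
  w <- max(3L, round(width_s * rate))
  bump <- amplitude_uv * 0.5 * (1 - cos(2 * pi * seq_len(w) / (w + 1)))
  c0 <- round(time_s * rate) - floor(w / 2)
  idx <- c0 + seq_len(w)
  keep <- idx >= 1 & idx <= n
  recording@samples[idx[keep]] <- recording@samples[idx[keep]] + bump[keep]
  recording
}

#' Simulate a full offline subject
#'
#' One subject = `nRuns` runs of `trialsPerRun` trials (defaults 3 x 5); in
#' each run every sound serves as target exactly once, in random order.
#' Each trial is simulated, screened against the raw-amplitude artifact
#' bounds, and re-simulated with a fresh sub-seed when the screen fails
#' (mirroring the protocol's "record the trial again"). Trials are then
#' notch- and band-pass filtered, epoched, baseline-corrected and
#' downsampled via [preprocessRecording()]. The subject's ERP template is
#' drawn from the population model unless supplied.
#'
#' @param seed integer subject seed (subject identity = seed).
#' @param template optional [ERPTemplate]; drawn via
#'   [drawSubjectTemplate()] when NULL.
#' @param nontargetTemplate optional [ERPTemplate] for non-target events.
#' @param noise [NoiseModel].
#' @param nRuns,trialsPerRun run structure, defaults 3 and 5.
#' @param nSequences sequences per trial, default 30.
#' @param soa stimulus-onset asynchrony, default 0.3 s.
#' @param sampleRate Hz, default 512.
#' @param epochJitterCv per-event amplitude jitter cv.
#' @param screen artifact bounds from [artifactScreen()].
#' @param maxRetries maximum re-recordings per trial.
#' @return [ERPDataset] with `nRuns * trialsPerRun` trials.
#' @export
simulateSubject <- function(seed, template = NULL, nontargetTemplate = NULL,
                            noise = noiseModel(), nRuns = 3L,
                            trialsPerRun = 5L, nSequences = 30L, soa = 0.3,
                            sampleRate = 512, epochJitterCv = 0.3,
                            screen = artifactScreen(), maxRetries = 20L) {
  seed <- as.integer(seed)
  set.seed(seed)
  if (is.null(template)) template <- drawSubjectTemplate()
  trialList <- vector("list", nRuns * trialsPerRun)
  tid <- 0L
  for (run in seq_len(nRuns)) {
    targets <- if (trialsPerRun == 5L) sample(5L)
               else sample(5L, trialsPerRun, replace = trialsPerRun > 5L)
    for (tr in seq_len(trialsPerRun)) {
      tid <- tid + 1L
      rec <- NULL
      for (attempt in seq_len(maxRetries)) {
        sched <- buildTrialSchedule(targets[tr], nSequences, soa)
        cand <- simulateRecording(sched, template, nontargetTemplate, noise,
                                  sampleRate, epochJitterCv = epochJitterCv)
        if (screenArtifacts(samples(cand), screen)$pass) { rec <- cand; break }
      }
      if (is.null(rec))
        stop("trial ", tid, " failed the artifact screen ", maxRetries,
             " times; noise model incompatible with the screen")
      es <- preprocessRecording(rec)
      es@trialId <- tid
      es@targetLabel <- targets[tr]
      trialList[[tid]] <- es
    }
  }
  new("ERPDataset", trials = trialList, subjectSeed = seed,
      template = template)
}
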