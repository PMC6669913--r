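#' Pipeline configuration with the paradigm's printed defaults
#'
#' One flat configuration covering all stages. Every default equals the
#' paradigm's stated value where one exists: 150 ms stimulus + 150 ms gap
#' (SOA 0.3 s), 30 sequences, head-model r = 0.9 / c = 340, 512 Hz,
#' 0.5-10 Hz order-4 band-pass, 50 Hz notch, +40.0/-25.0 uV artifact
#' bounds, 100 ms baseline, SWLDA p < 0.10 entry / p > 0.15 removal, 45 s
#' selection time. Synthesis parameters (noise level, jitter) are the
#' generator's calibrated defaults.
#'
#' @param ... named overrides of the top-level entries, e.g.
#'   `swlda = list(pEnter = 0.05)` (partial lists are merged).
#' @return nested named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    paradigm = list(soa = 0.3, stimulusDuration = 0.15, nSequences = 30L,
                    headRadius = 0.9, soundSpeed = 340.0),
    preprocess = list(sampleRate = 512, notchHz = 50, low = 0.5, high = 10,
                      order = 4, baselineLen = 0.1, epochLen = 1,
                      featureRate = 16, screenUpper = 40.0,
                      screenLower = -25.0),
    synth = list(noiseSd = 4.5, alpha = 1, whiteFraction = 0.5,
                 epochJitterCv = 0.3, preRoll = 0.5),
    swlda = list(pEnter = 0.10, pRemove = 0.15),
    evaluate = list(selectionTime = 45),
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Read a YAML configuration file over the defaults
#'
#' Entries present in the file override the corresponding
#' [pipelineConfig()] defaults; everything else keeps its default, so any
#' run is reproducible from the resolved config plus seed.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return nested named list.
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- pipelineConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], user[[nm]])
    else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

simulateExtraTrials <- function(template, cfg, targets, startTrialId,
                                noise, screen) {
  out <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    rec <- NULL
    for (attempt in 1:20) {
      sched <- buildTrialSchedule(targets[i], cfg$paradigm$nSequences,
                                  cfg$paradigm$soa)
      cand <- simulateRecording(
        sched, template, noise = noise,
        sampleRate = cfg$preprocess$sampleRate,
        preRoll = cfg$synth$preRoll,
        epochJitterCv = cfg$synth$epochJitterCv)
      if (screenArtifacts(samples(cand), screen)$pass) { rec <- cand; break }
    }
    if (is.null(rec)) stop("online trial failed the artifact screen repeatedly")
    es <- preprocessRecording(rec, cfg$preprocess$notchHz, cfg$preprocess$low,
                              cfg$preprocess$high, cfg$preprocess$order,
                              cfg$preprocess$epochLen,
                              cfg$preprocess$baselineLen)
    es@trialId <- startTrialId + i - 1L
    es@targetLabel <- targets[i]
    out[[i]] <- es
  }
  out
}

#' Run the full analysis pipeline on a simulated subject
#'
#' Offline mode simulates 3 runs x 5 trials and evaluates LOTOCV at every
#' command count under both training schemes ("candidates": only
#' candidate-target trials train; "all": every remaining trial trains).
#' Online mode 1 freezes a model trained on all offline sub-trial data and
#' evaluates 2 fresh runs of 3 trials with candidates duck/frog/dove
#' (labels 1, 3, 5), each target used twice. Online mode 2 first appends
#' 2 calibration runs to the training data, refits, then evaluates 8
#' fresh runs. Reports (JSON) and feature tables (CSV) are written to
#' `outDir` when given.
#'
#' @param config [pipelineConfig()] list.
#' @param mode "offline", "online1" or "online2".
#' @param seed subject seed; defaults to `config$seed`.
#' @param outDir optional output directory for report files.
#' @return report list (also written as JSON when `outDir` is set).
#' @export
runPipeline <- function(config = pipelineConfig(),
                        mode = c("offline", "online1", "online2"),
                        seed = config$seed, outDir = NULL) {
  mode <- match.arg(mode)
  cfg <- config
  screen <- artifactScreen(cfg$preprocess$screenUpper,
                           cfg$preprocess$screenLower)
  noise <- noiseModel(cfg$synth$noiseSd, cfg$synth$alpha,
                      cfg$synth$whiteFraction)
  message("simulating offline subject (seed ", seed, ", noise sd ",
          noise@sd, " uV)")
  ds <- simulateSubject(seed, noise = noise,
                        nSequences = cfg$paradigm$nSequences,
                        soa = cfg$paradigm$soa,
                        sampleRate = cfg$preprocess$sampleRate,
                        epochJitterCv = cfg$synth$epochJitterCv,
                        screen = screen)
  nEpochs <- sum(vapply(ds@trials, function(t) nrow(epochMatrix(t)),
                        numeric(1)))
  message("  ", length(ds@trials), " trials, ", nEpochs, " epochs")
  T <- cfg$evaluate$selectionTime
  pe <- cfg$swlda$pEnter; pr <- cfg$swlda$pRemove
  report <- list(mode = mode, seed = seed,
                 counts = list(trials = length(ds@trials),
                               epochs = nEpochs))
  if (mode == "offline") {
    res5 <- lotocv(ds, 1:5, "candidates", pe, pr)
    perf <- list(list(commands = 5, scheme = "candidates",
                      accuracy = res5$accuracy,
                      itr_bits_min = itr(5, max(res5$accuracy, 1e-12), T)))
    for (K in c(4, 3, 2)) for (sch in c("candidates", "all")) {
      sw <- reducedCommandSweep(ds, K, sch, pe, pr)
      perf[[length(perf) + 1]] <-
        list(commands = K, scheme = sch, accuracy = sw$accuracy,
             itr_bits_min = itr(K, max(sw$accuracy, 1e-12), T))
    }
    tgt <- do.call(rbind, lapply(ds@trials, function(t)
      t@epochs[t@isTarget, , drop = FALSE]))
    ga <- colMeans(tgt)
    report$performance <- perf
    report$confusion_5cmd <- as.integer(res5$confusion$counts)
    report$peaks <- findPeaks(ga, cfg$preprocess$sampleRate)
    message(sprintf("  5-command LOTOCV accuracy %.1f%%, ITR %.2f bits/min",
                    100 * res5$accuracy, itr(5, max(res5$accuracy, 1e-12), T)))
  } else {
    candidates <- c(1L, 3L, 5L)
    trainTrials <- ds@trials
    if (mode == "online2") {
      calTargets <- rep(candidates, 2)[order(rep(1:2, each = 3))]
      cal <- simulateExtraTrials(ds@template, cfg,
                                 as.integer(calTargets), 100L, noise, screen)
      trainTrials <- c(trainTrials, cal)
      message("  added ", length(cal), " calibration trials")
    }
    td <- trainingData(trainTrials)
    model <- swldaFit(td$X, td$y, pe, pr)
    nRunsEval <- if (mode == "online1") 2L else 8L
    evTargets <- as.integer(unlist(lapply(seq_len(nRunsEval),
                                          function(r) sample(candidates))))
    ev <- simulateExtraTrials(ds@template, cfg, evTargets, 200L, noise,
                              screen)
    sess <- onlineSession(model, ev, candidates)
    report$performance <- list(list(
      commands = 3, scheme = "frozen-offline-model",
      accuracy = sess$accuracy,
      itr_bits_min = itr(3, max(sess$accuracy, 1e-12), T)))
    report$counts$evalTrials <- length(ev)
    report$counts$trainEpochs <- nrow(td$X)
    report$confusion <- as.integer(sess$confusion$counts)
    report$predictions <- sess$predictions
    message(sprintf("  %s accuracy %.1f%% over %d trials", mode,
                    100 * sess$accuracy, length(ev)))
  }
  report$config <- cfg
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeFeaturesCsv(ds, file.path(outDir, "features.csv"))
    message("  wrote report.json and features.csv to ", outDir)
  }
  invisible(report)
}
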