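## Evaluation machinery: Wolpaw ITR, leave-one-trial-out cross-validation,
## reduced-command sweeps, confusion/TPR arithmetic, signed-R2
## discriminability, peak analysis and incremental learning curves.

#' Wolpaw information transfer rate
#'
#' `ITR = (log2 N + P log2 P + (1-P) log2((1-P)/(N-1))) * 60 / T` in
#' bits/min, with N selectable commands, detection accuracy P and
#' selection time T seconds (45 s = one trial). At P = 1 the two
#' P-dependent terms vanish by continuity. The value is returned
#' unclipped and can be negative below chance level.
#'
#' @param nCommands N, number of selectable commands (>= 2).
#' @param accuracy P, detection accuracy in (0, 1].
#' @param selectionTime T, seconds per selection, default 45.
#' @return bits per minute.
#' @examples
#' itr(5, 1.0)    # 3.10 bits/min
#' itr(3, 0.875)  # 1.22 bits/min
#' @export
itr <- function(nCommands, accuracy, selectionTime = 45) {
  if (any(nCommands < 2)) stop("nCommands must be >= 2")
  if (any(accuracy <= 0 | accuracy > 1)) stop("accuracy must be in (0, 1]")
  stopifnot(selectionTime > 0)
  bits <- log2(nCommands) +
    ifelse(accuracy < 1,
           accuracy * log2(accuracy) +
             (1 - accuracy) * log2((1 - accuracy) / (nCommands - 1)),
           0)
  bits * 60 / selectionTime
}

## Per-label grand-average test features of one trial: average the 30
## epochs of each sound label at full rate, then downsample.
trialTestFeatures <- function(es, factor = 32) {
  labs <- sort(unique(es@label))
  m <- t(vapply(labs, function(l)
    downsampleEpoch(grandAverage(es, l), factor),
    numeric(ncol(es@epochs) / factor)))
  rownames(m) <- labs
  m
}

trainingData <- function(trialList) {
  list(X = do.call(rbind, lapply(trialList, featureMatrix)),
       y = unlist(lapply(trialList, epochTargets)))
}

#' Leave-one-trial-out cross-validation
#'
#' Each trial in turn is held out; an SWLDA model is trained on the
#' sub-trial feature vectors of the remaining trials and tested on the
#' held-out trial's five per-label grand-average waveforms (downsampled,
#' scored, decided via [decideTarget()] with the candidate restriction).
#' Folds are the trials whose target is in `candidates`. Training scheme
#' "candidates" uses only remaining trials whose target is a candidate
#' (11/8/5 trials for 4/3/2 commands); scheme "all" always trains on all
#' remaining trials.
#'
#' @param dataset [ERPDataset].
#' @param candidates eligible output labels, default all five.
#' @param scheme "candidates" (default) or "all".
#' @param pEnter,pRemove SWLDA stepping thresholds.
#' @return list with `predictions` (data.frame: trial, truth, predicted,
#'   nTrainEpochs), `accuracy`, `confusion` (from [confusionStats()]) and
#'   `nTestWaveforms`.
#' @export
lotocv <- function(dataset, candidates = 1:5,
                   scheme = c("candidates", "all"),
                   pEnter = 0.10, pRemove = 0.15) {
  scheme <- match.arg(scheme)
  stopifnot(is(dataset, "ERPDataset"))
  tl <- dataset@trials
  if (length(tl) < 2) stop("need at least 2 trials")
  tgts <- vapply(tl, targetLabel, integer(1))
  folds <- which(tgts %in% candidates)
  preds <- data.frame(trial = folds, truth = tgts[folds],
                      predicted = NA_integer_, nTrainEpochs = NA_integer_)
  for (k in seq_along(folds)) {
    i <- folds[k]
    trainIdx <- setdiff(seq_along(tl), i)
    if (scheme == "candidates")
      trainIdx <- trainIdx[tgts[trainIdx] %in% candidates]
    td <- trainingData(tl[trainIdx])
    model <- swldaFit(td$X, td$y, pEnter, pRemove)
    tf <- trialTestFeatures(tl[[i]])
    scores <- swldaScore(model, tf)
    names(scores) <- rownames(tf)
    preds$predicted[k] <- decideTarget(scores, candidates)
    preds$nTrainEpochs[k] <- nrow(td$X)
  }
  conf <- confusionStats(preds$truth, preds$predicted, sort(candidates))
  list(predictions = preds, accuracy = mean(preds$predicted == preds$truth),
       confusion = conf, nTestWaveforms = length(candidates))
}

#' Reduced-command accuracy sweep
#'
#' Mean LOTOCV accuracy over all size-`k` candidate subsets, each fold
#' evaluated only under subsets containing its true target (otherwise its
#' accuracy is undefined). Under scheme "all" the training set of a fold
#' does not depend on the subset, so one model per fold is fitted and
#' reused; under scheme "candidates" training is restricted to
#' candidate-target trials and refitted per (fold, subset).
#'
#' @param dataset [ERPDataset].
#' @param k number of commands, 2..5.
#' @param scheme "candidates" (default) or "all".
#' @param pEnter,pRemove SWLDA stepping thresholds.
#' @return list with `accuracy` (mean over all decisions), `decisions`
#'   (data.frame: trial, truth, predicted, subset, nTrainEpochs) and `k`.
#' @export
reducedCommandSweep <- function(dataset, k,
                                scheme = c("candidates", "all"),
                                pEnter = 0.10, pRemove = 0.15) {
  scheme <- match.arg(scheme)
  stopifnot(is(dataset, "ERPDataset"), k >= 2, k <= 5)
  tl <- dataset@trials
  tgts <- vapply(tl, targetLabel, integer(1))
  subsets <- utils::combn(5L, k)
  rows <- list()
  if (scheme == "all") {
    for (i in seq_along(tl)) {
      trainIdx <- setdiff(seq_along(tl), i)
      td <- trainingData(tl[trainIdx])
      model <- swldaFit(td$X, td$y, pEnter, pRemove)
      tf <- trialTestFeatures(tl[[i]])
      scores <- swldaScore(model, tf)
      names(scores) <- rownames(tf)
      for (s in seq_len(ncol(subsets))) {
        cand <- subsets[, s]
        if (!(tgts[i] %in% cand)) next
        rows[[length(rows) + 1L]] <- data.frame(
          trial = i, truth = tgts[i],
          predicted = decideTarget(scores, cand),
          subset = paste(cand, collapse = ","),
          nTrainEpochs = nrow(td$X))
      }
    }
  } else {
    for (s in seq_len(ncol(subsets))) {
      cand <- subsets[, s]
      res <- lotocv(dataset, cand, scheme = "candidates", pEnter, pRemove)
      res$predictions$subset <- paste(cand, collapse = ",")
      rows[[length(rows) + 1L]] <-
        res$predictions[, c("trial", "truth", "predicted", "subset",
                            "nTrainEpochs")]
    }
  }
  dec <- do.call(rbind, rows)
  list(accuracy = mean(dec$predicted == dec$truth), decisions = dec, k = k)
}

#' Confusion matrix, per-class TPR and mean accuracy
#'
#' `confusionStats` tallies true-by-predicted counts from label vectors;
#' `confusionFromCounts` computes the derived statistics from an existing
#' count matrix. The per-class true positive rate (TPR, "detection
#' accuracy") is the diagonal over the row sum, and the mean accuracy is
#' the trace over the total.
#'
#' @param true,predicted equal-length label vectors.
#' @param labels the label set; values outside it are an error.
#' @return list with `counts` (K x K matrix, true in rows), `tpr` (per
#'   class, proportion) and `accuracy` (trace/total).
#' @export
confusionStats <- function(true, predicted, labels = sort(unique(c(true, predicted)))) {
  if (length(true) != length(predicted))
    stop("true and predicted must have equal length")
  if (!all(c(true, predicted) %in% labels))
    stop("label outside the declared label set")
  f <- function(v) factor(v, levels = labels)
  counts <- table(true = f(true), predicted = f(predicted))
  confusionFromCounts(unclass(counts))
}

#' @rdname confusionStats
#' @param counts square matrix of true-by-predicted counts.
#' @export
confusionFromCounts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  rs <- rowSums(counts)
  tpr <- ifelse(rs > 0, diag(counts) / rs, NA_real_)
  list(counts = counts, tpr = tpr,
       accuracy = sum(diag(counts)) / sum(counts))
}

#' Signed R-squared discriminability time course
#'
#' Per time point, the squared point-biserial correlation between epoch
#' amplitude and class membership (target vs non-target), signed by the
#' direction of the class mean difference. Values lie in [-1, 1]; time
#' points with zero overall variance yield 0. Invariant under adding a
#' common constant to all epochs; swapping the classes flips the sign.
#'
#' @param targetEpochs,nontargetEpochs numeric matrices, epochs in rows,
#'   the same number of time-point columns.
#' @param sampleRate Hz for the time axis, default 512.
#' @return list with `values` (one per time point) and `time` (seconds
#'   post-onset).
#' @export
signedR2 <- function(targetEpochs, nontargetEpochs, sampleRate = 512) {
  targetEpochs <- as.matrix(targetEpochs)
  nontargetEpochs <- as.matrix(nontargetEpochs)
  if (nrow(targetEpochs) == 0 || nrow(nontargetEpochs) == 0)
    stop("both classes must be non-empty")
  if (ncol(targetEpochs) != ncol(nontargetEpochs))
    stop("epoch lengths differ between classes")
  x <- rbind(targetEpochs, nontargetEpochs)
  g <- c(rep(1, nrow(targetEpochs)), rep(0, nrow(nontargetEpochs)))
  gc <- g - mean(g)
  xc <- sweep(x, 2, colMeans(x))
  num <- as.numeric(crossprod(gc, xc))          # (n-1) * cov(g, x_t)
  den <- sqrt(sum(gc^2) * colSums(xc^2))
  r <- ifelse(den > 0, num / den, 0)
  vals <- sign(colMeans(targetEpochs) - colMeans(nontargetEpochs)) * r^2
  vals[den == 0] <- 0
  list(values = vals, time = (seq_len(ncol(x)) - 1) / sampleRate)
}

#' Locate negative and positive ERP peaks
#'
#' The negative peak is the minimum within 200-350 ms post-onset and the
#' positive peak the maximum within 350-1000 ms, the standard search
#' windows for the N200 and P300-family components here. Ties resolve to
#' the earliest time point.
#'
#' @param waveform 1-second grand-average waveform.
#' @param sampleRate Hz, default 512.
#' @param negWindow,posWindow search windows in seconds.
#' @return list with `negLatency` and `posLatency` (seconds),
#'   `negLatencyMs`/`posLatencyMs` and `negAmp`/`posAmp` (uV).
#' @export
findPeaks <- function(waveform, sampleRate = 512,
                      negWindow = c(0.200, 0.350),
                      posWindow = c(0.350, 1.000)) {
  t <- (seq_along(waveform) - 1) / sampleRate
  ni <- which(t >= negWindow[1] & t <= negWindow[2])
  pi_ <- which(t >= posWindow[1] & t <= posWindow[2])
  if (!length(ni) || !length(pi_)) stop("search windows outside the waveform")
  nIdx <- ni[which.min(waveform[ni])]
  pIdx <- pi_[which.max(waveform[pi_])]
  list(negLatency = t[nIdx], negLatencyMs = t[nIdx] * 1000,
       negAmp = waveform[nIdx],
       posLatency = t[pIdx], posLatencyMs = t[pIdx] * 1000,
       posAmp = waveform[pIdx])
}

#' Incremental learning curve
#'
#' For each fold and each value of `nTrainValues`, training trials are
#' drawn uniformly at random from the remaining trials, an SWLDA model is
#' fitted on their sub-trial features, and the held-out trial is decided.
#' For command counts below five, each decision uses a random candidate
#' subset containing the fold's true target. Accuracies are averaged over
#' `nRepeats` draws; seeded and reproducible.
#'
#' @param dataset [ERPDataset].
#' @param nTrainValues training-set sizes to probe, default 1..(n-1).
#' @param nRepeats random draws per size, default 10.
#' @param commands vector of command counts to evaluate, default
#'   c(2, 3, 4, 5).
#' @param seed optional integer seed.
#' @param pEnter,pRemove SWLDA stepping thresholds.
#' @return data.frame with columns `nTrain`, `commands`, `accuracy`.
#' @export
learningCurve <- function(dataset, nTrainValues = NULL, nRepeats = 10,
                          commands = c(2, 3, 4, 5), seed = NULL,
                          pEnter = 0.10, pRemove = 0.15) {
  stopifnot(is(dataset, "ERPDataset"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  tl <- dataset@trials
  nT <- length(tl)
  if (is.null(nTrainValues)) nTrainValues <- seq_len(nT - 1)
  stopifnot(all(nTrainValues >= 1), all(nTrainValues < nT))
  tgts <- vapply(tl, targetLabel, integer(1))
  hits <- array(0, dim = c(length(nTrainValues), length(commands)))
  tot <- hits
  testFeats <- lapply(tl, trialTestFeatures)
  ## per-trial sufficient statistics; Gram matrices add over trials
  stats <- lapply(tl, function(es) {
    Xd <- cbind(1, featureMatrix(es))
    yy <- ifelse(epochTargets(es), 1, -1)
    list(G = crossprod(Xd), cy = as.numeric(crossprod(Xd, yy)),
         yty = sum(yy^2), n = nrow(Xd))
  })
  nf <- ncol(featureMatrix(tl[[1]]))
  for (rep in seq_len(nRepeats)) {
    for (i in seq_len(nT)) {
      rest <- setdiff(seq_len(nT), i)
      for (v in seq_along(nTrainValues)) {
        trainIdx <- if (nTrainValues[v] == nT - 1) rest
                    else sample(rest, nTrainValues[v])
        G <- Reduce(`+`, lapply(stats[trainIdx], `[[`, "G"))
        cy <- Reduce(`+`, lapply(stats[trainIdx], `[[`, "cy"))
        yty <- sum(vapply(stats[trainIdx], `[[`, numeric(1), "yty"))
        n <- sum(vapply(stats[trainIdx], `[[`, numeric(1), "n"))
        model <- swldaFitCore(G, cy, yty, n, nf, pEnter, pRemove)
        scores <- swldaScore(model, testFeats[[i]])
        names(scores) <- rownames(testFeats[[i]])
        for (ci in seq_along(commands)) {
          K <- commands[ci]
          cand <- if (K == 5) 1:5
                  else sort(c(tgts[i], sample(setdiff(1:5, tgts[i]), K - 1)))
          hit <- decideTarget(scores, cand) == tgts[i]
          hits[v, ci] <- hits[v, ci] + hit
          tot[v, ci] <- tot[v, ci] + 1
        }
      }
    }
  }
  out <- expand.grid(nTrain = nTrainValues, commands = commands)
  out$accuracy <- as.numeric(hits / tot)
  out
}

#' Fit the offline model of a subject
#'
#' Trains a single SWLDA model on the sub-trial features of all trials of
#' the dataset (optionally restricted to candidate-target trials) — the
#' model that is then frozen for online use.
#'
#' @param dataset [ERPDataset].
#' @param candidates restrict training trials to these targets under
#'   scheme "candidates".
#' @param scheme "all" (default: every trial contributes) or "candidates".
#' @param pEnter,pRemove SWLDA stepping thresholds.
#' @return [SWLDAModel].
#' @export
fitSubjectModel <- function(dataset, candidates = 1:5,
                            scheme = c("all", "candidates"),
                            pEnter = 0.10, pRemove = 0.15) {
  scheme <- match.arg(scheme)
  tl <- dataset@trials
  if (scheme == "candidates") {
    tgts <- vapply(tl, targetLabel, integer(1))
    tl <- tl[tgts %in% candidates]
  }
  td <- trainingData(tl)
  swldaFit(td$X, td$y, pEnter, pRemove)
}

#' Evaluate new trials with a frozen model
#'
#' Online evaluation: no refitting. Each new trial is decided from its
#' five per-label grand-average waveforms via [decideTarget()] with the
#' candidate restriction. To emulate the second online protocol, append
#' calibration trials to the training data and refit with
#' [fitSubjectModel()] before calling this.
#'
#' @param model fitted [SWLDAModel].
#' @param newTrials [ERPDataset] or list of [EpochSet] trials.
#' @param candidates eligible output labels.
#' @return list with `predictions` (data.frame trial/truth/predicted),
#'   `accuracy` and `confusion`.
#' @export
onlineSession <- function(model, newTrials, candidates = c(1, 3, 5)) {
  stopifnot(is(model, "SWLDAModel"))
  tl <- if (is(newTrials, "ERPDataset")) newTrials@trials else newTrials
  tgts <- vapply(tl, targetLabel, integer(1))
  preds <- integer(length(tl))
  for (i in seq_along(tl)) {
    tf <- trialTestFeatures(tl[[i]])
    scores <- swldaScore(model, tf)
    names(scores) <- rownames(tf)
    preds[i] <- decideTarget(scores, candidates)
  }
  conf <- confusionStats(tgts, preds, sort(unique(c(candidates, tgts))))
  list(predictions = data.frame(trial = seq_along(tl), truth = tgts,
                                predicted = preds),
       accuracy = mean(preds == tgts), confusion = conf)
}
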