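test_that("ITR matches an independent transcription of the formula", {
  for (N in 2:5) for (P in c(0.05, 0.2, 1 / N, 0.5, 0.875, 0.99, 1))
    expect_equal(itr(N, P), naiveItr(N, P), tolerance = 1e-12)
  expect_equal(round(itr(5, 1), 2), 3.10)
  expect_equal(itr(2, 0.5), 0, tolerance = 1e-12)   # fair coin carries no info
  # log2 N minus the entropy of the induced distribution is never negative
  for (N in 2:5) expect_gte(min(itr(N, seq(0.01, 1, by = 0.01))), -1e-12)
  expect_error(itr(1, 0.5), "nCommands")
  expect_error(itr(3, 0), "accuracy")
  expect_error(itr(3, 1.2), "accuracy")
})

test_that("confusion arithmetic: counts, TPR and mean accuracy", {
  true <- c(1, 1, 2, 2, 3, 3)
  pred <- c(1, 2, 2, 2, 3, 1)
  cs <- confusionStats(true, pred, 1:3)
  expect_equal(sum(cs$counts), 6)
  expect_equal(as.numeric(cs$tpr), c(0.5, 1, 0.5))
  expect_equal(cs$accuracy, 4 / 6)
  expect_error(confusionStats(c(1, 9), c(1, 1), 1:3), "label")
  # perfect predictions -> identity pattern
  cp <- confusionStats(1:5, 1:5, 1:5)
  expect_equal(unname(diag(cp$counts)), rep(1L, 5))
  expect_equal(as.numeric(cp$tpr), rep(1, 5))
  # balanced designs: mean of per-class TPRs equals trace/total
  m <- matrix(c(18, 1, 1, 3, 13, 4, 1, 2, 17), 3, byrow = TRUE)
  cf <- confusionFromCounts(m)
  expect_equal(mean(cf$tpr), cf$accuracy)
  expect_equal(cf$accuracy, 0.80)
})

test_that("signed R2 behaves as a signed point-biserial r-squared", {
  set.seed(33)
  # identical class distributions -> near zero everywhere
  a <- matrix(rnorm(40 * 64), 40)
  b <- matrix(rnorm(40 * 64), 40)
  r0 <- signedR2(a, b)
  expect_true(all(abs(r0$values) < 3 / sqrt(80)))
  # pure constant shift, no within-class noise -> exactly 1
  base <- matrix(rep(rnorm(64), each = 5), 5)
  r1 <- signedR2(base + 2, base)
  expect_equal(r1$values, rep(1, 64), tolerance = 1e-12)
  # sign flips under class swap; invariant to common offsets
  x <- a + 0.8; y <- b
  rs <- signedR2(x, y)
  expect_equal(signedR2(y, x)$values, -rs$values, tolerance = 1e-12)
  expect_equal(signedR2(x + 5, y + 5)$values, rs$values, tolerance = 1e-10)
  # zero-variance time points give 0
  z <- signedR2(matrix(1, 4, 3), matrix(1, 4, 3))
  expect_equal(z$values, c(0, 0, 0))
})

test_that("signed R2 peaks near the generating template peaks", {
  set.seed(44)
  tpl <- erpTemplate()
  sched <- buildTrialSchedule(1, 30, 0.3)
  rec <- simulateRecording(sched, tpl, noise = noiseModel(sd = 3))
  es <- preprocessRecording(rec)
  rs <- signedR2(epochMatrix(es)[epochTargets(es), ],
                 epochMatrix(es)[!epochTargets(es), ])
  negPeak <- rs$time[which.min(rs$values * (rs$time < 0.35))]
  iNeg <- which(rs$time >= 0.15 & rs$time <= 0.45)
  tNeg <- rs$time[iNeg][which.min(rs$values[iNeg])]
  expect_lt(abs(tNeg - tpl@negLatency), 0.05)
  iPos <- which(rs$time >= 0.45 & rs$time <= 1)
  tPos <- rs$time[iPos][which.max(rs$values[iPos])]
  expect_lt(abs(tPos - tpl@posLatency), 0.05)
})

test_that("peak search respects its windows and tie-breaks", {
  tpl <- erpTemplate()
  pk <- findPeaks(templateWaveform(tpl))
  expect_equal(pk$negLatencyMs, 281.25, tolerance = 0.01)
  expect_equal(pk$negAmp, -1.35, tolerance = 0.01)
  expect_equal(pk$posLatency, 0.748, tolerance = 2 / 512)
  ramp <- seq(0, 1, length.out = 512)
  pr <- findPeaks(ramp)
  expect_equal(pr$negLatency, 103 / 512)    # first sample with t >= 0.2
  expect_equal(pr$posLatency, 511 / 512)
  flat <- findPeaks(rep(0, 512))
  expect_equal(flat$negAmp, 0)
  expect_equal(flat$negLatency, 103 / 512)  # earliest-index tie-break
  expect_equal(flat$posLatency, 180 / 512)
})

test_that("LOTOCV structure: folds, training sizes, test waveforms", {
  ds <- quickSubject(17, noiseSd = 1.5, nSequences = 6L, jitterCv = 0.2)
  perTrial <- 6L * 5L
  r5 <- lotocv(ds, 1:5, "candidates")
  expect_equal(nrow(r5$predictions), 15)
  expect_true(all(r5$predictions$nTrainEpochs == 14 * perTrial))
  expect_equal(r5$nTestWaveforms, 5)
  # candidates-only training shrinks with the candidate set: 3K-1 trials
  for (K in c(4, 3, 2)) {
    cand <- sort(sample(5, K))
    rk <- lotocv(ds, cand, "candidates")
    expect_equal(nrow(rk$predictions), 3 * K)          # folds: 3 per target
    expect_true(all(rk$predictions$nTrainEpochs == (3 * K - 1) * perTrial))
    ra <- lotocv(ds, cand, "all")
    expect_true(all(ra$predictions$nTrainEpochs == 14 * perTrial))
  }
})

test_that("reduced-command sweep enumerates subsets containing each truth", {
  ds <- quickSubject(18, noiseSd = 1.5, nSequences = 6L, jitterCv = 0.2)
  for (K in c(4, 3, 2)) {
    sw <- reducedCommandSweep(ds, K, "all")
    # per fold: C(4, K-1) subsets contain its target; 15 folds
    expect_equal(nrow(sw$decisions), 15 * choose(4, K - 1))
    expect_true(all(mapply(function(s, tr)
      tr %in% as.integer(strsplit(s, ",")[[1]]),
      sw$decisions$subset, sw$decisions$truth)))
  }
  # K = 5 sweep is plain LOTOCV
  sw5 <- reducedCommandSweep(ds, 5, "candidates")
  r5 <- lotocv(ds, 1:5, "candidates")
  expect_equal(sw5$accuracy, r5$accuracy)
})

test_that("noiseless subjects are decoded perfectly at every command count", {
  ds <- quickSubject(19, noiseSd = 0, nSequences = 6L, jitterCv = 0)
  expect_equal(lotocv(ds, 1:5)$accuracy, 1)
  for (K in c(4, 3, 2)) {
    expect_equal(reducedCommandSweep(ds, K, "candidates")$accuracy, 1)
    expect_equal(reducedCommandSweep(ds, K, "all")$accuracy, 1)
  }
})

test_that("learning curve at full training reproduces plain LOTOCV", {
  ds <- quickSubject(20, noiseSd = 2, nSequences = 6L, jitterCv = 0.2)
  lc <- learningCurve(ds, nTrainValues = 14, nRepeats = 1, commands = 5,
                      seed = 1)
  r5 <- lotocv(ds, 1:5, "all")
  expect_equal(lc$accuracy, r5$accuracy)
  # noiseless data: perfect for any training size
  ds0 <- quickSubject(21, noiseSd = 0, nSequences = 6L, jitterCv = 0)
  lc0 <- learningCurve(ds0, nTrainValues = c(1, 5, 14), nRepeats = 2,
                       commands = c(2, 5), seed = 2)
  expect_true(all(lc0$accuracy == 1))
})

test_that("a frozen model generalizes to matched new trials", {
  accCV <- accOn <- numeric(10)
  for (s in 1:10) {
    ds <- quickSubject(s + 400, noiseSd = 4.5, nSequences = 10L,
                       jitterCv = 0.3)
    model <- fitSubjectModel(ds)
    set.seed(s + 900)
    newTrials <- lapply(rep(c(1L, 3L, 5L), 2), function(tg) {
      sched <- buildTrialSchedule(tg, 10L, 0.3)
      rec <- simulateRecording(sched, ds@template,
                               noise = noiseModel(sd = 4.5))
      es <- preprocessRecording(rec)
      es@targetLabel <- tg
      es
    })
    sess <- onlineSession(model, newTrials, c(1, 3, 5))
    accOn[s] <- sess$accuracy
    accCV[s] <- reducedCommandSweep(ds, 3, "all")$accuracy
  }
  expect_lt(abs(mean(accOn) - mean(accCV)), 0.15)
})
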