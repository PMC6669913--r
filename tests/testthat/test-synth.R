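test_that("template waveform realizes the two-bump morphology", {
  # zero amplitudes -> flat
  z <- templateWaveform(erpTemplate(negAmp = 0, posAmp = 0))
  expect_equal(z, rep(0, 512))
  # isolated negative bump: minimum -1.35 uV at sample round(0.281*512)=144
  tn <- templateWaveform(erpTemplate(negAmp = -1.35, posAmp = 0))
  expect_equal(which.min(tn), 145)          # 1-based index of sample 144
  expect_equal(min(tn), -1.35, tolerance = 1e-4)
  tp <- templateWaveform(erpTemplate(posAmp = 1.88, negAmp = 0))
  expect_equal(which.max(tp), round(0.748 * 512) + 1)
  expect_equal(max(tp), 1.88, tolerance = 1e-4)
  # linearity in amplitudes
  t1 <- templateWaveform(erpTemplate())
  t2 <- templateWaveform(erpTemplate(negAmp = -2.70, posAmp = 3.76))
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
  expect_error(erpTemplate(negLatency = 0.5), "negLatency")
  expect_error(erpTemplate(posLatency = 0.2), "posLatency")
})

test_that("noiseless simulation reproduces the template in target epochs", {
  set.seed(11)
  sched <- fixedSlotSchedule(1L, nSequences = 10L, slot = 3L)
  tpl <- erpTemplate()
  rec <- simulateRecording(sched, tpl, noise = noiseModel(sd = 0),
                           epochJitterCv = 0, seed = 1)
  es <- extractEpochs(rec)      # raw extraction, no filtering
  tw <- templateWaveform(tpl)
  tgt <- epochMatrix(es)[epochTargets(es), , drop = FALSE]
  expect_equal(nrow(tgt), 10)
  for (i in seq_len(nrow(tgt)))
    expect_equal(as.numeric(tgt[i, ]), tw, tolerance = 1e-8)
})

test_that("average target minus non-target recovers the template shape", {
  # brute-force averaging oracle on a random noiseless schedule: the
  # difference of class averages is the template up to overlap bleed
  set.seed(12)
  sched <- buildTrialSchedule(2, 30, 0.3)
  tpl <- erpTemplate()
  rec <- simulateRecording(sched, tpl, noise = noiseModel(sd = 0),
                           epochJitterCv = 0)
  es <- extractEpochs(rec)
  avgT <- grandAverage(epochMatrix(es)[epochTargets(es), ])
  avgN <- grandAverage(epochMatrix(es)[!epochTargets(es), ])
  d <- avgT - avgN
  tw <- templateWaveform(tpl)
  expect_gt(cor(d, tw), 0.98)
  expect_equal(max(d), max(tw), tolerance = 0.4)
  expect_equal(min(d), min(tw), tolerance = 0.4)
})

test_that("simulation is deterministic given a seed", {
  sched <- buildTrialSchedule(1, 5, 0.3, seed = 3)
  r1 <- simulateRecording(sched, erpTemplate(), seed = 42)
  r2 <- simulateRecording(sched, erpTemplate(), seed = 42)
  expect_identical(samples(r1), samples(r2))
  r3 <- simulateRecording(sched, erpTemplate(), seed = 43)
  expect_false(identical(samples(r1), samples(r3)))
})

test_that("injected artifacts trip the screen exactly when out of range", {
  sched <- buildTrialSchedule(1, 5, 0.3, seed = 3)
  rec <- simulateRecording(sched, erpTemplate(), noise = noiseModel(sd = 0),
                           epochJitterCv = 0)
  expect_true(screenArtifacts(samples(rec))$pass)
  r50 <- injectArtifact(rec, 3.0, 50)
  expect_false(screenArtifacts(samples(r50))$pass)
  rm30 <- injectArtifact(rec, 3.0, -30)     # below -25 uV bound
  expect_false(screenArtifacts(samples(rm30))$pass)
  r10 <- injectArtifact(rec, 3.0, 10)
  expect_true(screenArtifacts(samples(r10))$pass)
})

test_that("default-noise recordings rarely violate the artifact screen", {
  set.seed(21)
  fails <- 0L
  for (i in 1:60) {
    sched <- buildTrialSchedule(sample(5, 1), 30, 0.3)
    rec <- simulateRecording(sched, erpTemplate(), noise = noiseModel())
    if (!screenArtifacts(samples(rec))$pass) fails <- fails + 1L
  }
  # per-trial failure probability < 1%: P(>3 of 60) ~ 3e-3 at p = 0.01
  expect_lte(fails, 3)
})

test_that("a simulated subject has the full offline structure", {
  ds <- quickSubject(5, noiseSd = 2, nSequences = 10L, jitterCv = 0.3)
  expect_s4_class(ds, "ERPDataset")
  expect_length(trials(ds), 15)
  tgts <- vapply(trials(ds), targetLabel, integer(1))
  expect_equal(as.vector(table(tgts)), rep(3L, 5))   # 3 runs x each sound once
  for (es in trials(ds)[1:3]) {
    expect_equal(nrow(epochMatrix(es)), 50)          # 10 sequences x 5
    expect_equal(sum(epochTargets(es)), 10)
    expect_equal(ncol(featureMatrix(es)), 16)
  }
  # subject identity = seed
  ds2 <- quickSubject(5, noiseSd = 2, nSequences = 10L, jitterCv = 0.3)
  expect_equal(featureMatrix(trials(ds)[[1]]),
               featureMatrix(trials(ds2)[[1]]))
})
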