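rms <- function(x) sqrt(mean(x^2))

test_that("notch filter suppresses 50 Hz and spares the passband", {
  rate <- 512
  t <- seq(0, 10, by = 1 / rate)
  mid <- seq(2 * rate, 8 * rate)     # avoid filter transients at the edges
  s50 <- sin(2 * pi * 50 * t)
  expect_lt(rms(notchFilter(s50, rate)[mid]), 0.1 * rms(s50[mid]))
  s10 <- sin(2 * pi * 10 * t)
  out10 <- notchFilter(s10, rate)
  expect_lt(abs(rms(out10[mid]) - rms(s10[mid])) / rms(s10[mid]), 0.11)
  expect_equal(notchFilter(rep(0, 1000), rate), rep(0, 1000))
  expect_error(notchFilter(s50, 80), "rate")
})

test_that("band-pass keeps 5 Hz, removes DC and 40 Hz", {
  rate <- 512
  t <- seq(0, 10, by = 1 / rate)
  mid <- seq(2 * rate, 8 * rate)
  dc <- rep(5, length(t))
  expect_lt(abs(mean(bandpassFilter(dc, rate)[mid])), 0.05)
  s5 <- sin(2 * pi * 5 * t)
  expect_lt(abs(rms(bandpassFilter(s5, rate)[mid]) - rms(s5[mid])) /
              rms(s5[mid]), 0.05)
  s40 <- sin(2 * pi * 40 * t)
  expect_lt(rms(bandpassFilter(s40, rate)[mid]), 0.05 * rms(s40[mid]))
  expect_error(bandpassFilter(s5, rate, low = 20, high = 10), "low")
})

test_that("epoch extraction baselines, counts and labels correctly", {
  sched <- buildTrialSchedule(1, 30, 0.3, seed = 8)
  rec <- simulateRecording(sched, erpTemplate(), noise = noiseModel(sd = 1),
                           epochJitterCv = 0, seed = 9)
  es <- extractEpochs(rec)
  expect_equal(nrow(epochMatrix(es)), 150)
  expect_equal(sum(epochTargets(es)), 30)
  expect_equal(epochLabels(es), scheduleEvents(sched)$label)
  # constant signal -> baseline removes everything
  flat <- rec; flat@samples <- rep(7.3, length(samples(rec)))
  esf <- extractEpochs(flat)
  expect_equal(max(abs(epochMatrix(esf))), 0)
  # truncated recording drops the final epoch with a warning
  short <- rec
  lastStart <- round((0.5 + 44.7) * 512) + 1   # 1-based start of final epoch
  short@samples <- samples(rec)[1:(lastStart + 502)]  # 10 samples short
  expect_warning(ess <- extractEpochs(short), "skipped")
  expect_equal(nrow(epochMatrix(ess)), 149)
})

test_that("block-average downsampling gives 16 features", {
  expect_equal(downsampleEpoch(rep(3.2, 512)), rep(3.2, 16))
  ramp <- downsampleEpoch(0:511)
  expect_equal(ramp, seq(15.5, 495.5, by = 32))   # block means of 0..511
  expect_length(ramp, 16)
  expect_error(downsampleEpoch(1:100), "divisible")
  expect_equal(downsampleEpoch(0:511, method = "decimate"),
               seq(0, 511, by = 32))
})

test_that("artifact screen is an exact threshold comparison", {
  x <- c(0, 39.9, -24.9, 5)
  expect_true(screenArtifacts(x)$pass)
  r <- screenArtifacts(c(0, 40.1, 0))
  expect_false(r$pass)
  expect_equal(r$violations, 2L)
  expect_false(screenArtifacts(c(-25.1))$pass)
})

test_that("grand averaging is the pointwise mean and commutes with downsampling", {
  sched <- buildTrialSchedule(2, 6, 0.3, seed = 10)
  rec <- simulateRecording(sched, erpTemplate(), noise = noiseModel(sd = 3),
                           seed = 11)
  es <- extractEpochs(rec)
  one <- epochMatrix(es)[1, , drop = FALSE]
  expect_equal(grandAverage(one), as.numeric(one))
  expect_equal(grandAverage(rbind(one, -one)), rep(0, 512))
  # linearity: downsample(mean) == mean(downsample)
  m <- epochMatrix(es)[epochTargets(es), ]
  expect_equal(downsampleEpoch(grandAverage(m)),
               colMeans(t(apply(m, 1, downsampleEpoch))),
               tolerance = 1e-12)
  expect_error(grandAverage(m[0, , drop = FALSE]), "no epochs")
})

test_that("feature k is the mean of its 32-sample block of the baselined epoch", {
  # direct recomputation pins the fixed pipeline order:
  # filter -> epoch+baseline -> block-mean downsample
  sched <- buildTrialSchedule(3, 6, 0.3, seed = 12)
  rec <- simulateRecording(sched, erpTemplate(), noise = noiseModel(sd = 3),
                           seed = 13)
  es <- preprocessRecording(rec)
  ep <- epochMatrix(es)[4, ]
  expect_equal(featureMatrix(es)[4, ],
               as.numeric(colMeans(matrix(ep, nrow = 32))))
})
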