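test_that("the omission template is tri-phasic with the published latencies", {
  cfg <- cleanConfig()
  w <- ospTemplate(cfg)
  t <- (seq_along(w) - 1) / samplingRate(cfg)
  at <- function(sec) w[which.min(abs(t - sec))]
  expect_gt(at(0.160), 0)
  expect_lt(at(0.210), 0)
  expect_gt(at(0.290), 0)
  ## P2 is the largest deflection and peaks within 5 ms of 290 ms
  expect_equal(max(abs(w)), max(w))
  expect_lt(abs(t[which.max(w)] - 0.290), 0.005)
  zero <- forwardModelConfig(ospAmplitude = c(0, 0, 0), seed = 1)
  expect_true(all(ospTemplate(zero) == 0))
  expect_error(forwardModelConfig(ospLatency = c(0.21, 0.16, 0.29)),
               "increasing")
})

test_that("simulated trials are deterministic under a fixed seed", {
  sched <- defaultParadigm("missing_white")
  cfg <- forwardModelConfig(seed = 42, noiseSd = 3)
  a <- simulateTrial(sched, 2, cfg)
  b <- simulateTrial(sched, 2, cfg)
  expect_identical(eegData(a), eegData(b))
  expect_identical(events(a), events(b))
})

test_that("the attended disc dominates the occipital spectrum", {
  sched <- defaultParadigm("missing_white")
  cfg <- cleanConfig(nonattendedGain = 0)
  for (disc in c(1, 2)) {
    rec <- simulateTrial(sched, disc, cfg)
    oz <- eegData(rec)["Oz" == channelLabels(rec), ][1:(2.5 * 1200)]
    sp <- Mod(stats::fft(oz))[2:150]
    fHz <- (2:150 - 1) / 2.5
    expect_lt(abs(fHz[which.max(sp)] - discFrequencies(sched)[disc]), 0.5)
  }
})

test_that("onset-locked averaging recovers the inserted omission response", {
  ## isolate the omission response: no SSVEP, no noise, sparse omissions so
  ## consecutive templates do not overlap
  spec <- flickerSpec(10, 4, missingPattern = "missing_white",
                      intervalFlickers = 8, firstOnset = 0.3)
  sched <- stimulusSchedule(list(spec, flickerSpec(12, 4, intervalFlickers = 8,
                                                   firstOnset = 0.5)))
  cfg <- cleanConfig(ssvepAmplitude = 0, nonattendedGain = 0)
  rec <- simulateTrial(sched, 1, cfg)
  es <- epochRecording(rec, missingOnsets(sched, 1), window = c(0, 0.5))
  avg <- averageEpochs(es, nEpochs(es))
  expected <- 1.25 * ospTemplate(cfg)          # missing_white pattern gain
  expect_equal(avg["Oz", ], expected, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(avg["Cz", ], 0.3 * expected, tolerance = 1e-6,
               ignore_attr = TRUE)             # topography gain
})

test_that("session protocols produce the published trial bookkeeping", {
  expect_equal(nTrials(trainingProtocol()), 448)   # 4 x 7 x 16
  expect_equal(nTrials(onlineProtocol()), 160)     # 10 x 16
  sched <- defaultParadigm("missing_black")
  tr <- simulateSession(trainingProtocol(nRuns = 1, nTrialsPerRun = 2),
                        sched, forwardModelConfig(seed = 5, noiseSd = 1))
  expect_equal(nTrials(tr), 8)
  expect_equal(trialLabels(tr), rep(1:4, each = 2))  # stratified by task
  on <- simulateSession(onlineProtocol(nRuns = 1, nTrialsPerRun = 8),
                        sched, forwardModelConfig(seed = 5, noiseSd = 1))
  expect_equal(tabulate(trialLabels(on), 4), rep(2, 4))  # balanced
  on2 <- simulateSession(onlineProtocol(nRuns = 1, nTrialsPerRun = 8),
                         sched, forwardModelConfig(seed = 5, noiseSd = 1))
  expect_identical(eegData(on@trials[[3]]), eegData(on2@trials[[3]]))
})

test_that("averaging K white-noise epochs shrinks the residual by sqrt(K)", {
  sched <- defaultParadigm("missing_black")
  cfg <- forwardModelConfig(seed = 13, noiseSd = 5, noiseColor = "white",
                            ssvepAmplitude = 0, ospAmplitude = c(0, 0, 0),
                            lineNoiseAmp = 0)
  rec <- simulateTrial(sched, 1, cfg)
  es <- epochRecording(rec, seq(0.1, 2.4, by = 0.4), window = c(0, 0.25))
  one <- stats::sd(epochArray(es)[1, , ])
  k4 <- stats::sd(averageEpochs(es, 4))
  expect_equal(k4 / one, 0.5, tolerance = 0.15)
})

test_that("the pink-noise generator follows a 1/f power spectrum", {
  sched <- defaultParadigm("missing_black")
  cfg <- forwardModelConfig(seed = 31, noiseSd = 2, ssvepAmplitude = 0,
                            ospAmplitude = c(0, 0, 0), lineNoiseAmp = 0)
  rec <- simulateTrial(sched, 1, cfg, tail = 7.5)   # 10 s of pure noise
  slopes <- vapply(1:4, function(ch) {
    x <- eegData(rec)[ch, ]
    sp <- Mod(stats::fft(x))^2
    fHz <- (seq_along(sp) - 1) / (length(x) / samplingRate(rec))
    keep <- fHz >= 1 & fHz <= 45
    unname(stats::coef(stats::lm(log10(sp[keep]) ~ log10(fHz[keep])))[2])
  }, numeric(1))
  expect_equal(mean(slopes), -1, tolerance = 0.3)
})

test_that("event tables survive the file round trip", {
  sched <- defaultParadigm("missing_white")
  rec <- simulateTrial(sched, 3, forwardModelConfig(seed = 3, noiseSd = 1))
  path <- file.path(tempdir(), "ev.csv")
  writeEvents(events(rec), path)
  back <- readEvents(path)
  expect_equal(back$time, events(rec)$time)
  expect_equal(back$disc, events(rec)$disc)
  expect_equal(back$kind, events(rec)$kind)
})
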