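test_that("frame sequences match a brute-force frame walker", {
  cases <- expand.grid(freq = c(10, 12), pattern = c("missing_white", "missing_black"),
                       interval = c(3, 5), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    spec <- flickerSpec(cs$freq, duration = 2.5, missingPattern = cs$pattern,
                        intervalFlickers = cs$interval, firstOnset = 27 / 60)
    got <- buildFlickerFrames(spec)
    exp <- oracleFlickerFrames(cs$freq, 60, 2.5, cs$pattern, cs$interval, 27 / 60)
    expect_identical(got$frames, exp$frames,
                     info = paste(cs$freq, cs$pattern, cs$interval))
    expect_equal(got$onsets, exp$onsets)
  }
})

test_that("missing-event period arithmetic at 12 Hz gives 250 and 417 ms", {
  on3 <- missingEventOnsets(flickerSpec(12, 2.5, intervalFlickers = 3))
  expect_equal(unique(round(1000 * diff(on3))), 250)
  on5 <- missingEventOnsets(flickerSpec(12, 5, intervalFlickers = 5))
  expect_equal(unique(round(1000 * diff(on5))), 417)
})

test_that("10 Hz spec with first onset 0.45 s yields 7 onsets at 0.45..2.25", {
  on <- missingEventOnsets(flickerSpec(10, 2.5, firstOnset = 0.45))
  expect_equal(on, seq(0.45, 2.25, by = 0.3))
  ## deterministic: same spec, same answer
  expect_identical(on, missingEventOnsets(flickerSpec(10, 2.5, firstOnset = 0.45)))
})

test_that("infinite interval degenerates to a pure square wave", {
  bf <- buildFlickerFrames(flickerSpec(10, 2, intervalFlickers = Inf))
  expect_length(bf$onsets, 0)
  expect_equal(sum(bf$frames), length(bf$frames) / 2)  # 3 white + 3 black
})

test_that("default paradigm reproduces the published onset layout", {
  for (pat in c("missing_white", "missing_black")) {
    sched <- defaultParadigm(pat)
    first <- vapply(1:4, function(d) missingOnsets(sched, d)[1], numeric(1))
    expect_equal(round(first, 3), c(0.467, 0.450, 0.633, 0.650))
    ## paired discs lag by two flicker periods of their shared frequency
    expect_lt(abs((first[3] - first[1]) * 1000 - 166), 1)
    expect_equal((first[4] - first[2]) * 1000, 200)
    expect_equal(discFrequencies(sched), c(12, 10, 12, 10))
    for (d in 1:4) {
      on <- missingOnsets(sched, d)
      expect_true(all(diff(on) > 0))
      ## spacing = intervalFlickers / frequency to frame resolution
      expect_true(all(abs(diff(on) -
                          3 * round(60 / discFrequencies(sched)[d]) / 60) < 1e-9))
    }
  }
})

test_that("white-frame bookkeeping distinguishes the omission patterns", {
  base <- buildFlickerFrames(flickerSpec(12, 2.5, intervalFlickers = Inf))
  mw <- buildFlickerFrames(flickerSpec(12, 2.5, missingPattern = "missing_white"))
  mb <- buildFlickerFrames(flickerSpec(12, 2.5, missingPattern = "missing_black"))
  expect_lt(sum(mw$frames), sum(base$frames))   # white phase held black
  expect_gt(sum(mb$frames), sum(base$frames))   # black phase held white
  ## non-omitted periods keep a constant white count (12 Hz: 3 of 5 frames)
  fpp <- 5
  onFrames <- round(mw$onsets * 60)
  periodStarts <- setdiff(seq(onFrames[1] %% fpp, 149, by = fpp), onFrames)
  periodStarts <- periodStarts[periodStarts + fpp <= 150]
  whites <- vapply(periodStarts, function(s) sum(mw$frames[(s + 1):(s + fpp)]),
                   numeric(1))
  expect_true(all(whites == 3))
})

test_that("infeasible specs are rejected with quantization errors", {
  expect_error(buildFlickerFrames(flickerSpec(35, 2.5)), "refresh")  # < 2 frames
  expect_error(buildFlickerFrames(flickerSpec(11, 2.5)), "quantization")
  expect_error(flickerSpec(10, 2.5, firstOnset = 3))                 # past end
  expect_error(flickerSpec(10, 2.5, intervalFlickers = 2.5), "integer")
})

test_that("schedules round-trip through CSV + JSON export", {
  sched <- defaultParadigm("missing_black")
  path <- file.path(tempdir(), "sched.csv")
  writeSchedule(sched, path)
  back <- readSchedule(path)
  expect_identical(frameSequence(back), frameSequence(sched))
  expect_equal(missingOnsets(back), missingOnsets(sched))
  expect_equal(discFrequencies(back), discFrequencies(sched))
  expect_identical(back@missingPattern, sched@missingPattern)
})
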