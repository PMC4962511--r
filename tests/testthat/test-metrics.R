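test_that("the ITR formula reproduces the published worked examples", {
  expect_equal(itr(4, 0.9625, 3.0), 34.20, tolerance = 0.01 / 34.20)
  expect_equal(itr(4, 0.9969, 3.0), 39.30, tolerance = 0.01 / 39.30)
  expect_equal(itr(4, 0.9018, 3.5), 23.68, tolerance = 0.01 / 23.68)
  expect_equal(itr(4, 0.8812, 3.5), 22.04, tolerance = 0.01 / 22.04)
  expect_equal(itr(4, 1.0, 3.0), 40)           # 60/3 * log2(4)
  expect_equal(itr(4, 0.25, 3.0), 0)           # chance level
  expect_equal(itr(4, 0.25, 0.7), 0)
  expect_error(itr(4, 1.2, 3), "acc")
  expect_error(itr(1, 0.5, 3), "N")
})

test_that("ITR is increasing in accuracy above chance and scales as 1/DTI", {
  accs <- seq(0.26, 1, by = 0.02)
  vals <- vapply(accs, function(a) itr(4, a, 3), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(itr(4, 0.9, 1.5), 2 * itr(4, 0.9, 3.0))
  for (N in c(2, 4, 8)) expect_equal(itr(N, 1 / N, 2), 0)
})

test_that("per-subject ITRs regenerate from the published accuracies", {
  pub <- publishedResults()
  chk <- table1Check(pub$accuracy_pct, pub$averaging_times)
  ## every printed cell regenerates to within rounding of the source table
  expect_lt(max(abs(chk$itr - pub$itr_bits_min)), 0.02)
  ## column statistics per omission pattern
  black <- pub$pattern == "black"
  cb <- table1Check(pub$accuracy_pct[black], pub$averaging_times[black])
  cw <- table1Check(pub$accuracy_pct[!black], pub$averaging_times[!black])
  expect_equal(round(cb$meanAcc, 2), 79.29)
  expect_equal(round(cw$meanAcc, 2), 86.92)
  ## regenerated ITR means carry the printed cells' rounding
  expect_lt(abs(cb$meanItr - 19.45), 0.02)
  expect_lt(abs(cw$meanItr - 24.06), 0.02)
  expect_equal(round(cb$sdAcc, 2), 18.14)
  expect_equal(round(cb$sdItr, 2), 11.99)
  expect_error(table1Check(c(90, 80), c(4, 12)), "averaging")
})

test_that("session evaluation recounts decisions correctly", {
  set.seed(20)
  truth <- sample(1:4, 60, replace = TRUE)
  decided <- truth
  flip <- sample(60, 15)
  decided[flip] <- (truth[flip] %% 4) + 1
  res <- evaluateSession(decided, truth, N = 4, dti = 3, nAvg = 4)
  expect_equal(accuracy(res), 45 / 60)
  expect_equal(itrBitsPerMin(res), itr(4, 0.75, 3))
  expect_equal(nrow(res@trials), 60)
  expect_equal(evaluateSession(rep(1, 4), c(1, 1, 2, 2))@acc, 0.5)
  expect_error(evaluateSession(integer(0), integer(0)), "no decisions")
  expect_error(evaluateSession(1:3, 1:4), "equal length")
})

test_that("the two-stage decision is exact on noise-free trials", {
  model <- fixtureModel()
  sched <- fixtureSchedule()
  for (disc in c(1, 3, 4)) {
    rec <- bandpass(simulateTrial(sched, disc, cleanConfig(seed = 40 + disc)))
    d <- quietly(decideTarget(rec, sched, model, nAvg = 4))
    expect_equal(d$disc, disc)
    expect_equal(d$frequency, discFrequencies(sched)[disc])
  }
})

test_that("a noise-free online session decodes at 100 % accuracy", {
  model <- fixtureModel()
  sched <- fixtureSchedule()
  on <- simulateSession(onlineProtocol(nRuns = 1, nTrialsPerRun = 8),
                        sched, cleanConfig(seed = 55))
  res <- quietly(decodeSession(on, model, nAvg = 4))
  expect_equal(accuracy(res), 1)
  expect_equal(itrBitsPerMin(res), itr(4, 1, 3.0))
  ## recount oracle: summary accuracy equals the per-trial hand count
  expect_equal(accuracy(res),
               mean(res@trials$decided == res@trials$truth))
})

test_that("the averaging sweep maximizes ITR and breaks ties toward small n", {
  model <- fixtureModel()
  sched <- fixtureSchedule()
  on <- simulateSession(onlineProtocol(nRuns = 1, nTrialsPerRun = 4),
                        sched, cleanConfig(seed = 60))
  sw <- quietly(averagingSweep(on, model, avgSet = c(2, 4)))
  ## noise-free: accuracy 1 everywhere, so the shortest DTI wins
  expect_equal(sw$nAvg, 2)
  expect_equal(itrBitsPerMin(sw$best), itr(4, 1, defaultDtiMap()[["2"]]))
  expect_true(all(itrBitsPerMin(sw$best) >= sw$sweep$itr))
  ## constant DTI and constant accuracy: smallest averaging count wins
  swTie <- quietly(averagingSweep(on, model, avgSet = c(2, 4),
                                  dtiMap = c(`2` = 3, `4` = 3)))
  expect_equal(swTie$nAvg, 2)
})

test_that("decoding accuracy improves with the averaging count under noise", {
  model <- fixtureModel()
  sched <- fixtureSchedule()
  on <- simulateSession(onlineProtocol(nRuns = 1, nTrialsPerRun = 32),
                        sched, forwardModelConfig(seed = 321, noiseSd = 25))
  acc <- vapply(c(2, 6), function(na)
    accuracy(quietly(decodeSession(on, model, nAvg = na))), numeric(1))
  expect_gt(acc[1], 0.25)                       # above 4-class chance
  expect_gte(acc[2], acc[1])
})
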