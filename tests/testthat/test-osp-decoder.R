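test_that("the window grid slices epochs into ten 25 ms x 30-sample windows", {
  g <- windowGrid(1200)
  expect_length(g@starts, 10)
  expect_equal(g@starts[1], 0.125)
  expect_equal(g@ends[10], 0.375)
  expect_equal(g@samplesPerWindow, 30L)
  expect_equal(windowGrid(1000)@samplesPerWindow, 25L)
  expect_error(windowGrid(1111), "integer")     # 27.775 samples per window
})

test_that("feature extraction yields 10 x 30 vectors per electrode", {
  g <- windowGrid(1200)
  cfg <- cleanConfig()
  tmpl <- ospTemplate(cfg)
  avg <- rbind(Oz = tmpl[1:450], O1 = 0)        # epoch window [0, 0.375)
  f <- extractFeatures(avg, c(0, 0.375), g)
  expect_equal(dim(f), c(2, 300))
  expect_true(all(f["O1", ] == 0))
  ## the window containing the 290 ms peak carries the most energy
  winMeans <- vapply(1:10, function(k)
    mean(abs(f["Oz", ((k - 1) * 30 + 1):(k * 30)])), numeric(1))
  expect_equal(which.max(winMeans), 7)          # [275, 300) ms
  expect_error(extractFeatures(avg, c(0, 0.2), g), "too short")
  expect_error(extractFeatures(avg, c(0, 0.375), g, electrodes = "PO8"),
               "absent")
})

test_that("the SVM bank separates a separable toy set and not permuted labels", {
  g <- windowGrid(1200)
  set.seed(10)
  n <- 200
  X <- matrix(rnorm(n * 300), n, 300)
  y <- rep(0:1, each = n / 2)
  X[y == 1, ] <- X[y == 1, ] + 3                # widely separated classes
  bank <- trainSvmBank(X, y, g, foldSeed = 2)
  d <- vapply(1:10, function(k)
    mean(svmDecide(bank, k, X[, ((k - 1) * 30 + 1):(k * 30)]) == y),
    numeric(1))
  expect_true(all(d == 1))                      # training accuracy 100 %

  yPerm <- sample(y)
  bankP <- trainSvmBank(X, yPerm, g, foldSeed = 2)
  ## chance-level CV accuracy (selected-C values carry a slight upward
  ## selection bias, hence the wider per-window band)
  expect_lt(abs(mean(bankP@cvAccuracy) - 0.5), 0.1)
  expect_true(all(abs(bankP@cvAccuracy - 0.5) < 0.15))

  expect_error(trainSvmBank(X, rep(1, n), g), "both classes")
  few <- c(1:8, (n / 2 + 1):(n / 2 + 8))        # both classes, too few
  expect_error(trainSvmBank(X[few, ], y[few], g), "at least 20")
})

test_that("duplicating the training set leaves the decision function unchanged", {
  g <- windowGrid(1200)
  set.seed(11)
  n <- 60
  X <- matrix(rnorm(n * 300), n, 300)
  y <- rep(0:1, n / 2)
  X[y == 1, ] <- X[y == 1, ] + 1
  b1 <- trainSvmBank(X, y, g, foldSeed = 3)
  b2 <- trainSvmBank(rbind(X, X), c(y, y), g, foldSeed = 3)
  for (k in c(1, 5, 10)) {
    sl <- X[, ((k - 1) * 30 + 1):(k * 30)]
    expect_equal(svmDecide(b1, k, sl), svmDecide(b2, k, sl))
  }
})

test_that("svmDecide implements the signed linear rule with zero mapped to 0", {
  g <- windowGrid(1200)
  W <- matrix(0, 10, 30); W[, 1] <- 1           # w = e1 for every window
  bank <- methods::new("SvmBank", weights = W, bias = rep(0, 10),
                       cost = rep(1, 10), cvAccuracy = rep(NA_real_, 10),
                       grid = g, fits = list())
  x <- c(1, rep(0, 29))
  expect_equal(svmDecide(bank, 1, x), 1L)
  expect_equal(svmDecide(bank, 1, -x), 0L)      # mirrored sample
  expect_equal(svmDecide(bank, 1, rep(0, 30)), 0L)  # exact zero -> class 0
  expect_error(svmDecide(bank, 1, rep(0, 29)), "expects 30")
})

test_that("extracted weights agree with the support-vector decision sum", {
  g <- windowGrid(1200)
  set.seed(12)
  n <- 80
  X <- matrix(rnorm(n * 300), n, 300)
  y <- rep(0:1, n / 2)
  X[y == 1, ] <- X[y == 1, ] + 0.8
  bank <- trainSvmBank(X, y, g, foldSeed = 5)
  for (k in c(2, 7)) {
    fit <- bank@fits[[k]]
    sl <- X[, ((k - 1) * 30 + 1):(k * 30)]
    ## brute-force decision sum over stored support vectors
    dv <- drop(sl %*% t(fit$SV) %*% fit$coefs) - fit$rho
    mine <- drop(sl %*% bank@weights[k, ]) + bank@bias[k]
    expect_equal(abs(mine), abs(dv), tolerance = 1e-8)   # up to orientation
    expect_equal(svmDecide(bank, k, sl),
                 as.integer((sign(dv) * sign(sum(dv * mine))) > 0))
  }
})

test_that("the fusion table applies Laplace smoothing and normalizes", {
  set.seed(13)
  n <- 98
  labels <- rep(0:1, each = n)
  perfect <- matrix(rep(labels, 10), ncol = 10)
  tab <- fitBayesTable(perfect, labels)
  expect_equal(unname(tab@p[, "1", "1"]), rep(99 / 100, 10))
  expect_equal(unname(tab@p[, "1", "0"]), rep(1 / 100, 10))
  expect_equal(tab@p[, "0", ] + tab@p[, "1", ],
               matrix(1, 10, 2), ignore_attr = TRUE)

  indep <- matrix(rbinom(2 * n * 10, 1, 0.5), ncol = 10)
  tabI <- fitBayesTable(indep, labels)
  expect_lt(max(abs(tabI@p[, "1", "1"] - tabI@p[, "1", "0"])), 0.2)
  expect_error(fitBayesTable(perfect, rep(1, 2 * n)), "both classes")
})

test_that("fusion equals the brute-force likelihood ratio", {
  ## uninformative table: ratio cancels for every decision vector
  pU <- array(0.5, dim = c(10, 2, 2),
              dimnames = list(NULL, d = c("0", "1"), c = c("0", "1")))
  tabU <- methods::new("BayesTable", p = pU)
  for (d in list(rep(0, 10), rep(1, 10), rep(c(0, 1), 5)))
    expect_equal(fusionScore(d, tabU), 1)

  ## worked example: all detectors fire, p11/p10 = 1.8 per window
  pW <- pU
  pW[, "1", "1"] <- 0.9; pW[, "0", "1"] <- 0.1
  pW[, "1", "0"] <- 0.5; pW[, "0", "0"] <- 0.5
  tabW <- methods::new("BayesTable", p = pW)
  expect_equal(fusionScore(rep(1, 10), tabW), 1.8^10, tolerance = 1e-10)

  ## exhaustive enumeration over all 1024 decision vectors
  tab <- randomBayesTable(14)
  D <- allBinaryVectors(10)
  for (i in seq_len(nrow(D)))
    expect_equal(fusionScore(D[i, ], tab), oracleFusion(D[i, ], tab@p),
                 tolerance = 1e-10)
})

test_that("fusion is monotone in informative window decisions", {
  tab <- randomBayesTable(15)
  lr1 <- tab@p[, "1", "1"] / tab@p[, "1", "0"]
  lr0 <- tab@p[, "0", "1"] / tab@p[, "0", "0"]
  d <- rep(0, 10)
  for (k in which(lr1 > lr0)) {
    d1 <- d; d1[k] <- 1
    expect_gt(fusionScore(d1, tab), fusionScore(d, tab))
  }
})

test_that("onset-candidate classification picks the attended disc", {
  model <- fixtureModel()
  sched <- fixtureSchedule()
  rec <- bandpass(simulateTrial(sched, 2, cleanConfig(seed = 77)))
  cands <- list(`2` = missingOnsets(sched, 2), `4` = missingOnsets(sched, 4))
  res <- classifyOnsetCandidates(rec, cands, nAvg = 4, model)
  expect_equal(res$selected, 1L)                 # first candidate = disc 2
  swapped <- classifyOnsetCandidates(rec, rev(cands), nAvg = 4, model)
  expect_equal(swapped$selected, 2L)             # decision follows the disc
  expect_equal(sort(res$logScores), sort(swapped$logScores))
  expect_error(classifyOnsetCandidates(rec, cands["2"], 4, model), "two")
  expect_error(classifyOnsetCandidates(rec, cands, nAvg = 50, model),
               "supports only")
})
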