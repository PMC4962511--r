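## Shared fixtures. Everything is generated in code; the trained decoder is
## built once per test run and reused.

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

## A noise-free config: pure deterministic forward model (no notch applied
## since there is no line component to remove).
cleanConfig <- function(seed = 1L, ...) {
  forwardModelConfig(seed = seed, noiseSd = 0, lineNoiseAmp = 0, ...)
}

## small but realistic training session + decoder, shared across files
.fixtureCache <- new.env(parent = emptyenv())

fixtureModel <- function() {
  if (is.null(.fixtureCache$model)) {
    sched <- defaultParadigm("missing_black")
    tr <- simulateSession(trainingProtocol(nRuns = 1, nTrialsPerRun = 6),
                          sched, forwardModelConfig(seed = 101, noiseSd = 2))
    .fixtureCache$model <- trainDecoder(tr, nAvg = 4, foldSeed = 7)
    .fixtureCache$schedule <- sched
  }
  .fixtureCache$model
}

fixtureSchedule <- function() {
  fixtureModel()
  .fixtureCache$schedule
}

## independent brute-force frame walker: builds the flicker sequence frame
## by frame, tracking period position from the anchor, omitting every
## intervalFlickers-th period starting at the first onset
oracleFlickerFrames <- function(freq, refresh, duration, pattern,
                                interval, firstOnset, omPeriods = 1) {
  fpp <- round(refresh / freq)
  nWhite <- ceiling(fpp / 2)
  nFrames <- round(duration * refresh)
  onsetFrame <- round(firstOnset * refresh)
  frames <- integer(nFrames)
  onsets <- numeric(0)
  for (f in 0:(nFrames - 1)) {
    rel <- f - onsetFrame
    posInPeriod <- ((rel %% fpp) + fpp) %% fpp
    periodIdx <- floor(rel / fpp)
    omitted <- is.finite(interval) && periodIdx >= 0 &&
      (periodIdx %% interval) < omPeriods &&
      (periodIdx - periodIdx %% interval) * fpp + onsetFrame +
        omPeriods * fpp <= nFrames
    frames[f + 1] <- if (omitted) {
      if (pattern == "missing_white") 0L else 1L
    } else as.integer(posInPeriod < nWhite)
    if (omitted && posInPeriod == 0 && periodIdx %% interval == 0)
      onsets <- c(onsets, f / refresh)
  }
  list(frames = frames, onsets = onsets)
}

## direct covariance-eigen canonical-correlation oracle
oracleCCA <- function(X, Y) {
  Xc <- scale(t(X), center = TRUE, scale = FALSE)
  Yc <- scale(t(Y), center = TRUE, scale = FALSE)
  Cxx <- crossprod(Xc); Cyy <- crossprod(Yc); Cxy <- crossprod(Xc, Yc)
  M <- solve(Cxx, Cxy) %*% solve(Cyy, t(Cxy))
  sqrt(max(0, max(Re(eigen(M, only.values = TRUE)$values))))
}

## brute-force Bayes likelihood-ratio over the ten factors
oracleFusion <- function(d, p) {
  d <- unname(d)
  num <- den <- 1
  for (k in seq_along(d)) {
    num <- num * p[k, "0", "1"]^(1 - d[k]) * p[k, "1", "1"]^d[k]
    den <- den * p[k, "0", "0"]^(1 - d[k]) * p[k, "1", "0"]^d[k]
  }
  num / den
}

## random smoothed-probability fusion table
randomBayesTable <- function(seed, nW = 10) {
  set.seed(seed)
  p <- array(0, dim = c(nW, 2, 2),
             dimnames = list(NULL, d = c("0", "1"), c = c("0", "1")))
  p1 <- matrix(runif(nW * 2, 0.05, 0.95), nW, 2)
  p[, "1", ] <- p1
  p[, "0", ] <- 1 - p1
  methods::new("BayesTable", p = p)
}

## all 2^n binary vectors as rows
allBinaryVectors <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))
}
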