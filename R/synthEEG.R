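## Forward-model EEG simulator for the flicker-with-omissions paradigm.
##
## Signal model per channel ch and time t (microvolts):
##   x_ch(t) = g_ch * sum_d a_d * [ SSVEP_d(t) + OSP_d(t) ] + noise_ch(t)
## where a_d is 1 for the fixated disc and nonattendedGain otherwise,
## SSVEP_d is a harmonically weighted sinusoid at disc d's flicker rate
## gated off during its omitted periods, and OSP_d places the tri-phasic
## omission template at each of disc d's missing-event onsets. Noise is
## 1/f ("pink") or white, plus 50 Hz line interference which is then
## notch-filtered (48-52 Hz), emulating the acquisition chain.

#' Construct a ForwardModelConfig
#'
#' Defaults emulate a posterior-dominant response: unit gain on the six
#' decodable electrodes (O1, Oz, O2, POz, PO4, PO8), 0.3 elsewhere; SSVEP
#' fundamental 4 uV with a 0.4-weight second harmonic; omission response
#' built from three Gaussian-windowed deflections (+1.0, -1.5, +2.0 uV;
#' widths 20/25/30 ms) at 160, 210 and 290 ms — the last (P2) largest.
#' Omissions of the white phase yield a 1.25-fold larger response than
#' omissions of the black phase.
#'
#' @param fs sampling rate, Hz.
#' @param ssvepAmplitude fundamental SSVEP amplitude, uV.
#' @param harmonicWeights relative amplitude per harmonic.
#' @param ospLatency,ospWidth,ospAmplitude P1/N2/P2 Gaussian parameters
#'   (seconds, seconds, uV).
#' @param channelLabels,channelGain electrode montage and topography.
#' @param nonattendedGain response gain of non-fixated discs, in [0, 1].
#' @param patternGainWhite OSP multiplier under `missing_white`.
#' @param noiseSd per-channel noise SD, uV.
#' @param noiseColor `"pink"` or `"white"`.
#' @param lineNoiseAmp 50 Hz interference amplitude, uV.
#' @param seed integer seed.
#' @return A validated [ForwardModelConfig-class].
#' @export
forwardModelConfig <- function(fs = 1200, ssvepAmplitude = 4,
                               harmonicWeights = c(1, 0.4),
                               ospLatency = c(0.160, 0.210, 0.290),
                               ospWidth = c(0.020, 0.025, 0.030),
                               ospAmplitude = c(1.0, -1.5, 2.0),
                               channelLabels = .DEFAULT_CHANNELS,
                               channelGain = NULL,
                               nonattendedGain = 0.1,
                               patternGainWhite = 1.25,
                               noiseSd = 2, noiseColor = c("pink", "white"),
                               lineNoiseAmp = 1, seed = 1L) {
  noiseColor <- match.arg(noiseColor)
  if (is.null(channelGain)) {
    channelGain <- ifelse(channelLabels %in% .OSP_ELECTRODES, 1.0, 0.3)
    names(channelGain) <- channelLabels
  }
  methods::new("ForwardModelConfig", channelLabels = channelLabels, fs = fs,
               ssvepAmplitude = ssvepAmplitude,
               harmonicWeights = harmonicWeights, ospLatency = ospLatency,
               ospWidth = ospWidth, ospAmplitude = ospAmplitude,
               channelGain = unname(channelGain),
               nonattendedGain = nonattendedGain,
               patternGainWhite = patternGainWhite, noiseSd = noiseSd,
               noiseColor = noiseColor, lineNoiseAmp = lineNoiseAmp,
               seed = as.integer(seed))
}

#' The tri-phasic omitted-stimulus response template
#'
#' Sum of three Gaussian-windowed deflections — positive P1, negative N2 and
#' the largest positive P2 — evaluated on [0, 0.5) s after the omission
#' onset.
#'
#' @param config a [ForwardModelConfig-class].
#' @return numeric vector of `0.5 * fs` samples (uV).
#' @examples
#' w <- ospTemplate(forwardModelConfig())
#' which.max(w) / 1200  # ~0.29 s
#' @export
ospTemplate <- function(config) {
  methods::validObject(config)
  t <- seq(0, 0.5 - 1 / config@fs, by = 1 / config@fs)
  w <- numeric(length(t))
  for (i in 1:3)
    w <- w + config@ospAmplitude[i] *
      exp(-(t - config@ospLatency[i])^2 / (2 * config@ospWidth[i]^2))
  w
}

#' 1/f ("pink") noise by spectral shaping
#'
#' White Gaussian spectrum scaled by 1/sqrt(f) (power ~ 1/f), inverse
#' transformed and rescaled to the requested standard deviation.
#'
#' @param n samples.
#' @param sd target standard deviation.
#' @return numeric vector of length `n`.
#' @keywords internal
pinkNoise <- function(n, sd = 1) {
  if (sd == 0) return(numeric(n))
  m <- n %/% 2
  f <- seq_len(m)                       # positive frequency bins
  amp <- 1 / sqrt(f)
  spec <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) * amp
  full <- complex(length.out = n)
  full[2:(m + 1)] <- spec
  full[n:(n - m + 2)] <- Conj(spec[seq_len(m - 1)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

## 48-52 Hz zero-phase notch used to emulate the acquisition chain.
.notch5050 <- function(x, fs) {
  bf <- signal::butter(2, c(48, 52) / (fs / 2), type = "stop")
  signal::filtfilt(bf, x)
}

## omitted windows (start, end) in seconds for one disc of a schedule
.omissionWindows <- function(schedule, disc) {
  sp <- schedule@specs[[disc]]
  fpp <- framesPerPeriod(sp)
  omDur <- sp@omissionPeriods * fpp / sp@refresh
  on <- schedule@onsets[[disc]]
  cbind(start = on, end = on + omDur)
}

#' Simulate one stimulation trial
#'
#' Produces an event-annotated recording covering the stimulation window
#' plus a short post-stimulation tail (so that epochs locked to the last
#' omission onsets remain fully inside the recording).
#'
#' @param schedule a [StimulusSchedule-class].
#' @param attendedDisc fixated disc, 1-based index into the schedule.
#' @param config a [ForwardModelConfig-class]; its `seed` makes the trial
#'   reproducible.
#' @param tail post-stimulation seconds appended (noise only; default 0.5,
#'   the inter-trial dark interval).
#' @return An [EEGRecording-class] whose events carry `stim_on`, every
#'   disc's `missing_event` onsets, and `stim_off`.
#' @export
simulateTrial <- function(schedule, attendedDisc, config, tail = 0.5) {
  methods::validObject(config)
  nDisc <- ncol(schedule@frames)
  if (!attendedDisc %in% seq_len(nDisc))
    stop("attendedDisc must index a disc of the schedule")
  fs <- config@fs
  if (abs(fs %% schedule@refresh) > 1e-9 && abs(fs / schedule@refresh -
      round(fs / schedule@refresh)) > 1e-6)
    stop("sampling rate must be an integer multiple of the display refresh")
  n <- round((schedule@duration + tail) * fs)
  t <- (seq_len(n) - 1) / fs
  stimOn <- t < schedule@duration

  patGain <- if (schedule@missingPattern == "missing_white")
    config@patternGainWhite else 1
  template <- ospTemplate(config)

  source <- numeric(n)
  for (d in seq_len(nDisc)) {
    g <- if (d == attendedDisc) 1 else config@nonattendedGain
    if (g == 0) next
    ## SSVEP with harmonics, gated off outside stimulation and in omissions
    ss <- numeric(n)
    for (h in seq_along(config@harmonicWeights))
      ss <- ss + config@harmonicWeights[h] *
        sin(2 * pi * h * schedule@frequencies[d] * t)
    ss <- ss * config@ssvepAmplitude
    gate <- stimOn
    wins <- .omissionWindows(schedule, d)
    for (i in seq_len(nrow(wins)))
      gate <- gate & !(t >= wins[i, 1] & t < wins[i, 2])
    ss[!gate] <- 0
    ## OSP at each omission onset
    osp <- numeric(n)
    for (on in schedule@onsets[[d]]) {
      i0 <- round(on * fs) + 1L
      idx <- i0:min(n, i0 + length(template) - 1L)
      osp[idx] <- osp[idx] + patGain * template[seq_along(idx)]
    }
    source <- source + g * (ss + osp)
  }

  set.seed(config@seed)
  nCh <- length(config@channelLabels)
  data <- matrix(0, nCh, n)
  for (ch in seq_len(nCh)) {
    noise <- if (config@noiseSd == 0) numeric(n)
      else if (config@noiseColor == "pink") pinkNoise(n, config@noiseSd)
      else stats::rnorm(n, sd = config@noiseSd)
    line <- if (config@lineNoiseAmp > 0)
      config@lineNoiseAmp * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
      else 0
    data[ch, ] <- config@channelGain[ch] * source + noise + line
  }
  if (config@lineNoiseAmp > 0)
    for (ch in seq_len(nCh)) data[ch, ] <- .notch5050(data[ch, ], fs)

  ev <- data.frame(time = 0, disc = NA_integer_, kind = "stim_on")
  for (d in seq_len(nDisc))
    if (length(schedule@onsets[[d]]))
      ev <- rbind(ev, data.frame(time = schedule@onsets[[d]], disc = d,
                                 kind = "missing_event"))
  ev <- rbind(ev, data.frame(time = schedule@duration, disc = NA_integer_,
                             kind = "stim_off"))
  ev <- ev[order(ev$time, ev$disc, method = "radix"), ]
  rownames(ev) <- NULL

  methods::new("EEGRecording", data = data, fs = fs,
               channelLabels = config@channelLabels, events = ev)
}

#' Session protocols
#'
#' `trainingProtocol()` defaults to 4 fixation tasks x 7 runs x 16 trials
#' (448 trials, 112 per disc); `onlineProtocol()` to 10 runs x 16 trials
#' (160 trials). Trial timing: dark 2 s, cue 0.5 s, stimulation 2.5 s,
#' inter-trial 0.5 s.
#'
#' @param nRuns runs per task (training) or runs (online).
#' @param nTrialsPerRun trials per run.
#' @param nTasks fixation tasks (training only; one per disc).
#' @return A [SessionProtocol-class].
#' @export
trainingProtocol <- function(nRuns = 7, nTrialsPerRun = 16, nTasks = 4) {
  methods::new("SessionProtocol", phase = "training",
               nTasks = as.integer(nTasks), nRuns = as.integer(nRuns),
               nTrialsPerRun = as.integer(nTrialsPerRun),
               timing = c(dark = 2, cue = 0.5, stim = 2.5, iti = 0.5))
}

#' @rdname trainingProtocol
#' @export
onlineProtocol <- function(nRuns = 10, nTrialsPerRun = 16) {
  methods::new("SessionProtocol", phase = "online", nTasks = 1L,
               nRuns = as.integer(nRuns),
               nTrialsPerRun = as.integer(nTrialsPerRun),
               timing = c(dark = 2, cue = 0.5, stim = 2.5, iti = 0.5))
}

## deterministic per-trial seed derivation (kept below 2^31)
.trialSeed <- function(masterSeed, trial) {
  as.integer((as.double(masterSeed) + 104729 * as.double(trial)) %% 2147483647)
}

#' Simulate a full labeled session
#'
#' Training sessions fixate disc 1..nTasks in task order (labels are
#' stratified: nRuns x nTrialsPerRun trials per disc); online sessions draw
#' a balanced random label sequence under the master seed. Each trial gets
#' its own seed derived deterministically from `config@seed`, so sessions
#' are reproducible end to end.
#'
#' @param protocol a [SessionProtocol-class].
#' @param schedule a [StimulusSchedule-class] shared by all trials.
#' @param config a [ForwardModelConfig-class]; `config@seed` is the master
#'   seed.
#' @return An [EEGSession-class].
#' @export
simulateSession <- function(protocol, schedule, config) {
  methods::validObject(protocol)
  nd <- ncol(schedule@frames)
  if (protocol@phase == "training") {
    labels <- rep(seq_len(protocol@nTasks),
                  each = protocol@nRuns * protocol@nTrialsPerRun)
  } else {
    n <- protocol@nRuns * protocol@nTrialsPerRun
    set.seed(config@seed)
    labels <- sample(rep(seq_len(nd), length.out = n))
  }
  trials <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    cfg <- config
    cfg@seed <- .trialSeed(config@seed, i)
    trials[[i]] <- simulateTrial(schedule, labels[i], cfg,
                                 tail = protocol@timing[["iti"]])
  }
  methods::new("EEGSession", trials = trials, labels = as.integer(labels),
               protocol = protocol, schedule = schedule)
}
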