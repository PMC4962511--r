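## Central S4 containers. Validity methods enforce the structural contracts;
## everything downstream may assume them.

.MISSING_PATTERNS <- c("missing_white", "missing_black")

.DEFAULT_CHANNELS <- c("O1", "O2", "Oz", "PO3", "POz", "PO4", "PO7", "PO8",
                       "Pz", "Cz")

## Electrodes carrying the decodable occipital response; used by both the
## frequency (CCA) and omission-onset (SVM/Bayes) stages.
.OSP_ELECTRODES <- c("O1", "Oz", "O2", "POz", "PO4", "PO8")

#' FlickerSpec: one disc's flicker train with periodic omissions
#'
#' Describes a square-wave luminance train rendered on a fixed-refresh
#' display, in which every `intervalFlickers`-th flicker period starting at
#' `firstOnset` is omitted (held at constant luminance). With
#' `missing_white` the would-be white phase is held black (the disc
#' disappears against a black background); with `missing_black` it is held
#' white (the disc pauses).
#'
#' @slot frequency flicker rate in Hz.
#' @slot refresh display refresh rate in Hz (default 60).
#' @slot duration stimulation length in seconds.
#' @slot missingPattern `"missing_white"` or `"missing_black"`.
#' @slot intervalFlickers flicker periods per omission cycle (3 = two
#'   flickers then one omission); `Inf` disables omissions.
#' @slot firstOnset time of the first omitted period, seconds from
#'   stimulation start.
#' @slot omissionPeriods duration of each omission in flicker periods
#'   (default 1, i.e. 1/frequency seconds).
#' @export
setClass("FlickerSpec",
  representation(frequency = "numeric", refresh = "numeric",
                 duration = "numeric", missingPattern = "character",
                 intervalFlickers = "numeric", firstOnset = "numeric",
                 omissionPeriods = "numeric"),
  prototype(refresh = 60, missingPattern = "missing_white",
            intervalFlickers = 3, firstOnset = 0, omissionPeriods = 1))

setValidity("FlickerSpec", function(object) {
  msg <- character()
  if (length(object@frequency) != 1L || object@frequency <= 0)
    msg <- c(msg, "frequency must be a single positive number")
  if (object@refresh <= 0)
    msg <- c(msg, "refresh must be positive")
  if (length(object@frequency) == 1L && object@frequency > 0 &&
      object@refresh / object@frequency < 2 - 1e-9)
    msg <- c(msg, "refresh must be at least twice the flicker frequency")
  if (object@duration <= 0)
    msg <- c(msg, "duration must be positive")
  if (!object@missingPattern %in% .MISSING_PATTERNS)
    msg <- c(msg, sprintf("missingPattern must be one of %s",
                          paste(.MISSING_PATTERNS, collapse = ", ")))
  if (is.finite(object@intervalFlickers) &&
      (object@intervalFlickers < 1 ||
       object@intervalFlickers != round(object@intervalFlickers)))
    msg <- c(msg, "intervalFlickers must be a positive integer (or Inf)")
  if (object@firstOnset < 0 || object@firstOnset >= object@duration)
    msg <- c(msg, "firstOnset must lie in [0, duration)")
  if (object@omissionPeriods < 1 ||
      object@omissionPeriods != round(object@omissionPeriods))
    msg <- c(msg, "omissionPeriods must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' StimulusSchedule: frame sequences for the four-disc layout
#'
#' Frame-accurate binary luminance sequences (1 = white, 0 = black) for four
#' discs plus the omission-onset times each disc carries. Discs sharing a
#' flicker frequency are told apart downstream purely by their omission
#' onsets.
#'
#' @slot frames integer matrix, frames x discs, values 0/1.
#' @slot onsets list of numeric vectors, omission-onset seconds per disc.
#' @slot frequencies flicker frequency per disc, Hz.
#' @slot refresh display refresh rate, Hz.
#' @slot duration stimulation length, seconds.
#' @slot missingPattern omission pattern shared by all discs.
#' @slot specs list of the [FlickerSpec-class] objects that built each disc.
#' @export
setClass("StimulusSchedule",
  representation(frames = "matrix", onsets = "list", frequencies = "numeric",
                 refresh = "numeric", duration = "numeric",
                 missingPattern = "character", specs = "list"))

setValidity("StimulusSchedule", function(object) {
  msg <- character()
  nd <- ncol(object@frames)
  if (!all(object@frames %in% c(0L, 1L)))
    msg <- c(msg, "frames must be binary")
  if (length(object@onsets) != nd || length(object@frequencies) != nd)
    msg <- c(msg, "onsets and frequencies must have one entry per disc")
  if (nrow(object@frames) != round(object@duration * object@refresh))
    msg <- c(msg, "frame count must equal round(duration * refresh)")
  for (d in seq_along(object@onsets)) {
    on <- object@onsets[[d]]
    if (length(on) && any(diff(on) <= 0))
      msg <- c(msg, sprintf("disc %d onsets must be strictly increasing", d))
    if (length(on) &&
        any(abs(on * object@refresh - round(on * object@refresh)) > 1e-6))
      msg <- c(msg, sprintf("disc %d onsets must fall on frame boundaries", d))
  }
  if (length(msg)) msg else TRUE
})

#' ForwardModelConfig: parameters of the synthetic-EEG generator
#'
#' Amplitudes are in microvolts, times in seconds. The generator sums, per
#' disc, a harmonically weighted SSVEP at that disc's flicker frequency
#' (gated off during its omitted periods) and a tri-phasic
#' omitted-stimulus-potential template inserted at each omission onset, scales
#' by a fixation gain and a posterior-weighted channel topography, and adds
#' 1/f (or white) noise plus 50 Hz line interference which is subsequently
#' notch-filtered, emulating the acquisition chain.
#'
#' @slot channelLabels electrode names (default the ten posterior/central
#'   sites O1, O2, Oz, PO3, POz, PO4, PO7, PO8, Pz, Cz).
#' @slot fs sampling rate, Hz (default 1200).
#' @slot ssvepAmplitude fundamental SSVEP amplitude, uV.
#' @slot harmonicWeights relative amplitude per harmonic (fundamental first).
#' @slot ospLatency,ospWidth,ospAmplitude three Gaussian-windowed deflections
#'   (positive P1, negative N2, positive P2) at 160/210/290 ms.
#' @slot channelGain per-channel scalar topography.
#' @slot nonattendedGain gain applied to non-fixated discs, in [0, 1].
#' @slot patternGainWhite multiplier on OSP amplitude under the
#'   `missing_white` pattern (the omission of a bright phase yields a larger
#'   deflection); `missing_black` uses 1.
#' @slot noiseSd noise standard deviation per channel, uV.
#' @slot noiseColor `"pink"` (power ~ 1/f) or `"white"`.
#' @slot lineNoiseAmp 50 Hz line-interference amplitude, uV.
#' @slot seed integer seed making every simulation reproducible.
#' @export
setClass("ForwardModelConfig",
  representation(channelLabels = "character", fs = "numeric",
                 ssvepAmplitude = "numeric", harmonicWeights = "numeric",
                 ospLatency = "numeric", ospWidth = "numeric",
                 ospAmplitude = "numeric", channelGain = "numeric",
                 nonattendedGain = "numeric", patternGainWhite = "numeric",
                 noiseSd = "numeric", noiseColor = "character",
                 lineNoiseAmp = "numeric", seed = "integer"))

setValidity("ForwardModelConfig", function(object) {
  msg <- character()
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (object@fs <= 2 * 45)
    msg <- c(msg, "fs must exceed twice the 45 Hz band edge")
  if (length(object@channelGain) != length(object@channelLabels))
    msg <- c(msg, "one channel gain per channel required")
  if (any(object@channelGain < 0))
    msg <- c(msg, "channel gains must be non-negative")
  if (length(object@ospLatency) != 3L || length(object@ospWidth) != 3L ||
      length(object@ospAmplitude) != 3L)
    msg <- c(msg, "three OSP components (P1, N2, P2) are required")
  else {
    if (is.unsorted(object@ospLatency, strictly = TRUE))
      msg <- c(msg, "OSP latencies must be strictly increasing (P1 < N2 < P2)")
    if (any(object@ospLatency < 0.1) || any(object@ospLatency > 0.4))
      msg <- c(msg, "OSP latencies must lie near the 125-375 ms response window")
  }
  if (object@nonattendedGain < 0 || object@nonattendedGain > 1)
    msg <- c(msg, "nonattendedGain must lie in [0, 1]")
  if (object@noiseSd < 0 || object@lineNoiseAmp < 0)
    msg <- c(msg, "noise amplitudes must be non-negative")
  if (!object@noiseColor %in% c("pink", "white"))
    msg <- c(msg, "noiseColor must be 'pink' or 'white'")
  if (length(msg)) msg else TRUE
})

#' EEGRecording: multichannel EEG with event annotations
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot fs sampling rate, Hz.
#' @slot channelLabels one label per row of `data`.
#' @slot events data.frame with columns `time` (s), `disc` (integer or NA)
#'   and `kind` (`stim_on`, `missing_event`, `stim_off`).
#' @export
setClass("EEGRecording",
  representation(data = "matrix", fs = "numeric",
                 channelLabels = "character", events = "data.frame"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "one channel label per data row required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "data must be finite")
  if (nrow(object@events)) {
    need <- c("time", "disc", "kind")
    if (!all(need %in% names(object@events)))
      msg <- c(msg, "events needs columns time, disc, kind")
    else {
      dur <- ncol(object@data) / object@fs
      if (any(object@events$time < 0 | object@events$time > dur + 1e-9))
        msg <- c(msg, "event times must lie within the recording")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SessionProtocol: trial bookkeeping for training or online sessions
#'
#' Training sessions comprise 4 fixation tasks (one per disc) x 7 runs x 16
#' trials; online sessions 10 runs x 16 trials. Per-trial timing is dark
#' 2 s, cue 0.5 s, stimulation 2.5 s, inter-trial 0.5 s.
#'
#' @slot phase `"training"` or `"online"`.
#' @slot nTasks,nRuns,nTrialsPerRun counts defining the session.
#' @slot timing named numeric: `dark`, `cue`, `stim`, `iti` seconds.
#' @export
setClass("SessionProtocol",
  representation(phase = "character", nTasks = "integer", nRuns = "integer",
                 nTrialsPerRun = "integer", timing = "numeric"))

setValidity("SessionProtocol", function(object) {
  msg <- character()
  if (!object@phase %in% c("training", "online"))
    msg <- c(msg, "phase must be 'training' or 'online'")
  if (any(c(object@nTasks, object@nRuns, object@nTrialsPerRun) < 1L))
    msg <- c(msg, "task/run/trial counts must be positive")
  if (!all(c("dark", "cue", "stim", "iti") %in% names(object@timing)))
    msg <- c(msg, "timing needs dark, cue, stim, iti entries")
  if (length(msg)) msg else TRUE
})

#' EEGSession: simulated trials with their fixation labels
#'
#' @slot trials list of [EEGRecording-class] objects, one per trial.
#' @slot labels integer vector of attended-disc labels, one per trial.
#' @slot protocol the [SessionProtocol-class] that produced the session.
#' @slot schedule the [StimulusSchedule-class] driving every trial.
#' @export
setClass("EEGSession",
  representation(trials = "list", labels = "integer",
                 protocol = "SessionProtocol", schedule = "StimulusSchedule"))

setValidity("EEGSession", function(object) {
  if (length(object@trials) != length(object@labels))
    return("one label per trial required")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > ncol(object@schedule@frames)))
    return("labels must index discs of the schedule")
  TRUE
})

#' EpochSet: event-locked EEG segments
#'
#' @slot epochs numeric array, epochs x channels x samples.
#' @slot window half-open time window (start, end) in seconds relative to
#'   the locking event.
#' @slot fs source sampling rate, Hz.
#' @slot lockedEvent description of the locking event kind.
#' @slot channelLabels channel names along the second array dimension.
#' @export
setClass("EpochSet",
  representation(epochs = "array", window = "numeric", fs = "numeric",
                 lockedEvent = "character", channelLabels = "character"))

setValidity("EpochSet", function(object) {
  msg <- character()
  if (length(dim(object@epochs)) != 3L)
    msg <- c(msg, "epochs must be a 3-d array (epochs x channels x samples)")
  if (length(object@window) != 2L || object@window[2] <= object@window[1])
    msg <- c(msg, "window must be (start, end) with start < end")
  else {
    len <- diff(object@window) * object@fs
    if (abs(len - round(len)) > 1e-6)
      msg <- c(msg, "window length times fs must be integral")
    if (length(dim(object@epochs)) == 3L &&
        dim(object@epochs)[3] != round(len))
      msg <- c(msg, "sample dimension must match window length")
  }
  if (length(dim(object@epochs)) == 3L &&
      dim(object@epochs)[2] != length(object@channelLabels))
    msg <- c(msg, "one channel label per channel dimension required")
  if (length(msg)) msg else TRUE
})

#' WindowGrid: the ten 25 ms analysis windows after an omission onset
#'
#' Windows are half-open, contiguous, 25 ms each, spanning [125, 375) ms
#' after the omission onset: {[125,150), ..., [350,375)} ms. At 1200 Hz each
#' window holds 30 samples, so a per-electrode feature vector is 10 x 30.
#'
#' @slot starts,ends window edges in seconds relative to the onset.
#' @slot fs sampling rate, Hz.
#' @slot samplesPerWindow samples per window at `fs`.
#' @export
setClass("WindowGrid",
  representation(starts = "numeric", ends = "numeric", fs = "numeric",
                 samplesPerWindow = "integer"))

setValidity("WindowGrid", function(object) {
  msg <- character()
  if (length(object@starts) != length(object@ends))
    msg <- c(msg, "starts and ends must align")
  if (any(abs(object@ends - object@starts - 0.025) > 1e-9))
    msg <- c(msg, "windows must be 25 ms wide")
  if (length(object@starts) > 1L &&
      any(abs(object@starts[-1] - object@ends[-length(object@ends)]) > 1e-9))
    msg <- c(msg, "windows must be contiguous")
  spw <- 0.025 * object@fs
  if (abs(spw - round(spw)) > 1e-9)
    msg <- c(msg, "fs must yield an integer number of samples per 25 ms window")
  if (object@samplesPerWindow != round(spw))
    msg <- c(msg, "samplesPerWindow inconsistent with fs")
  if (length(msg)) msg else TRUE
})

#' SvmBank: one linear SVM per analysis window
#'
#' Each window's classifier is a linear decision function d = 1 iff
#' w.x + b > 0 (exact zero maps to class 0). Weights are extracted from the
#' trained support-vector expansion so the bank serializes to plain JSON.
#'
#' @slot weights numeric matrix, windows x samplesPerWindow.
#' @slot bias numeric, one intercept per window.
#' @slot cost selected misclassification penalty C per window.
#' @slot cvAccuracy cross-validated accuracy of the selected C per window.
#' @slot grid the [WindowGrid-class] the bank was trained on.
#' @slot fits optional list of underlying svm fits (in-memory only; not
#'   serialized).
#' @export
setClass("SvmBank",
  representation(weights = "matrix", bias = "numeric", cost = "numeric",
                 cvAccuracy = "numeric", grid = "WindowGrid", fits = "list"))

setValidity("SvmBank", function(object) {
  msg <- character()
  k <- nrow(object@weights)
  if (k != length(object@grid@starts))
    msg <- c(msg, "one weight row per grid window required")
  if (length(object@bias) != k || length(object@cost) != k)
    msg <- c(msg, "bias and cost must have one entry per window")
  if (ncol(object@weights) != object@grid@samplesPerWindow)
    msg <- c(msg, "weight dimensionality must match samples per window")
  if (length(msg)) msg else TRUE
})

#' BayesTable: conditional decision probabilities for likelihood-ratio fusion
#'
#' Stores p[k, m, n] = P(window-k SVM outputs decision m | class n), the
#' quantities entering the naive-Bayes fusion ratio. Estimated with Laplace
#' (+1/+2) smoothing so all entries lie strictly inside (0, 1).
#'
#' @slot p numeric array, windows x decision (0/1) x class (0/1).
#' @export
setClass("BayesTable", representation(p = "array"))

setValidity("BayesTable", function(object) {
  msg <- character()
  d <- dim(object@p)
  if (length(d) != 3L || d[2] != 2L || d[3] != 2L)
    msg <- c(msg, "p must be windows x 2 x 2")
  else {
    if (any(object@p <= 0 | object@p >= 1))
      msg <- c(msg, "all probabilities must lie strictly in (0, 1)")
    sums <- object@p[, 1, ] + object@p[, 2, ]
    if (any(abs(sums - 1) > 1e-9))
      msg <- c(msg, "P(d=0|c) + P(d=1|c) must equal 1 for every window and class")
  }
  if (length(msg)) msg else TRUE
})

#' DecoderModel: the trained hybrid decoder bundle
#'
#' @slot bank the window-wise [SvmBank-class].
#' @slot bayes the fusion [BayesTable-class].
#' @slot grid the analysis [WindowGrid-class].
#' @slot electrodes electrode labels used for decoding.
#' @slot fs sampling rate the model expects, Hz.
#' @slot nAvgTrain averaging count used when building training features.
#' @slot version serialization format tag.
#' @export
setClass("DecoderModel",
  representation(bank = "SvmBank", bayes = "BayesTable", grid = "WindowGrid",
                 electrodes = "character", fs = "numeric",
                 nAvgTrain = "integer", version = "character"))

#' CCAResult: canonical-correlation frequency identification outcome
#'
#' @slot correlations maximal canonical correlation per candidate frequency
#'   (named by frequency).
#' @slot selected the argmax frequency, Hz (ties go to the lower frequency).
#' @slot margin top correlation minus runner-up (0 with one candidate).
#' @export
setClass("CCAResult",
  representation(correlations = "numeric", selected = "numeric",
                 margin = "numeric"))

setValidity("CCAResult", function(object) {
  msg <- character()
  if (any(object@correlations < -1e-9 | object@correlations > 1 + 1e-9))
    msg <- c(msg, "canonical correlations must lie in [0, 1]")
  if (!isTRUE(all.equal(unname(object@selected),
                        as.numeric(names(which.max(object@correlations))))))
    msg <- c(msg, "selected frequency must maximize the correlation")
  if (length(msg)) msg else TRUE
})

#' SessionResult: per-trial decisions with accuracy and ITR
#'
#' @slot trials data.frame with columns `trial`, `truth`, `decided` and
#'   (when available) `frequency`, `ccaMargin`.
#' @slot acc mean decision accuracy in [0, 1].
#' @slot itr information transfer rate, bits/min.
#' @slot nAvg averaging count used at test time.
#' @slot dti decision transfer interval, seconds.
#' @slot nClasses number of selectable targets.
#' @export
setClass("SessionResult",
  representation(trials = "data.frame", acc = "numeric", itr = "numeric",
                 nAvg = "integer", dti = "numeric", nClasses = "integer"))

setValidity("SessionResult", function(object) {
  if (object@acc < 0 || object@acc > 1) return("acc must lie in [0, 1]")
  TRUE
})

## ---- accessors ----

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object, ...) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "ForwardModelConfig", function(object, ...) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(object, ...) object@fs)

#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(object, ...) object@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "ForwardModelConfig", function(object, ...) object@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EpochSet", function(object, ...) object@channelLabels)

#' @rdname accessors
#' @export
setMethod("eegData", "EEGRecording", function(object, ...) object@data)

#' @rdname accessors
#' @export
setMethod("events", "EEGRecording", function(object, ...) object@events)

#' @rdname accessors
#' @export
setMethod("discFrequencies", "StimulusSchedule", function(object, ...) object@frequencies)

#' @param disc disc index (1-4); omit for the full list.
#' @rdname accessors
#' @export
setMethod("missingOnsets", "StimulusSchedule", function(object, disc = NULL, ...) {
  if (is.null(disc)) object@onsets else object@onsets[[disc]]
})

#' @rdname accessors
#' @export
setMethod("frameSequence", "StimulusSchedule", function(object, ...) object@frames)

#' @rdname accessors
#' @export
setMethod("nTrials", "EEGSession", function(object, ...) length(object@trials))

#' @rdname accessors
#' @export
setMethod("nTrials", "SessionProtocol", function(object, ...) {
  n <- object@nRuns * object@nTrialsPerRun
  if (object@phase == "training") n <- n * object@nTasks
  as.integer(n)
})

#' @rdname accessors
#' @export
setMethod("trialLabels", "EEGSession", function(object, ...) object@labels)

#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochSet", function(object, ...) dim(object@epochs)[1])

#' @rdname accessors
#' @export
setMethod("epochArray", "EpochSet", function(object, ...) object@epochs)

#' @rdname accessors
#' @export
setMethod("epochWindow", "EpochSet", function(object, ...) object@window)

#' @rdname accessors
#' @export
setMethod("decodingElectrodes", "DecoderModel", function(object, ...) object@electrodes)

#' @rdname accessors
#' @export
setMethod("bayesTable", "DecoderModel", function(object, ...) object@bayes)

#' @rdname accessors
#' @export
setMethod("svmBank", "DecoderModel", function(object, ...) object@bank)

#' @rdname accessors
#' @export
setMethod("accuracy", "SessionResult", function(object, ...) object@acc)

#' @rdname accessors
#' @export
setMethod("itrBitsPerMin", "SessionResult", function(object, ...) object@itr)

#' @rdname accessors
#' @export
setMethod("selectedFrequency", "CCAResult", function(object, ...) object@selected)

## ---- show methods ----

setMethod("show", "FlickerSpec", function(object) {
  cat(sprintf(
    "FlickerSpec: %.4g Hz on %.4g Hz refresh, %.3g s, %s, omission every %s flickers from %.4g s\n",
    object@frequency, object@refresh, object@duration, object@missingPattern,
    format(object@intervalFlickers), object@firstOnset))
})

setMethod("show", "StimulusSchedule", function(object) {
  cat(sprintf("StimulusSchedule: %d discs, %d frames @ %.4g Hz refresh, pattern %s\n",
              ncol(object@frames), nrow(object@frames), object@refresh,
              object@missingPattern))
  for (d in seq_len(ncol(object@frames)))
    cat(sprintf("  disc %d: %.4g Hz, %d missing events (first %.4g s)\n",
                d, object@frequencies[d], length(object@onsets[[d]]),
                if (length(object@onsets[[d]])) object@onsets[[d]][1] else NA))
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %.4g Hz (%.3g s), %d events\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs, nrow(object@events)))
})

setMethod("show", "EEGSession", function(object) {
  cat(sprintf("EEGSession (%s): %d trials, labels %s\n", object@protocol@phase,
              length(object@trials),
              paste(sprintf("%d x disc %s", tabulate(object@labels),
                            seq_len(max(object@labels))), collapse = ", ")))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples, window [%g, %g) s re %s\n",
              d[1], d[2], d[3], object@window[1], object@window[2],
              object@lockedEvent))
})

setMethod("show", "DecoderModel", function(object) {
  cat(sprintf("DecoderModel: %d-window linear-SVM bank + naive-Bayes fusion\n",
              nrow(object@bank@weights)))
  cat(sprintf("  electrodes: %s; fs %.4g Hz; trained with nAvg = %d\n",
              paste(object@electrodes, collapse = ", "), object@fs,
              object@nAvgTrain))
})

setMethod("show", "CCAResult", function(object) {
  cat("CCAResult:", paste(sprintf("%s Hz: %.3f", names(object@correlations),
                                  object@correlations), collapse = ", "),
      sprintf("-> %g Hz (margin %.3f)\n", object@selected, object@margin))
})

setMethod("show", "SessionResult", function(object) {
  cat(sprintf("SessionResult: %d trials, nAvg %d, Acc %.2f %%, ITR %.2f bits/min (DTI %.2g s)\n",
              nrow(object@trials), object@nAvg, 100 * object@acc, object@itr,
              object@dti))
})
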