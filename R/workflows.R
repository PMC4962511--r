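## End-to-end workflows: training-feature construction, decoder training,
## and the file-based simulate / train / decode commands backing the
## command-line wrapper.

#' Build labeled training features from a session
#'
#' For every trial, epochs locked to the fixated disc's omission onsets are
#' averaged (`nAvg` of them) and yield one target-aligned (class 1) feature
#' vector per decoding electrode; epochs locked to the onsets of the disc
#' sharing the same flicker frequency yield the misaligned class-0
#' counterparts. A default 448-trial training session thus contributes
#' 6 x 4 x 7 x 16 = 2688 target-aligned per-electrode samples (and as many
#' misaligned), each of dimensionality 10 windows x 30 samples.
#'
#' @param session a training [EEGSession-class].
#' @param nAvg epochs averaged per feature (capped at the epochs a disc
#'   offers within one trial).
#' @param grid a [WindowGrid-class].
#' @param electrodes decoding electrodes.
#' @param filter band-pass each trial first (default TRUE).
#' @return list with `features` (samples x 300 matrix) and `labels` (0/1).
#' @export
extractTrainingFeatures <- function(session, nAvg = 4, grid = windowGrid(),
                                    electrodes = .OSP_ELECTRODES,
                                    filter = TRUE) {
  schedule <- session@schedule
  freqs <- schedule@frequencies
  window <- c(grid@starts[1], grid@ends[length(grid@ends)])
  featList <- list()
  labList <- list()
  for (i in seq_len(nTrials(session))) {
    rec <- session@trials[[i]]
    if (filter) rec <- bandpass(rec)
    target <- session@labels[i]
    partner <- setdiff(which(abs(freqs - freqs[target]) < 1e-9), target)
    for (cls in c(1L, 0L)) {
      disc <- if (cls == 1L) target else partner[1]
      es <- epochRecording(rec, schedule@onsets[[disc]], window)
      avg <- averageEpochs(es, min(nAvg, dim(es@epochs)[1]))
      f <- extractFeatures(avg, window, grid, electrodes = electrodes)
      featList[[length(featList) + 1L]] <- f
      labList[[length(labList) + 1L]] <- rep(cls, nrow(f))
    }
  }
  list(features = do.call(rbind, featList), labels = unlist(labList))
}

#' Train the full hybrid decoder on a labeled session
#'
#' Extracts aligned/misaligned training features, trains the window-wise
#' linear-SVM bank (penalty by seeded 10-fold cross-validation), runs the
#' bank back over the training samples and estimates the naive-Bayes
#' fusion table from its decisions.
#'
#' @inheritParams extractTrainingFeatures
#' @param cGrid,nFolds,foldSeed passed to [trainSvmBank()].
#' @return A [DecoderModel-class].
#' @export
trainDecoder <- function(session, nAvg = 4, grid = windowGrid(),
                         electrodes = .OSP_ELECTRODES, cGrid = 10^(-3:1),
                         nFolds = 10, foldSeed = 1L, filter = TRUE) {
  tf <- extractTrainingFeatures(session, nAvg = nAvg, grid = grid,
                                electrodes = electrodes, filter = filter)
  bank <- trainSvmBank(tf$features, tf$labels, grid = grid, cGrid = cGrid,
                       nFolds = nFolds, foldSeed = foldSeed)
  d <- .bankDecisions(bank, tf$features)
  bayes <- fitBayesTable(d, tf$labels)
  methods::new("DecoderModel", bank = bank, bayes = bayes, grid = grid,
               electrodes = electrodes, fs = grid@fs,
               nAvgTrain = as.integer(nAvg), version = "ssvepOSP-model-1")
}

## config -> simulator pieces
.configToObjects <- function(cfg) {
  pattern <- .fullPattern(cfg$pattern %||% "white")
  schedule <- defaultParadigm(pattern,
                              intervalFlickers = cfg$interval_flickers %||% 3)
  fmc <- forwardModelConfig(
    fs = cfg$fs %||% 1200,
    ssvepAmplitude = cfg$ssvep_amplitude %||% 4,
    noiseSd = cfg$noise_sd %||% 2,
    noiseColor = cfg$noise_color %||% "pink",
    lineNoiseAmp = cfg$line_noise_amp %||% 1,
    nonattendedGain = cfg$nonattended_gain %||% 0.1,
    seed = cfg$seed)
  protocol <- if ((cfg$protocol %||% "training") == "training")
    trainingProtocol(nRuns = cfg$runs %||% 7,
                     nTrialsPerRun = cfg$trials_per_run %||% 16)
  else
    onlineProtocol(nRuns = cfg$runs %||% 10,
                   nTrialsPerRun = cfg$trials_per_run %||% 16)
  list(schedule = schedule, fmc = fmc, protocol = protocol)
}

#' Simulate a session to disk
#'
#' Writes one EDF (+ event CSV sidecar) per trial, a labels CSV, the
#' schedule, and a manifest with the configuration and file checksums.
#'
#' @param config a `RunConfig` list (see [readRunConfig()]); must carry a
#'   seed.
#' @param outDir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
cmdSimulate <- function(config, outDir) {
  if (is.null(config$seed)) stop("configuration must supply an integer 'seed'")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  obj <- .configToObjects(config)
  session <- simulateSession(obj$protocol, obj$schedule, obj$fmc)
  files <- character()
  for (i in seq_len(nTrials(session))) {
    p <- file.path(outDir, sprintf("trial_%04d.edf", i))
    writeEDF(session@trials[[i]], p)
    files <- c(files, p, paste0(p, ".events.csv"))
  }
  labPath <- file.path(outDir, "labels.csv")
  utils::write.csv(data.frame(trial = seq_len(nTrials(session)),
                              attended_disc = session@labels),
                   labPath, row.names = FALSE)
  schedPath <- file.path(outDir, "schedule.csv")
  writeSchedule(obj$schedule, schedPath)
  writeManifest(outDir, config, c(files, labPath, schedPath,
                                  paste0(schedPath, ".json")),
                extra = list(n_trials = nTrials(session),
                             phase = obj$protocol@phase))
}

## load a simulated session back from disk
.loadSession <- function(dataDir) {
  labPath <- file.path(dataDir, "labels.csv")
  if (!file.exists(labPath)) stop("label file absent: ", labPath)
  labels <- utils::read.csv(labPath)
  schedule <- readSchedule(file.path(dataDir, "schedule.csv"))
  trials <- lapply(labels$trial, function(i)
    readEDF(file.path(dataDir, sprintf("trial_%04d.edf", i))))
  proto <- if (nrow(labels) %% 4 == 0 &&
               all(tabulate(labels$attended_disc, 4) == nrow(labels) / 4) &&
               !is.unsorted(labels$attended_disc))
    trainingProtocol(nRuns = 1, nTrialsPerRun = nrow(labels) / 4)
  else onlineProtocol(nRuns = 1, nTrialsPerRun = nrow(labels))
  methods::new("EEGSession", trials = trials,
               labels = as.integer(labels$attended_disc), protocol = proto,
               schedule = schedule)
}

#' Train a decoder from simulated data on disk
#'
#' @param config a `RunConfig` list.
#' @param dataDir directory produced by [cmdSimulate()].
#' @param modelPath output JSON path for the model archive.
#' @return the model path, invisibly; logs the per-alignment training
#'   sample count (6 electrodes x trials).
#' @export
cmdTrain <- function(config, dataDir, modelPath) {
  session <- .loadSession(dataDir)
  nAvg <- config$n_avg %||% 4
  model <- trainDecoder(session, nAvg = nAvg,
                        foldSeed = config$seed %||% 1L)
  message(sprintf("trained on %d target-aligned feature samples (6 x %d trials)",
                  6L * nTrials(session), nTrials(session)))
  writeDecoderModel(model, modelPath)
  invisible(modelPath)
}

#' Decode simulated data on disk with a trained model
#'
#' @param config a `RunConfig` list.
#' @param dataDir directory produced by [cmdSimulate()].
#' @param modelPath model archive from [cmdTrain()].
#' @param outDir output directory for `decisions.csv` and `summary.json`.
#' @return the summary list, invisibly.
#' @export
cmdDecode <- function(config, dataDir, modelPath, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  session <- .loadSession(dataDir)
  model <- readDecoderModel(modelPath)
  if (abs(model@fs - session@trials[[1]]@fs) > 1e-9)
    stop("model / data sampling-rate mismatch")
  if (!all(model@electrodes %in% session@trials[[1]]@channelLabels))
    stop("model electrodes absent from the data")
  nAvg <- config$n_avg %||% 4
  res <- decodeSession(session, model, nAvg = nAvg)
  utils::write.csv(res@trials, file.path(outDir, "decisions.csv"),
                   row.names = FALSE)
  summary <- list(n_trials = nrow(res@trials), n_avg = res@nAvg,
                  dti_s = res@dti, accuracy_pct = 100 * accuracy(res),
                  itr_bits_min = itrBitsPerMin(res))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeManifest(outDir, config,
                file.path(outDir, c("decisions.csv", "summary.json")))
  invisible(summary)
}
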