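## File interchange: a minimal 16-bit EDF writer/reader for recordings, a
## CSV event sidecar, YAML run configuration, and JSON serialization of the
## trained decoder bundle.
##
## EDF stores each channel as int16 against a stated physical range
## (+/- 200 uV here); one data record holds the whole recording. Event
## annotations live in a CSV sidecar (time_s, disc, kind) because EDF
## annotation dialects vary.

.EDF_PHYS <- 200   # physical range, +/- uV

.padField <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to EDF
#'
#' Samples are quantized to 16 bits over +/- 200 uV (values outside are
#' clipped). The event table goes to `<path>.events.csv`.
#'
#' @param recording an [EEGRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(recording, path) {
  nCh <- nrow(recording@data)
  nSamp <- ncol(recording@data)
  recDur <- nSamp / recording@fs
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .padField("0", 8),
    .padField("X X X X", 80),
    .padField("Startdate X X X X", 80),
    .padField("01.01.26", 8), .padField("00.00.00", 8),
    .padField(256 * (1 + nCh), 8),
    .padField("", 44),
    .padField(1, 8),
    .padField(format(recDur, digits = 8), 8),
    .padField(nCh, 4),
    paste(vapply(recording@channelLabels, .padField, "", width = 16), collapse = ""),
    paste(rep(.padField("AgAgCl electrode", 80), nCh), collapse = ""),
    paste(rep(.padField("uV", 8), nCh), collapse = ""),
    paste(rep(.padField(-.EDF_PHYS, 8), nCh), collapse = ""),
    paste(rep(.padField(.EDF_PHYS, 8), nCh), collapse = ""),
    paste(rep(.padField(-32768, 8), nCh), collapse = ""),
    paste(rep(.padField(32767, 8), nCh), collapse = ""),
    paste(rep(.padField("BP 1-45 Hz; notch 50 Hz", 80), nCh), collapse = ""),
    paste(rep(.padField(nSamp, 8), nCh), collapse = ""),
    paste(rep(.padField("", 32), nCh), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  scale <- 32767 / .EDF_PHYS
  for (ch in seq_len(nCh)) {
    dig <- as.integer(round(pmin(pmax(recording@data[ch, ], -.EDF_PHYS),
                                 .EDF_PHYS) * scale))
    writeBin(dig, con, size = 2, endian = "little")
  }
  writeEvents(recording@events, paste0(path, ".events.csv"))
  invisible(path)
}

#' @rdname writeEDF
#' @param fs sampling rate to attach on read (EDF stores record duration and
#'   sample counts; `NULL` derives fs from them).
#' @return `readEDF`: an [EEGRecording-class].
#' @export
readEDF <- function(path, fs = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nCh <- as.integer(rd(4))
  labels <- vapply(seq_len(nCh), function(i) rd(16), "")
  rd(80 * nCh); rd(8 * nCh)
  physMin <- as.numeric(vapply(seq_len(nCh), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(nCh), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(nCh), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(nCh), function(i) rd(8), ""))
  rd(80 * nCh)
  spr <- as.integer(vapply(seq_len(nCh), function(i) rd(8), ""))
  rd(32 * nCh)
  data <- matrix(0, nCh, spr[1] * nRec)
  for (r in seq_len(nRec))
    for (ch in seq_len(nCh)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      data[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        physMin[ch] + (dig - digMin[ch]) *
          (physMax[ch] - physMin[ch]) / (digMax[ch] - digMin[ch])
    }
  if (is.null(fs)) fs <- spr[1] / (recDur / 1)
  evPath <- paste0(path, ".events.csv")
  events <- if (file.exists(evPath)) readEvents(evPath) else
    data.frame(time = numeric(0), disc = integer(0), kind = character(0))
  methods::new("EEGRecording", data = data, fs = fs, channelLabels = labels,
               events = events)
}

#' Event sidecar CSV
#'
#' Columns `time_s`, `disc` (empty for non-disc events) and `kind`.
#'
#' @param events data.frame with columns `time`, `disc`, `kind`.
#' @param path CSV path.
#' @return `path` invisibly (writer); the events data.frame (reader).
#' @export
writeEvents <- function(events, path) {
  utils::write.csv(data.frame(time_s = events$time, disc = events$disc,
                              kind = events$kind), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  df <- utils::read.csv(path)
  data.frame(time = df$time_s, disc = as.integer(df$disc), kind = df$kind)
}

#' Serialize / restore a trained decoder
#'
#' The whole bundle — window weights and biases, selected penalties, fusion
#' table, window grid, electrode list and a format version tag — goes to a
#' single JSON file, so trained decoders are portable and inspectable.
#'
#' @param model a [DecoderModel-class].
#' @param path JSON file path.
#' @return `path` invisibly (writer); a [DecoderModel-class] (reader). The
#'   in-memory svm fits are not serialized; the linear weights fully
#'   determine every decision.
#' @export
writeDecoderModel <- function(model, path) {
  obj <- list(
    version = model@version,
    fs = model@fs,
    electrodes = model@electrodes,
    n_avg_train = model@nAvgTrain,
    grid = list(starts = model@grid@starts, ends = model@grid@ends,
                fs = model@grid@fs,
                samples_per_window = model@grid@samplesPerWindow),
    svm = list(weights = model@bank@weights, bias = model@bank@bias,
               cost = model@bank@cost, cv_accuracy = model@bank@cvAccuracy),
    bayes = list(p = as.vector(model@bayes@p), dim = dim(model@bayes@p)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDecoderModel
#' @export
readDecoderModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- methods::new("WindowGrid", starts = obj$grid$starts,
                       ends = obj$grid$ends, fs = obj$grid$fs,
                       samplesPerWindow = as.integer(obj$grid$samples_per_window))
  bank <- methods::new("SvmBank", weights = as.matrix(obj$svm$weights),
                       bias = obj$svm$bias, cost = obj$svm$cost,
                       cvAccuracy = obj$svm$cv_accuracy, grid = grid,
                       fits = list())
  p <- array(obj$bayes$p, dim = obj$bayes$dim,
             dimnames = list(NULL, d = c("0", "1"), c = c("0", "1")))
  methods::new("DecoderModel", bank = bank,
               bayes = methods::new("BayesTable", p = p), grid = grid,
               electrodes = obj$electrodes, fs = obj$fs,
               nAvgTrain = as.integer(obj$n_avg_train), version = obj$version)
}

## ---- run configuration ----

.RUNCONFIG_KEYS <- c("seed", "pattern", "n_avg", "fs", "noise_sd",
                     "noise_color", "ssvep_amplitude", "line_noise_amp",
                     "nonattended_gain", "protocol", "runs",
                     "trials_per_run", "interval_flickers", "duration",
                     "out_dir")

#' Read and validate a run configuration (YAML or JSON)
#'
#' Unknown keys are rejected; `seed` is mandatory for simulation commands.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param requireSeed error when `seed` is absent.
#' @return a validated named list with class `"RunConfig"`.
#' @export
readRunConfig <- function(path, requireSeed = TRUE) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .RUNCONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (requireSeed && is.null(cfg$seed))
    stop("configuration must supply an integer 'seed'")
  if (!is.null(cfg$pattern) &&
      !cfg$pattern %in% c("white", "black", .MISSING_PATTERNS))
    stop("pattern must be 'white' or 'black'")
  structure(cfg, class = "RunConfig")
}

## expand shorthand pattern names
.fullPattern <- function(pattern) {
  if (pattern %in% .MISSING_PATTERNS) pattern
  else paste0("missing_", match.arg(pattern, c("white", "black")))
}

#' Write a run manifest
#'
#' Records the configuration, seed, package version and the MD5 checksum of
#' every listed file — sufficient to reproduce the run bit for bit.
#'
#' @param dir output directory.
#' @param config the run configuration (list).
#' @param files character vector of file paths to checksum.
#' @param extra optional named list merged into the manifest.
#' @return the manifest path, invisibly.
#' @export
writeManifest <- function(dir, config, files = character(), extra = list()) {
  man <- c(list(
    package = "ssvepOSP",
    version = as.character(utils::packageVersion("ssvepOSP")),
    config = unclass(config),
    files = if (length(files))
      data.frame(path = basename(files), md5 = unname(tools::md5sum(files)))
    else NULL), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
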