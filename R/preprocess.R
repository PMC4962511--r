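## Zero-phase band-pass filtering and event-locked epoching/averaging.
##
## Filter: 4th-order Butterworth applied forward-backward (filtfilt), so the
## pass-band is phase-free — essential, since the decoder lives off component
## latencies at 160/210/290 ms. Onset-to-sample mapping rounds to the
## nearest sample with ties toward -Inf; windows are half-open [start, end).

.roundHalfDown <- function(x) ceiling(x - 0.5)

#' Zero-phase band-pass filter
#'
#' @param recording an [EEGRecording-class].
#' @param low,high pass-band edges, Hz (defaults 1-45: removes baseline
#'   excursion and high-frequency noise while keeping both flicker
#'   fundamentals and second harmonics).
#' @param order Butterworth order (applied twice by filtfilt).
#' @return A filtered [EEGRecording-class] of identical length.
#' @export
bandpass <- function(recording, low = 1, high = 45, order = 4) {
  fs <- recording@fs
  if (!(low < high && high < fs / 2))
    stop("require low < high < fs/2 (Nyquist)")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- recording
  for (ch in seq_len(nrow(recording@data)))
    out@data[ch, ] <- signal::filtfilt(bf, recording@data[ch, ])
  out
}

#' Cut event-locked epochs
#'
#' One epoch per onset, samples on the half-open window
#' `[onset + window[1], onset + window[2])`. Onsets whose window falls
#' outside the recording are skipped with a warning; if none remain an
#' error is raised.
#'
#' @param recording an [EEGRecording-class].
#' @param onsets event times, seconds.
#' @param window `c(start, end)` seconds relative to each onset.
#' @param lockedEvent label stored on the result.
#' @return An [EpochSet-class] (epochs x channels x samples).
#' @export
epochRecording <- function(recording, onsets, window,
                           lockedEvent = "missing_event") {
  if (!length(onsets)) stop("no onsets supplied")
  fs <- recording@fs
  len <- round(diff(window) * fs)
  nSamp <- ncol(recording@data)
  i0 <- .roundHalfDown((onsets + window[1]) * fs) + 1L  # 1-based start
  ok <- i0 >= 1L & (i0 + len - 1L) <= nSamp
  if (any(!ok))
    warning(sprintf("skipping %d onset(s) whose window falls outside the recording",
                    sum(!ok)))
  i0 <- i0[ok]
  if (!length(i0)) stop("no usable onsets: every window falls outside the recording")
  nCh <- nrow(recording@data)
  ep <- array(0, dim = c(length(i0), nCh, len))
  for (e in seq_along(i0))
    ep[e, , ] <- recording@data[, i0[e]:(i0[e] + len - 1L), drop = FALSE]
  methods::new("EpochSet", epochs = ep, window = window, fs = fs,
               lockedEvent = lockedEvent,
               channelLabels = recording@channelLabels)
}

#' Average the first n event-locked epochs
#'
#' Arithmetic mean of the first `nAvg` epochs in onset order; averaging n
#' time-locked epochs suppresses additive zero-mean noise by sqrt(n) while
#' leaving the time-locked response untouched.
#'
#' @param epochset an [EpochSet-class].
#' @param nAvg number of epochs to average.
#' @return numeric matrix, channels x samples.
#' @export
averageEpochs <- function(epochset, nAvg) {
  nAvail <- dim(epochset@epochs)[1]
  if (nAvg > nAvail)
    stop(sprintf("nAvg = %d exceeds the %d available epoch(s)", nAvg, nAvail))
  sub <- epochset@epochs[seq_len(nAvg), , , drop = FALSE]
  out <- apply(sub, c(2, 3), mean)
  rownames(out) <- epochset@channelLabels
  out
}

#' Export an epoch set to CSV for inspection
#'
#' Long format: one row per (epoch, channel, sample) with the sample's time
#' in seconds relative to the locking event.
#'
#' @param epochset an [EpochSet-class].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
writeEpochs <- function(epochset, path) {
  d <- dim(epochset@epochs)
  tRel <- epochset@window[1] + (seq_len(d[3]) - 1) / epochset@fs
  df <- data.frame(
    epoch = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(epochset@channelLabels, each = d[1]), times = d[3]),
    time_s = rep(tRel, each = d[1] * d[2]),
    value = as.vector(epochset@epochs))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
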