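## Hybrid target decision (frequency x omission onset), accuracy and
## information transfer rate.
##
## ITR (bits/min) for N targets, accuracy Acc and a decision transfer
## interval DTI (seconds per command):
##   ITR = 60/DTI * [log2 N + Acc log2 Acc + (1-Acc) log2((1-Acc)/(N-1))]
## with 0*log2(0) taken as 0. The default DTI per averaging count is
## {2 -> 2.5, 4 -> 3.0, 6 -> 3.5, 8 -> 4.0} s.

#' Default decision-transfer-interval map
#'
#' Seconds consumed per output command for each averaging count. The 3.0 s
#' (nAvg 4) and 3.5 s (nAvg 6) values exactly regenerate the published
#' per-subject ITRs from their accuracies; 2.5 and 4.0 s extend the
#' +0.5 s per +2 averages pattern.
#'
#' @return named numeric vector (names = averaging counts).
#' @export
defaultDtiMap <- function() c(`2` = 2.5, `4` = 3.0, `6` = 3.5, `8` = 4.0)

#' Information transfer rate
#'
#' @param N number of selectable targets (>= 2).
#' @param acc mean detection accuracy in [0, 1].
#' @param dti decision transfer interval, seconds per command.
#' @return ITR in bits/min. Zero at chance (acc = 1/N), strictly increasing
#'   in `acc` above chance, and scaling as 1/DTI.
#' @examples
#' itr(4, 0.9625, 3.0)  # 34.20
#' itr(4, 1, 3.0)       # 40
#' itr(4, 0.25, 3.0)    # 0
#' @export
itr <- function(N, acc, dti) {
  if (N < 2) stop("N must be at least 2")
  if (dti <= 0) stop("dti must be positive")
  if (acc < 0 || acc > 1) stop("acc must lie in [0, 1]")
  bits <- log2(N)
  if (acc > 0) bits <- bits + acc * log2(acc)
  if (acc < 1) bits <- bits + (1 - acc) * log2((1 - acc) / (N - 1))
  60 / dti * bits
}

#' Decide the attended disc of one trial
#'
#' Two-stage hybrid decision: [detectFrequency()] picks the flicker
#' frequency among the schedule's distinct frequencies (frequency stage),
#' then [classifyOnsetCandidates()] disambiguates the discs sharing that
#' frequency by their omission-onset alignment (time stage). A wrong
#' frequency therefore confines the error to the wrong frequency pair.
#'
#' @param recording a band-passed [EEGRecording-class].
#' @param schedule the [StimulusSchedule-class] that drove the trial.
#' @param model a trained [DecoderModel-class].
#' @param nAvg omission epochs averaged per candidate (capped at the
#'   epochs available within the trial).
#' @return list with `disc`, `frequency`, `ccaMargin` and `logScores`.
#' @export
decideTarget <- function(recording, schedule, model, nAvg) {
  freqs <- schedule@frequencies
  cand <- sort(unique(freqs))
  cca <- detectFrequency(recording, candidates = cand,
                         electrodes = model@electrodes)
  discs <- which(abs(freqs - cca@selected) < 1e-9)
  onsetSets <- stats::setNames(schedule@onsets[discs], discs)
  if (length(discs) == 1L) {
    return(list(disc = discs, frequency = cca@selected,
                ccaMargin = cca@margin, logScores = NULL))
  }
  cls <- classifyOnsetCandidates(recording, onsetSets, nAvg, model,
                                 truncate = TRUE)
  list(disc = discs[cls$selected], frequency = cca@selected,
       ccaMargin = cca@margin, logScores = cls$logScores)
}

#' Summarize a sequence of decisions
#'
#' @param decided,truth equal-length integer vectors of decided and true
#'   disc labels.
#' @param N number of selectable targets.
#' @param dti decision transfer interval, seconds.
#' @param nAvg averaging count the decisions were made with.
#' @param extra optional data.frame of per-trial columns to carry along.
#' @return A [SessionResult-class].
#' @export
evaluateSession <- function(decided, truth, N = 4, dti = 3.0, nAvg = NA_integer_,
                            extra = NULL) {
  if (!length(decided)) stop("no decisions supplied")
  if (length(decided) != length(truth))
    stop("decided and truth must have equal length")
  trials <- data.frame(trial = seq_along(decided), truth = truth,
                       decided = decided)
  if (!is.null(extra)) trials <- cbind(trials, extra)
  acc <- mean(decided == truth)
  methods::new("SessionResult", trials = trials, acc = acc,
               itr = itr(N, acc, dti), nAvg = as.integer(nAvg), dti = dti,
               nClasses = as.integer(N))
}

#' Decode every trial of a session
#'
#' Band-passes each trial, runs the two-stage decision, and summarizes
#' accuracy and ITR.
#'
#' @param session an [EEGSession-class].
#' @param model a trained [DecoderModel-class].
#' @param nAvg averaging count at test time.
#' @param dti decision transfer interval; default looked up from
#'   [defaultDtiMap()] by `nAvg`.
#' @return A [SessionResult-class].
#' @export
decodeSession <- function(session, model, nAvg, dti = NULL) {
  if (is.null(dti)) {
    dti <- defaultDtiMap()[as.character(nAvg)]
    if (is.na(dti)) stop("no default DTI for nAvg = ", nAvg,
                         "; supply dti explicitly")
  }
  n <- nTrials(session)
  decided <- integer(n)
  freq <- margin <- numeric(n)
  for (i in seq_len(n)) {
    rec <- bandpass(session@trials[[i]])
    d <- decideTarget(rec, session@schedule, model, nAvg)
    decided[i] <- d$disc
    freq[i] <- d$frequency
    margin[i] <- d$ccaMargin
  }
  evaluateSession(decided, session@labels,
                  N = ncol(session@schedule@frames), dti = unname(dti),
                  nAvg = nAvg,
                  extra = data.frame(frequency = freq, ccaMargin = margin))
}

#' Sweep the averaging count and report the ITR maximizer
#'
#' Decodes the session at every averaging count and returns the one with
#' the highest ITR (ties go to the smallest count).
#'
#' @param session an [EEGSession-class].
#' @param model a trained [DecoderModel-class].
#' @param avgSet averaging counts to sweep.
#' @param dtiMap named numeric, DTI seconds per averaging count.
#' @return list with `best` (a [SessionResult-class]), `nAvg`, and `sweep`
#'   (data.frame of nAvg, acc, itr).
#' @export
averagingSweep <- function(session, model, avgSet = c(2, 4, 6, 8),
                           dtiMap = defaultDtiMap()) {
  res <- lapply(avgSet, function(na) {
    dti <- dtiMap[as.character(na)]
    if (is.na(dti)) stop("dtiMap supplies no DTI for nAvg = ", na)
    decodeSession(session, model, nAvg = na, dti = unname(dti))
  })
  tab <- data.frame(nAvg = avgSet,
                    acc = vapply(res, accuracy, numeric(1)),
                    itr = vapply(res, itrBitsPerMin, numeric(1)))
  best <- which.max(tab$itr)             # first max -> smallest nAvg on ties
  list(best = res[[best]], nAvg = avgSet[best], sweep = tab)
}

#' Recompute ITR columns and their statistics from published accuracies
#'
#' Applies the ITR formula to per-subject (accuracy, averaging-count)
#' pairs, looking the DTI up in `dtiMap`, and reports the per-subject ITRs
#' together with column means and standard deviations.
#'
#' @param accuracyPct per-subject mean accuracies, percent.
#' @param averagingTimes per-subject averaging counts.
#' @param dtiMap named numeric, DTI seconds per averaging count.
#' @param N number of targets.
#' @return list with `itr` (per subject, bits/min), `meanAcc`, `sdAcc`
#'   (percent), `meanItr`, `sdItr`.
#' @export
table1Check <- function(accuracyPct, averagingTimes, dtiMap = defaultDtiMap(),
                        N = 4) {
  stopifnot(length(accuracyPct) == length(averagingTimes))
  dti <- dtiMap[as.character(averagingTimes)]
  if (anyNA(dti)) stop("dtiMap misses an averaging count")
  itrs <- mapply(function(a, d) itr(N, a / 100, d), accuracyPct, unname(dti))
  list(itr = unname(itrs), meanAcc = mean(accuracyPct),
       sdAcc = stats::sd(accuracyPct), meanItr = mean(itrs),
       sdItr = stats::sd(itrs))
}
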