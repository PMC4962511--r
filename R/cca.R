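## Canonical-correlation frequency identification.
##
## The attended flicker frequency is the candidate whose sinusoidal
## reference set (sin/cos at the fundamental and second harmonic) attains
## the largest first canonical correlation with the multichannel EEG
## segment. The correlation is computed from thin-QR orthonormal bases of
## the (column-centered) data matrices; rank deficiency is handled by
## truncating to the numerical rank, which acts as a regularized solve.

#' Sinusoidal reference set for one candidate frequency
#'
#' @param frequency candidate flicker frequency, Hz.
#' @param nSamples segment length in samples.
#' @param fs sampling rate, Hz.
#' @param harmonics number of harmonics (default 2: fundamental plus second
#'   harmonic, which carries appreciable SSVEP power).
#' @return numeric matrix with `2 * harmonics` rows (sin and cos per
#'   harmonic) and `nSamples` columns.
#' @export
makeReference <- function(frequency, nSamples, fs, harmonics = 2) {
  t <- (seq_len(nSamples) - 1) / fs
  Y <- matrix(0, 2 * harmonics, nSamples)
  for (h in seq_len(harmonics)) {
    Y[2 * h - 1, ] <- sin(2 * pi * h * frequency * t)
    Y[2 * h, ]     <- cos(2 * pi * h * frequency * t)
  }
  rownames(Y) <- as.vector(t(outer(seq_len(harmonics), c("sin", "cos"),
                                   function(h, f) paste0(f, h * frequency))))
  Y
}

## orthonormal basis of the centered row space, truncated to numerical rank
.centeredBasis <- function(X, tol = 1e-10) {
  Xc <- scale(t(X), center = TRUE, scale = FALSE)  # samples x vars, centered
  qrd <- qr(Xc, tol = tol)
  r <- qrd$rank
  if (r == 0L) stop("input has no variance")
  if (r < ncol(Xc))
    message(sprintf("rank-deficient input (%d of %d): using a rank-truncated (regularized) solve",
                    r, ncol(Xc)))
  qr.Q(qrd)[, seq_len(r), drop = FALSE]
}

#' First canonical correlation between an EEG segment and a reference set
#'
#' Largest canonical correlation between the row spaces of `X` and `Y`
#' (both centered over samples), i.e. the largest singular value of
#' Qx' Qy for orthonormal bases Qx, Qy. Invariant to any invertible linear
#' mixing of the channels.
#'
#' @param X numeric matrix, channels x samples.
#' @param Y numeric matrix (e.g. from [makeReference()]), references x
#'   samples.
#' @return the first canonical correlation, clipped to [0, 1].
#' @export
ccaMaxCorrelation <- function(X, Y) {
  if (ncol(X) != ncol(Y)) stop("X and Y must share the sample dimension")
  if (ncol(X) <= nrow(X) + nrow(Y))
    stop("need more samples than total variables")
  Qx <- .centeredBasis(X)
  Qy <- .centeredBasis(Y)
  rho <- svd(crossprod(Qx, Qy))$d[1]
  min(max(rho, 0), 1)
}

#' Identify the attended flicker frequency
#'
#' Computes the maximal canonical correlation between the (band-passed)
#' segment restricted to the decoding electrodes and a sinusoidal reference
#' set per candidate frequency; the candidate with the largest correlation
#' wins, ties broken toward the lower frequency.
#'
#' @param recording an [EEGRecording-class] (band-passed).
#' @param candidates candidate frequencies, Hz.
#' @param electrodes channel labels entering the analysis (default the six
#'   occipito-parietal decoding electrodes).
#' @param window analysis window `c(start, end)` seconds (default the full
#'   stimulation span up to the last `stim_off` event, else the whole
#'   recording).
#' @param harmonics harmonics per reference set.
#' @return A [CCAResult-class].
#' @export
detectFrequency <- function(recording, candidates = c(10, 12),
                            electrodes = .OSP_ELECTRODES, window = NULL,
                            harmonics = 2) {
  if (!length(candidates)) stop("candidate set must be nonempty")
  candidates <- sort(candidates)
  fs <- recording@fs
  if (is.null(window)) {
    off <- recording@events$time[recording@events$kind == "stim_off"]
    window <- c(0, if (length(off)) off[1] else ncol(recording@data) / fs)
  }
  idx <- which(recording@channelLabels %in% electrodes)
  if (length(idx) < 2L) stop("need at least two decoding electrodes")
  i0 <- .roundHalfDown(window[1] * fs) + 1L
  i1 <- .roundHalfDown(window[2] * fs)
  X <- recording@data[idx, i0:i1, drop = FALSE]
  if (ncol(X) < fs / min(candidates))
    stop("segment shorter than one period of the lowest candidate frequency")
  rho <- vapply(candidates, function(f)
    ccaMaxCorrelation(X, makeReference(f, ncol(X), fs, harmonics)),
    numeric(1))
  names(rho) <- candidates
  best <- which.max(rho)                 # first max -> lower frequency on ties
  margin <- if (length(rho) > 1L) rho[best] - max(rho[-best]) else 0
  methods::new("CCAResult", correlations = rho,
               selected = candidates[best], margin = unname(margin))
}
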