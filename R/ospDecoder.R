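## Omission-onset recognition: windowed feature extraction, a linear-SVM
## bank (one classifier per 25 ms window), and naive-Bayes likelihood-ratio
## fusion of the ten binary decisions.
##
## The fusion statistic for a decision vector d = (d_1..d_10) is
##   P = prod_k p_k01^(1-d_k) p_k11^d_k / prod_k p_k00^(1-d_k) p_k10^d_k,
## with p_kmn = P(d_k = m | c = n); P > 1 favors the target alignment.
## P is computed in log space and exponentiated.

#' Construct the analysis window grid
#'
#' Ten contiguous half-open 25 ms windows spanning [125, 375) ms after the
#' omission onset. At 1200 Hz each window holds 30 samples.
#'
#' @param fs sampling rate, Hz (must give an integer sample count per
#'   25 ms window).
#' @return A [WindowGrid-class].
#' @export
windowGrid <- function(fs = 1200) {
  starts <- seq(0.125, 0.350, by = 0.025)
  methods::new("WindowGrid", starts = starts, ends = starts + 0.025, fs = fs,
               samplesPerWindow = as.integer(round(0.025 * fs)))
}

## column indices of window k within the concatenated feature vector
.windowSlice <- function(grid, k) {
  spw <- grid@samplesPerWindow
  ((k - 1L) * spw + 1L):(k * spw)
}

#' Extract per-electrode window features from an averaged epoch
#'
#' Cuts the [125, 375) ms span out of an onset-locked averaged epoch and
#' returns one concatenated windows-by-samples feature vector per
#' electrode (10 x 30 = 300 values at 1200 Hz); the k-th 25 ms slice feeds
#' the k-th SVM of the bank.
#'
#' @param avg numeric matrix, channels x samples (rownames = channel
#'   labels), e.g. from [averageEpochs()].
#' @param window the epoch's `c(start, end)` window in seconds relative to
#'   the onset; must cover [0.125, 0.375).
#' @param grid a [WindowGrid-class].
#' @param electrodes channel labels to keep (default all rows of `avg`).
#' @return numeric matrix, electrodes x (windows * samplesPerWindow).
#' @export
extractFeatures <- function(avg, window, grid, electrodes = rownames(avg)) {
  fs <- grid@fs
  lo <- grid@starts[1]
  hi <- grid@ends[length(grid@ends)]
  if (window[1] > lo + 1e-9 || window[2] < hi - 1e-9)
    stop("epoch too short: it must cover [125, 375) ms after the onset")
  offset <- round((lo - window[1]) * fs)
  nNeed <- length(grid@starts) * grid@samplesPerWindow
  if (!is.null(electrodes)) {
    miss <- setdiff(electrodes, rownames(avg))
    if (length(miss))
      stop("electrodes absent from the epoch: ", paste(miss, collapse = ", "))
    avg <- avg[electrodes, , drop = FALSE]
  }
  feats <- avg[, (offset + 1L):(offset + nNeed), drop = FALSE]
  dimnames(feats) <- list(rownames(avg), NULL)
  feats
}

## extract linear weights/bias from an e1071 svm fit, oriented so that
## w.x + b > 0 <=> class "1"
.linearWB <- function(fit, X, y) {
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  dv <- drop(X %*% w) + b
  ## orient by agreement with the fit's own predictions
  pred <- as.character(predict(fit, X))
  if (mean(dv[pred == "1"]) < mean(dv[pred == "0"])) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

#' Train the window-wise linear-SVM bank
#'
#' For each of the ten windows a linear SVM is trained on that window's
#' 25 ms feature slices; the misclassification penalty C is selected from a
#' logarithmic grid by 10-fold cross-validated accuracy (fold assignment
#' seeded; ties go to the smaller C).
#'
#' @param features numeric matrix, samples x (windows * samplesPerWindow),
#'   e.g. stacked rows of [extractFeatures()].
#' @param labels 0/1 vector (1 = target onset alignment).
#' @param grid a [WindowGrid-class].
#' @param cGrid candidate penalties (default 10^(-3..1): for noisy,
#'   non-separable window features the cross-validated optimum sits at
#'   small-to-moderate C, and the quadratic solver fails to converge at
#'   extreme penalties; pass a wider grid to extend the search).
#' @param nFolds cross-validation folds.
#' @param foldSeed seed fixing the fold assignment.
#' @return An [SvmBank-class].
#' @export
trainSvmBank <- function(features, labels, grid = windowGrid(),
                         cGrid = 10^(-3:1), nFolds = 10, foldSeed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the training labels")
  n <- nrow(features)
  if (n < 20L) stop("at least 20 training samples are required")
  y <- factor(labels, levels = c(0L, 1L))
  set.seed(foldSeed)
  fold <- sample(rep(seq_len(nFolds), length.out = n))
  nW <- length(grid@starts)
  weights <- matrix(0, nW, grid@samplesPerWindow)
  bias <- cost <- cvAcc <- numeric(nW)
  fits <- vector("list", nW)
  for (k in seq_len(nW)) {
    Xk <- features[, .windowSlice(grid, k), drop = FALSE]
    acc <- vapply(cGrid, function(C) {
      hits <- 0L
      for (f in seq_len(nFolds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L) next
        m <- e1071::svm(Xk[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = C, scale = FALSE)
        hits <- hits + sum(predict(m, Xk[!tr, , drop = FALSE]) == y[!tr])
      }
      hits / n
    }, numeric(1))
    best <- which.max(acc)               # first max -> smaller C on ties
    fit <- e1071::svm(Xk, y, kernel = "linear", cost = cGrid[best],
                      scale = FALSE)
    wb <- .linearWB(fit, Xk, y)
    weights[k, ] <- wb$w
    bias[k] <- wb$b
    cost[k] <- cGrid[best]
    cvAcc[k] <- acc[best]
    fits[[k]] <- fit
  }
  methods::new("SvmBank", weights = weights, bias = bias, cost = cost,
               cvAccuracy = cvAcc, grid = grid, fits = fits)
}

#' Window-k SVM decision
#'
#' d_k = 1 iff the linear decision value w_k . x + b_k is strictly
#' positive; exact zero maps to class 0.
#'
#' @param bank an [SvmBank-class].
#' @param k window index (1..10).
#' @param x numeric vector (one slice) or matrix (rows = slices) of
#'   window-k features.
#' @return integer 0/1 decision(s).
#' @export
svmDecide <- function(bank, k, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(bank@weights))
    stop(sprintf("feature slice has %d values; the bank expects %d",
                 ncol(x), ncol(bank@weights)))
  as.integer(drop(x %*% bank@weights[k, ]) + bank@bias[k] > 0)
}

## decisions for all windows: samples x windows matrix
.bankDecisions <- function(bank, features) {
  nW <- nrow(bank@weights)
  d <- matrix(0L, nrow(features), nW)
  for (k in seq_len(nW))
    d[, k] <- svmDecide(bank, k, features[, .windowSlice(bank@grid, k),
                                          drop = FALSE])
  d
}

#' Estimate the naive-Bayes fusion table
#'
#' Laplace-smoothed conditional frequencies
#' p_kmn = (count(d_k = m, c = n) + 1) / (count(c = n) + 2), guaranteeing
#' every entry lies strictly inside (0, 1).
#'
#' @param decisions integer matrix, samples x windows, values 0/1.
#' @param labels 0/1 class per sample.
#' @return A [BayesTable-class].
#' @export
fitBayesTable <- function(decisions, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  nW <- ncol(decisions)
  p <- array(0, dim = c(nW, 2, 2),
             dimnames = list(NULL, d = c("0", "1"), c = c("0", "1")))
  for (n in 0:1) {
    nc <- sum(labels == n)
    for (m in 0:1)
      p[, m + 1, n + 1] <- (colSums(decisions[labels == n, , drop = FALSE] == m) + 1) /
        (nc + 2)
  }
  methods::new("BayesTable", p = p)
}

#' Naive-Bayes likelihood-ratio fusion of the window decisions
#'
#' @param d integer vector of window decisions (0/1, length = windows).
#' @param table a [BayesTable-class].
#' @param log return the log-ratio instead of the ratio.
#' @return The fused probability ratio P (P > 1 favors target alignment).
#' @export
fusionScore <- function(d, table, log = FALSE) {
  p <- table@p
  if (length(d) != dim(p)[1])
    stop("decision vector length must match the table's window count")
  lp <- sum((1 - d) * base::log(p[, "0", "1"]) + d * base::log(p[, "1", "1"])) -
        sum((1 - d) * base::log(p[, "0", "0"]) + d * base::log(p[, "1", "0"]))
  if (log) lp else exp(lp)
}

#' Score competing onset hypotheses and pick the attended disc
#'
#' For each candidate onset set: epoch the recording at those onsets on
#' [125, 375) ms, average the first `nAvg` epochs, extract per-electrode
#' window features, run the SVM bank, fuse per window via the naive-Bayes
#' ratio, and sum the per-electrode log-ratios (electrodes act as
#' independent evidence, mirroring their role as independent training
#' samples). The candidate with the largest summed log-score wins.
#'
#' @param recording a band-passed [EEGRecording-class].
#' @param candidates named list of onset vectors (seconds), one per
#'   candidate disc.
#' @param nAvg epochs averaged per candidate.
#' @param model a [DecoderModel-class].
#' @param truncate if TRUE, `nAvg` is capped at the smallest number of
#'   usable epochs across candidates (keeping the comparison symmetric);
#'   if FALSE (default) a candidate with fewer than `nAvg` epochs is an
#'   error.
#' @return list with `selected` (index into `candidates`), `logScores`
#'   (summed log fusion score per candidate) and `nAvgUsed`.
#' @export
classifyOnsetCandidates <- function(recording, candidates, nAvg, model,
                                    truncate = FALSE) {
  if (length(candidates) < 2L) stop("need at least two candidate onset sets")
  sets <- lapply(seq_along(candidates), function(i) {
    es <- epochRecording(recording, candidates[[i]],
                         window = c(model@grid@starts[1],
                                    model@grid@ends[length(model@grid@ends)]))
    if (dim(es@epochs)[1] < nAvg && !truncate)
      stop(sprintf("candidate %s supports only %d epoch(s); nAvg = %d",
                   names(candidates)[i] %||% i, dim(es@epochs)[1], nAvg))
    es
  })
  nUse <- min(nAvg, min(vapply(sets, function(es) dim(es@epochs)[1],
                               integer(1))))
  scores <- vapply(seq_along(sets), function(i) {
    avg <- averageEpochs(sets[[i]], nUse)
    feats <- extractFeatures(avg, sets[[i]]@window, model@grid,
                             electrodes = model@electrodes)
    d <- .bankDecisions(model@bank, feats)
    sum(vapply(seq_len(nrow(d)), function(e)
      fusionScore(d[e, ], model@bayes, log = TRUE), numeric(1)))
  }, numeric(1))
  names(scores) <- names(candidates)
  list(selected = unname(which.max(scores)), logScores = scores,
       nAvgUsed = nUse)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a
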