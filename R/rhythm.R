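# Beat classification, PVC exclusion rule, PVC counting.

#' Classify beats as sinus or PVC
#'
#' A beat is a premature ventricular complex iff it is premature (RR to
#' the previous beat below `prematurityFactor` times the trailing 8-beat
#' sinus RR mean) AND its morphology correlation with the sinus template
#' (+/- 60 ms about R) is below `morphCorrMin`. The two-gate rule keeps
#' sinus arrhythmia (RR-only) and aberrant-but-on-time beats from being
#' mislabeled.
#'
#' @param x lead signal (numeric) or [ECGRecord-class].
#' @param fs sampling rate (ignored for records).
#' @param rIdx R-peak sample indices.
#' @param template an annotated [BeatTemplate-class].
#' @param lead lead name (for records).
#' @param config an [analysisConfig()].
#' @return character vector of labels ("sinus"/"pvc").
#' @export
classifyBeats <- function(x, fs, rIdx, template, lead = NULL,
                          config = analysisConfig()) {
  if (is(x, "ECGRecord")) {
    fs <- x@fs
    x <- if (is.null(lead)) x@signal[, 1] else leadSignal(x, lead)
  }
  n <- length(rIdx)
  if (n < 3) stop("need at least 3 beats to classify", call. = FALSE)
  msPS <- 1000 / fs
  fid <- template@fiducials
  rT <- round(fid["rPeak"] / msPS)
  half <- round(60 / msPS)
  w1 <- max(0, round(fid["rPeak"] / msPS) - half)
  w2 <- min(length(template@waveform) - 1, round(fid["rPeak"] / msPS) + half)
  tpSeg <- template@waveform[(w1 + 1L):(w2 + 1L)]

  corr <- vapply(seq_len(n), function(i) {
    lo <- rIdx[i] + w1 - rT; hi <- rIdx[i] + w2 - rT
    if (lo < 1 || hi > length(x)) return(NA_real_)
    suppressWarnings(cor(tpSeg, x[lo:hi]))
  }, numeric(1))

  rr <- diff(rIdx) * msPS
  labels <- rep("sinus", n)
  sinusRR <- numeric(0)
  for (i in 2:n) {
    premature <- length(sinusRR) >= 1 &&
      rr[i - 1] < config$prematurityFactor * mean(sinusRR)
    if (premature && !is.na(corr[i]) && corr[i] < config$morphCorrMin)
      labels[i] <- "pvc"
    if (labels[i] == "sinus" && labels[i - 1] == "sinus") {
      sinusRR <- c(sinusRR, rr[i - 1])
      if (length(sinusRR) > 8) sinusRR <- tail(sinusRR, 8)
    }
  }
  labels
}

#' PVC exclusion mask
#'
#' Implements the analysis exclusion rule: every PVC is excluded; its
#' succeeding beat is excluded; its preceding sinus beat is excluded iff
#' the PVC's R wave falls before that beat's T-wave end. The mask is
#' idempotent and order-independent; consecutive PVCs chain without
#' double counting.
#'
#' @param labels per-beat labels ("sinus"/"pvc").
#' @param rTimesMs beat R times, ms.
#' @param tEndMs per-beat absolute T-end times, ms (NA tolerated: the
#'   preceding-beat condition then falls back on `rTimesMs + fallbackQt`).
#' @param fallbackQt QT assumed when a T end is unavailable, ms.
#' @return sorted integer indices of excluded beats (possibly empty).
#' @export
exclusionMask <- function(labels, rTimesMs, tEndMs = NULL,
                          fallbackQt = 400) {
  n <- length(labels)
  if (n == 0) return(integer(0))
  if (is.null(tEndMs)) tEndMs <- rep(NA_real_, n)
  tEnd <- ifelse(is.na(tEndMs), rTimesMs + fallbackQt, tEndMs)
  excl <- logical(n)
  for (i in which(labels == "pvc")) {
    excl[i] <- TRUE
    if (i < n) excl[i + 1] <- TRUE
    if (i > 1 && labels[i - 1] == "sinus" && rTimesMs[i] < tEnd[i - 1])
      excl[i - 1] <- TRUE
  }
  which(excl)
}

#' PVC incidence profile
#'
#' Counts PVCs in consecutive windows (default 5-min windows over the 30
#' min after occlusion), the maximal PVC rate over 1-min sliding
#' windows, and the coupling interval of each PVC (RR from the prior
#' sinus beat). Runs of >= 3 consecutive PVCs are reported as
#' nonsustained VT episodes.
#'
#' @param labels per-beat labels.
#' @param rTimesMs beat R times, ms (absolute record time).
#' @param occlusionTimeS event clock origin, s.
#' @param windowS counting window, s (default 300).
#' @param spanS total span after occlusion, s (default 1800).
#' @param recordEndS end of the available record, s; when the span
#'   overruns it, counts are truncated with a warning and flag.
#' @return list of class `RhythmReport`: `pvcCountPerWindow`,
#'   `maxPvcRate` (PVCs/min), `couplingIntervals` (ms),
#'   `excludedBeatIndices`, `nsvtRuns`, `truncated`.
#' @export
pvcProfile <- function(labels, rTimesMs, occlusionTimeS, windowS = 300,
                       spanS = 1800, recordEndS = max(rTimesMs) / 1000) {
  occMs <- occlusionTimeS * 1000
  truncated <- FALSE
  if (occlusionTimeS + spanS > recordEndS + 1e-9) {
    warning("PVC counting span exceeds the record; truncating")
    truncated <- TRUE
    spanS <- max(0, recordEndS - occlusionTimeS)
  }
  edges <- seq(0, spanS, by = windowS)
  if (length(edges) < 2) edges <- c(0, spanS)
  pvcT <- rTimesMs[labels == "pvc"] - occMs
  pvcT <- pvcT[pvcT >= 0 & pvcT <= spanS * 1000]
  counts <- as.integer(table(cut(pvcT, breaks = edges * 1000,
                                 include.lowest = TRUE)))
  # maximal rate over 1-min sliding windows (1-s step)
  maxRate <- 0
  if (length(pvcT) && spanS >= 60) {
    starts <- seq(0, spanS - 60, by = 1) * 1000
    cnt <- vapply(starts, function(s)
      sum(pvcT >= s & pvcT < s + 60000), numeric(1))
    maxRate <- max(cnt)
  } else if (length(pvcT)) maxRate <- length(pvcT) / max(spanS / 60, 1e-9)
  # coupling interval: RR from the prior sinus beat
  coup <- numeric(0)
  for (i in which(labels == "pvc"))
    if (i > 1 && labels[i - 1] == "sinus")
      coup <- c(coup, rTimesMs[i] - rTimesMs[i - 1])
  # nsVT: runs of >= 3 consecutive PVCs
  rl <- rle(labels == "pvc")
  runEnds <- cumsum(rl$lengths)
  nsvt <- which(rl$values & rl$lengths >= 3)
  nsvtRuns <- lapply(nsvt, function(k)
    (runEnds[k] - rl$lengths[k] + 1L):runEnds[k])
  out <- list(pvcCountPerWindow = counts, maxPvcRate = maxRate,
              couplingIntervals = coup,
              excludedBeatIndices = exclusionMask(labels, rTimesMs),
              nsvtRuns = nsvtRuns, truncated = truncated,
              windowS = windowS, spanS = spanS)
  class(out) <- "RhythmReport"
  out
}

#' @export
print.RhythmReport <- function(x, ...) {
  cat("RhythmReport:", sum(x$pvcCountPerWindow), "PVCs in",
      length(x$pvcCountPerWindow), "windows of", x$windowS, "s; max rate",
      sprintf("%.2f", x$maxPvcRate), "PVCs/min\n")
  invisible(x)
}
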