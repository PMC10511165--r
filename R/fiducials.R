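# R-peak detection and fiducial-segment-averaging QT measurement.

#' BeatSet: detected beats with per-beat fiducials
#'
#' @slot beats data.frame with one row per beat: `r_time_ms`,
#'   `qrs_on_ms`, `t_end_ms` (absolute, ms), `qt_ms`, `corr_on`,
#'   `corr_tend` (segment-alignment correlations), `aligned` (logical),
#'   `label` ("sinus", "pvc", or "unclassified").
#' @slot lead lead name.
#' @slot fs sampling rate, Hz.
#' @exportClass BeatSet
setClass("BeatSet",
  representation(beats = "data.frame", lead = "character", fs = "numeric"))

setValidity("BeatSet", function(object) {
  b <- object@beats
  msg <- character(0)
  if (!all(c("r_time_ms", "qt_ms", "aligned", "label") %in% names(b)))
    msg <- c(msg, "beats must contain r_time_ms, qt_ms, aligned, label")
  else if (nrow(b) > 1 && any(diff(b$r_time_ms) <= 0))
    msg <- c(msg, "r_time_ms must be strictly increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BeatSet", function(object) {
  b <- object@beats
  cat("BeatSet [", object@lead, "]:", nrow(b), "beats,",
      sum(b$aligned), "aligned,", sum(b$label == "pvc"), "PVC\n")
})

#' @rdname accessors
setMethod("rTimes", "BeatSet", function(x) x@beats$r_time_ms)
#' @rdname accessors
setMethod("beatLabels", "BeatSet", function(x) x@beats$label)
#' @rdname accessors
setMethod("qtValues", "BeatSet", function(x) x@beats$qt_ms)

## ---- filters and correlation helpers ----

# Zero-phase 4th-order Butterworth low-pass at 50 Hz (skipped when the
# Nyquist frequency leaves no room for it).
lowpass50 <- function(x, fs) {
  wc <- 50 / (fs / 2)
  if (wc >= 0.99) return(x)
  bf <- signal::butter(4, wc, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Zero-phase 2nd-order high-pass for baseline-wander removal.
highpassBaseline <- function(x, fs, hz) {
  if (hz <= 0) return(x)
  bf <- signal::butter(2, hz / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

# Zero-phase mains notch (2nd-order Butterworth band-stop, +/- 2 Hz).
notchMains <- function(x, fs, hz) {
  if (hz <= 0 || (hz + 2) >= fs / 2 * 0.99) return(x)
  bf <- signal::butter(2, c(hz - 2, hz + 2) / (fs / 2), type = "stop")
  as.numeric(signal::filtfilt(bf, x))
}

# Normalized cross-correlation of template `tp` (length m) against an
# extended segment `ext` (length m + 2L), at integer lags -L..L.
ccNorm <- function(tp, ext) {
  m <- length(tp)
  K <- length(ext) - m + 1L
  tpc <- tp - mean(tp)
  den1 <- sqrt(sum(tpc^2))
  cs1 <- c(0, cumsum(ext))
  cs2 <- c(0, cumsum(ext^2))
  k <- seq_len(K)
  s1 <- cs1[k + m] - cs1[k]
  s2 <- cs2[k + m] - cs2[k]
  dot <- vapply(k, function(j) sum(ext[j:(j + m - 1)] * tp), numeric(1))
  num <- dot - s1 * mean(tp)
  den <- den1 * sqrt(pmax(s2 - s1^2 / m, 0))
  cc <- ifelse(den > 0, num / den, 0)
  cc
}

# Matched sub-sample refinement: after integer cross-correlation
# alignment, one Newton step on the squared-difference objective using
# the template derivative. For a beat segment seg(t) ~ tp(t - eps),
# seg - tp ~ -eps * tp', so eps_hat = -sum(tp' * (seg - tp)) / sum(tp'^2).
# Scale- and offset-insensitive via mean removal; clamped to one sample.
refineShift <- function(tp, ext, k, maxCorr = 4) {
  m <- length(tp)
  tpc <- tp - mean(tp)
  tpd <- c(tp[2] - tp[1], (tp[-(1:2)] - tp[-((m - 1):m)]) / 2,
           tp[m] - tp[m - 1])
  den <- sum(tpd^2)
  if (den <= 0) return(0)
  eps <- 0
  for (iter in 1:3) {
    # fractional segment extraction by linear interpolation
    off <- k + eps
    j0 <- floor(off); f <- off - j0
    if (j0 < 1 || j0 + m > length(ext)) break
    seg <- ext[j0:(j0 + m - 1L)] * (1 - f) + ext[(j0 + 1L):(j0 + m)] * f
    step <- -sum(tpd * ((seg - mean(seg)) - tpc)) / den
    eps <- max(-maxCorr, min(maxCorr, eps + step))
    if (abs(step) < 1e-3) break
  }
  eps
}

# Sub-sample peak of a correlation curve by parabolic interpolation.
# Returns c(lag, corr) with lag in samples relative to the curve center.
parabolicPeak <- function(cc) {
  k <- which.max(cc)
  L <- (length(cc) - 1) / 2
  frac <- 0
  if (k > 1 && k < length(cc)) {
    den <- cc[k - 1] - 2 * cc[k] + cc[k + 1]
    if (den < 0) frac <- max(-0.5, min(0.5, 0.5 * (cc[k - 1] - cc[k + 1]) / den))
  }
  c(lag = (k - 1 - L) + frac, corr = cc[k])
}

## ---- R-peak detection ----

#' Detect R peaks (Pan-Tompkins-class detector)
#'
#' Band-pass (5-15 Hz, zero-phase), differentiate, square, integrate
#' over a 150-ms window, threshold adaptively, and enforce a 200-ms
#' refractory period. Polarity-insensitive (squared stage), so inverted
#' ectopic complexes are detected.
#'
#' @param x numeric lead signal, mV, or an [ECGRecord-class] (first lead).
#' @param fs sampling rate, Hz (ignored for records).
#' @return strictly increasing integer sample indices of R peaks.
#' @export
detectRPeaks <- function(x, fs) {
  if (is(x, "ECGRecord")) { fs <- x@fs; x <- x@signal[, 1] }
  if (fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  if (length(x) < 2 * fs) stop("need at least 2 s of signal", call. = FALSE)
  if (!any(is.finite(x)) || diff(range(x, na.rm = TRUE)) < 1e-9)
    stop("no beats detectable: flat or empty signal", call. = FALSE)
  x[!is.finite(x)] <- 0
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, x))
  sq <- c(0, diff(bp))^2
  w <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.25 * quantile(integ, 0.995, names = FALSE)
  if (thr <= 0) stop("no beats detectable: flat or empty signal",
                     call. = FALSE)
  above <- integ > thr
  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  regions <- cbind(starts[rl$values], ends[rl$values])
  if (nrow(regions) == 0)
    stop("no beats detectable: flat or empty signal", call. = FALSE)
  # merge regions separated by < 100 ms
  gapMin <- round(0.1 * fs)
  merged <- list(); cur <- regions[1, ]
  for (i in seq_len(nrow(regions))[-1]) {
    if (regions[i, 1] - cur[2] < gapMin) cur[2] <- regions[i, 2]
    else { merged[[length(merged) + 1L]] <- cur; cur <- regions[i, ] }
  }
  merged[[length(merged) + 1L]] <- cur
  peaks <- vapply(merged, function(rg) {
    i1 <- max(1L, rg[1] - round(0.05 * fs))
    i2 <- min(length(bp), rg[2] + round(0.05 * fs))
    i1 + which.max(abs(bp[i1:i2])) - 1L
  }, numeric(1))
  # refractory: keep the stronger of peaks closer than 200 ms
  refr <- round(0.2 * fs)
  keep <- integer(0)
  for (p in sort(unique(peaks))) {
    if (length(keep) && p - keep[length(keep)] < refr) {
      if (abs(bp[p]) > abs(bp[keep[length(keep)]]))
        keep[length(keep)] <- p
    } else keep <- c(keep, p)
  }
  as.integer(keep)
}

## ---- template construction and annotation ----

#' Build an averaged beat template
#'
#' Pointwise mean of sinus beats aligned by cross-correlation about the
#' R peak (within +/- `alignSearchMs`). Beats correlating below
#' `templateCorrMin` with the running average (ectopics, artifacts) are
#' excluded; fewer than `minTemplateBeats` usable beats is an error.
#'
#' @param x lead signal (numeric) or an [ECGRecord-class].
#' @param fs sampling rate (ignored for records).
#' @param rIdx R-peak sample indices from [detectRPeaks()].
#' @param lead lead name to use when `x` is a record.
#' @param config an [analysisConfig()].
#' @return a [BeatTemplate-class] (fiducials unset; see
#'   [annotateTemplate()]).
#' @export
buildTemplate <- function(x, fs, rIdx, lead = NULL,
                          config = analysisConfig()) {
  if (is(x, "ECGRecord")) {
    fs <- x@fs
    x <- if (is.null(lead)) x@signal[, 1] else leadSignal(x, lead)
  }
  rrMed <- median(diff(rIdx)) / fs * 1000
  pre <- round(min(350, 0.40 * rrMed) / 1000 * fs)
  post <- round(min(620, 0.72 * rrMed) / 1000 * fs)
  L <- round(config$alignSearchMs / 1000 * fs)
  usable <- rIdx[rIdx - pre - L >= 1 & rIdx + post + L <= length(x)]
  if (length(usable) < config$minTemplateBeats)
    stop("insufficient beats for template (need >= ",
         config$minTemplateBeats, ")", call. = FALSE)
  if (length(usable) > config$maxTemplateBeats)
    usable <- usable[round(seq(1, length(usable),
                               length.out = config$maxTemplateBeats))]
  shift <- numeric(length(usable))
  extract <- function() {
    # fractional-shift extraction by linear interpolation keeps the
    # average sharp (integer alignment smears by up to half a sample)
    t(vapply(seq_along(usable), function(i) {
      off <- usable[i] + shift[i]
      j0 <- floor(off); f <- off - j0
      lo <- j0 - pre
      seg0 <- x[lo:(j0 + post)]
      seg1 <- x[(lo + 1L):(j0 + post + 1L)]
      seg0 * (1 - f) + seg1 * f
    }, numeric(pre + post + 1)))
  }
  B <- extract()
  tmpl <- apply(B, 2, median)
  include <- rep(TRUE, length(usable))
  for (iter in 1:3) {
    corr <- numeric(length(usable))
    for (i in seq_along(usable)) {
      c0 <- usable[i]
      ext <- x[(c0 - pre - L):(c0 + post + L)]
      cc <- ccNorm(tmpl, ext)
      k <- which.max(cc)
      lag <- (k - 1 - L) + refineShift(tmpl, ext, k, maxCorr = 1)
      shift[i] <- max(-L, min(L - 1, lag))
      corr[i] <- cc[k]
    }
    include <- corr >= config$templateCorrMin
    if (sum(include) < config$minTemplateBeats)
      stop("insufficient beats for template (need >= ",
           config$minTemplateBeats, ")", call. = FALSE)
    B <- extract()
    tmpl <- colMeans(B[include, , drop = FALSE])
  }
  new("BeatTemplate", waveform = tmpl, fs = fs,
      fiducials = c(qrsOn = NA_real_, rPeak = pre / fs * 1000,
                    qrsOff = NA_real_, tPeak = NA_real_, tEnd = NA_real_),
      nBeats = as.integer(sum(include)))
}

#' Tangent-method T-wave end
#'
#' The T end is the intersection of the tangent at the steepest
#' post-peak slope (toward baseline) with the baseline level, with
#' linear sub-sample interpolation. Works for positive and inverted T
#' waves.
#'
#' @param waveform numeric beat or template waveform, mV.
#' @param fs sampling rate, Hz.
#' @param tPeakHint approximate T-peak time, ms from waveform start
#'   (refined locally within +/- 10 ms).
#' @param baselineLevel baseline amplitude, mV.
#' @param searchMs search window length after the T peak, ms.
#' @return T-end time in ms from waveform start.
#' @examples
#' fs <- 1000; t <- seq(0, 599) # Gaussian T: closed-form end = 300 + 2*40
#' w <- exp(-(t - 300)^2 / (2 * 40^2))
#' tangentTEnd(w, fs, tPeakHint = 300)
#' @export
tangentTEnd <- function(waveform, fs, tPeakHint, baselineLevel = 0,
                        searchMs = 200) {
  n <- length(waveform)
  tp0 <- round(tPeakHint / 1000 * fs) + 1L
  if (tp0 < 2 || tp0 > n - 2)
    stop("T peak outside waveform", call. = FALSE)
  h <- round(0.010 * fs)
  lo <- max(2L, tp0 - h); hi <- min(n - 1L, tp0 + h)
  tp <- lo + which.max(abs(waveform[lo:hi] - baselineLevel)) - 1L
  sgn <- sign(waveform[tp] - baselineLevel)
  if (sgn == 0) stop("flat T wave: no downslope", call. = FALSE)
  hi2 <- min(n - 1L, tp + round(searchMs / 1000 * fs))
  if (hi2 <= tp + 1) stop("no samples after T peak", call. = FALSE)
  idx <- (tp + 1L):hi2
  d <- (waveform[idx + 1L] - waveform[idx - 1L]) * fs / 2000   # mV/ms
  s <- idx[which.min(sgn * d)]
  slope <- (waveform[s + 1L] - waveform[s - 1L]) * fs / 2000
  if (sgn * slope >= 0)
    stop("no downslope after T peak", call. = FALSE)
  tS <- (s - 1) * 1000 / fs
  tEnd <- tS + (waveform[s] - baselineLevel) / (-slope)
  if (!is.finite(tEnd) || tEnd > (tp - 1) * 1000 / fs + searchMs + 50)
    stop("tangent does not cross baseline within the search window",
         call. = FALSE)
  tEnd
}

#' Annotate a beat template with fiducials
#'
#' QRS onset and offset are derivative-threshold crossings (last/first
#' sustained sample with |dV/dt| below 2% of the maximum), the T peak is
#' the largest baseline-referenced excursion after the QRS, and the T
#' end comes from [tangentTEnd()]. The baseline level is the PR-segment
#' median.
#'
#' @param template a [BeatTemplate-class].
#' @param config an [analysisConfig()].
#' @return the template with its `fiducials` slot filled.
#' @export
annotateTemplate <- function(template, config = analysisConfig()) {
  x <- template@waveform
  fs <- template@fs
  msPS <- 1000 / fs
  n <- length(x)
  rIdxT <- which.max(abs(x - median(x)))
  d <- c(0, diff(x)) * fs / 1000
  thr <- 0.02 * max(abs(d))
  runMin <- max(2L, round(0.008 * fs))
  below <- abs(d) < thr

  # onset: scan backward from R for the first sustained below-threshold run
  onIdx <- NA_integer_
  i <- rIdxT - 1L
  while (i > runMin) {
    if (all(below[(i - runMin + 1L):i])) { onIdx <- i; break }
    i <- i - 1L
  }
  if (is.na(onIdx)) stop("template annotation failed: no QRS onset",
                         call. = FALSE)
  # offset: forward, requiring a prior above-threshold excursion (S wave)
  offIdx <- NA_integer_
  i <- rIdxT + 1L
  seenAbove <- FALSE
  while (i <= n - runMin) {
    if (!below[i]) seenAbove <- TRUE
    else if (seenAbove && all(below[i:(i + runMin - 1L)])) {
      offIdx <- i; break
    }
    i <- i + 1L
  }
  if (is.na(offIdx)) stop("template annotation failed: no QRS offset",
                          call. = FALSE)

  prIdx <- onIdx + round(config$prWindowMs / msPS)
  prIdx <- pmax(1L, pmin(n, prIdx))
  baseline <- median(x[prIdx[1]:prIdx[2]])

  tLo <- offIdx + round(130 / msPS)
  tHi <- min(n - 2L, offIdx + round(450 / msPS))
  if (tLo >= tHi) stop("template annotation failed: no room for T wave",
                       call. = FALSE)
  exc <- abs(x[tLo:tHi] - baseline)
  if (max(exc) < 0.02 * abs(x[rIdxT] - baseline))
    stop("no T wave found (amplitude below threshold)", call. = FALSE)
  tpIdx <- tLo + which.max(exc) - 1L
  tEnd <- tangentTEnd(x, fs, tPeakHint = (tpIdx - 1) * msPS,
                      baselineLevel = baseline,
                      searchMs = config$tEndSearchMs)
  fid <- c(qrsOn = (onIdx - 1) * msPS, rPeak = (rIdxT - 1) * msPS,
           qrsOff = (offIdx - 1) * msPS, tPeak = (tpIdx - 1) * msPS,
           tEnd = tEnd)
  if (!(fid["qrsOn"] < fid["rPeak"] && fid["rPeak"] < fid["tPeak"] &&
        fid["tPeak"] < fid["tEnd"]))
    stop("template annotation failed: fiducial ordering violated",
         call. = FALSE)
  out <- template
  out@fiducials <- fid
  validObject(out)
  out
}

## ---- per-beat QT measurement ----

#' Measure per-beat QT by fiducial segment averaging
#'
#' For each beat, the template's QRS-onset neighborhood (`onsetWinMs`)
#' and T-end neighborhood (`tEndWinMs`) are re-aligned to the beat by
#' normalized cross-correlation within +/- `alignSearchMs`, with
#' parabolic sub-sample refinement. Per-beat QT = (template T end +
#' T-end shift) - (template QRS onset + onset shift). Beats whose
#' alignment correlation falls below `beatCorrMin` are flagged invalid,
#' never dropped.
#'
#' @param x lead signal (numeric) or [ECGRecord-class].
#' @param fs sampling rate (ignored for records).
#' @param rIdx R-peak sample indices.
#' @param template an annotated [BeatTemplate-class].
#' @param lead lead name (selects the record column; also stored).
#' @param config an [analysisConfig()].
#' @param t0 record start time, s (taken from the record when given).
#' @return a [BeatSet-class] with per-beat QT, fiducials and alignment
#'   quality; labels are "unclassified" (see [classifyBeats()]).
#' @export
measureQT <- function(x, fs, rIdx, template, lead = "II",
                      config = analysisConfig(), t0 = 0) {
  if (is(x, "ECGRecord")) {
    fs <- x@fs; t0 <- x@t0
    x <- leadSignal(x, lead)
  }
  if (!isTRUE(all.equal(fs, template@fs)))
    stop("template and record sampling rates differ", call. = FALSE)
  fid <- template@fiducials
  if (anyNA(fid)) stop("template is not annotated", call. = FALSE)
  msPS <- 1000 / fs
  rT <- round(fid["rPeak"] / msPS)          # template R, 0-based samples
  L <- round(config$alignSearchMs / 1000 * fs)

  segIdx <- function(centerMs, winMs) {
    c0 <- round(centerMs / msPS)
    half <- round(winMs / 2 / msPS)
    (c0 - half):(c0 + half)
  }
  onWin <- segIdx(fid["qrsOn"], config$onsetWinMs)
  # The T-end neighborhood is anchored on the T peak (quarter before,
  # three quarters after): the peak-to-downslope region is shape-rich,
  # whereas the late tail is nearly shift/scale degenerate.
  teWin <- segIdx(fid["tPeak"] + config$tEndWinMs / 4, config$tEndWinMs)
  onWin <- onWin[onWin >= 0 & onWin < length(template@waveform)]
  teWin <- teWin[teWin >= 0 & teWin < length(template@waveform)]
  tpOn <- template@waveform[onWin + 1L]
  tpTe <- template@waveform[teWin + 1L]

  n <- length(rIdx)
  qt <- rep(NA_real_, n); dOn <- rep(NA_real_, n); dTe <- rep(NA_real_, n)
  cOn <- rep(NA_real_, n); cTe <- rep(NA_real_, n)
  alignSeg <- function(win, tp, r0) {
    lo <- r0 + win[1] - rT - L
    hi <- r0 + win[length(win)] - rT + L
    if (lo < 1 || hi > length(x)) return(NULL)
    ext <- x[lo:hi]
    cc <- ccNorm(tp, ext)
    k <- which.max(cc)
    c(lag = (k - 1 - L) + refineShift(tp, ext, k), corr = cc[k])
  }
  for (i in seq_len(n)) {
    r0 <- rIdx[i]
    pOn <- alignSeg(onWin, tpOn, r0)
    pTe <- alignSeg(teWin, tpTe, r0)
    if (is.null(pOn) || is.null(pTe)) next
    dOn[i] <- pOn["lag"] * msPS; cOn[i] <- pOn["corr"]
    dTe[i] <- pTe["lag"] * msPS; cTe[i] <- pTe["corr"]
    qt[i] <- (fid["tEnd"] + dTe[i]) - (fid["qrsOn"] + dOn[i])
  }
  aligned <- !is.na(cOn) & !is.na(cTe) &
    cOn >= config$beatCorrMin & cTe >= config$beatCorrMin
  rMs <- t0 * 1000 + (rIdx - 1) * msPS
  beats <- data.frame(
    r_time_ms = rMs,
    qrs_on_ms = rMs + (fid["qrsOn"] - fid["rPeak"]) + ifelse(is.na(dOn), 0, dOn),
    t_end_ms = rMs + (fid["tEnd"] - fid["rPeak"]) + ifelse(is.na(dTe), 0, dTe),
    qt_ms = qt, corr_on = cOn, corr_tend = cTe,
    aligned = aligned, label = "unclassified",
    row.names = NULL
  )
  new("BeatSet", beats = beats, lead = lead, fs = fs)
}
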