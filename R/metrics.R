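# BVR (STVQT) and companion repolarization metrics.

# Admissible successive pairs: consecutive beats that are both valid,
# with no excluded beat bridged over.
admissiblePairs <- function(valid) {
  n <- length(valid)
  if (n < 2) return(integer(0))
  which(valid[-n] & valid[-1])
}

stvCore <- function(qt, valid, denominator = "beats") {
  if (sum(valid) < 2)
    stop("need at least 2 valid beats for STV", call. = FALSE)
  pairs <- admissiblePairs(valid)
  s <- sum(abs(qt[pairs + 1L] - qt[pairs]))
  nn <- if (denominator == "beats") sum(valid) else max(length(pairs), 1L)
  s / (nn * sqrt(2))
}

#' @describeIn stv STV of a numeric per-beat QT vector.
#' @param valid logical mask of analyzable beats; differences are taken
#'   only between consecutive valid beats (never across an exclusion
#'   gap).
#' @param denominator `"beats"` divides by the number of QT intervals
#'   analyzed (the printed formula's "n beats"; default) or
#'   `"differences"` by the number of successive differences.
#' @export
setMethod("stv", "numeric",
  function(x, valid = rep(TRUE, length(x)),
           denominator = c("beats", "differences"), ...) {
    stvCore(x, valid & is.finite(x), match.arg(denominator))
  })

#' @describeIn stv STV of a [QTSeries-class]; uses its validity mask.
#' @export
setMethod("stv", "QTSeries",
  function(x, denominator = c("beats", "differences"), ...) {
    stvCore(x@qt, x@valid, match.arg(denominator))
  })

poincareCore <- function(qt, valid) {
  if (sum(valid) < 2)
    stop("need at least 2 valid beats for Poincare pairs", call. = FALSE)
  pairs <- admissiblePairs(valid)
  data.frame(qt = qt[pairs], qtNext = qt[pairs + 1L])
}

#' @describeIn poincarePairs pairs from a numeric QT vector.
#' @param valid logical mask of analyzable beats.
#' @export
setMethod("poincarePairs", "numeric",
  function(x, valid = rep(TRUE, length(x)), ...)
    poincareCore(x, valid & is.finite(x)))

#' @describeIn poincarePairs pairs from a [QTSeries-class].
#' @export
setMethod("poincarePairs", "QTSeries",
  function(x, ...) poincareCore(x@qt, x@valid))

#' QT dispersion across leads
#'
#' Inter-lead range (max - min) of the per-lead segment-mean QT.
#'
#' @param perLeadMeanQt numeric vector of per-lead mean QT, ms (NA leads
#'   dropped).
#' @return dispersion in ms.
#' @export
qtDispersion <- function(perLeadMeanQt) {
  v <- perLeadMeanQt[is.finite(perLeadMeanQt)]
  if (length(v) < 2)
    stop("need mean QT on at least 2 leads", call. = FALSE)
  max(v) - min(v)
}

## ---- per-segment analysis engine ----

#' Extract a time window of a record
#'
#' @param record an [ECGRecord-class].
#' @param startS,endS window boundaries in absolute seconds (relative to
#'   the record's clock, honoring `t0`).
#' @return an [ECGRecord-class] whose `t0` is `startS`.
#' @export
extractWindow <- function(record, startS, endS) {
  i1 <- max(1L, floor((startS - record@t0) * record@fs) + 1L)
  i2 <- min(nSamples(record), ceiling((endS - record@t0) * record@fs))
  if (i2 <= i1) stop("empty window", call. = FALSE)
  new("ECGRecord", fs = record@fs,
      signal = record@signal[i1:i2, , drop = FALSE],
      t0 = record@t0 + (i1 - 1) / record@fs)
}

# Per-beat ST level: median amplitude over the J+stWindow relative to
# the same beat's PR-segment median; averaged across analyzable sinus
# beats. Returns c(level, n) or NULL when no beat is measurable.
stLevelLead <- function(x, fs, rIdx, template, labels, aligned,
                        config = analysisConfig()) {
  fid <- template@fiducials
  msPS <- 1000 / fs
  jOff <- round((fid["qrsOff"] - fid["rPeak"]) / msPS)
  onOff <- round((fid["qrsOn"] - fid["rPeak"]) / msPS)
  stIdx <- round(config$stWindowMs / msPS)
  prIdx <- round(config$prWindowMs / msPS)
  lv <- c()
  for (i in seq_along(rIdx)) {
    if (labels[i] != "sinus" || !aligned[i]) next
    st1 <- rIdx[i] + jOff + stIdx[1]; st2 <- rIdx[i] + jOff + stIdx[2]
    pr1 <- rIdx[i] + onOff + prIdx[1]; pr2 <- rIdx[i] + onOff + prIdx[2]
    if (st1 < 1 || st2 > length(x) || pr1 < 1 || pr2 > length(x)) next
    lv <- c(lv, median(x[st1:st2]) - median(x[pr1:pr2]))
  }
  if (!length(lv)) return(NULL)
  c(level = mean(lv), n = length(lv))
}

#' Analyze one lead of one segment
#'
#' Runs the full per-lead pipeline: optional 50-Hz low-pass, R-peak
#' detection, template building and annotation, beat classification,
#' per-beat QT measurement, PVC exclusion, and the segment metrics (BVR,
#' mean QT, heart rate from sinus beats, ST level, PVC count).
#'
#' @param record an [ECGRecord-class].
#' @param lead lead name.
#' @param config an [analysisConfig()].
#' @return list of class `SegmentAnalysis`: `lead`, `beats`
#'   ([BeatSet-class]), `template`, `qts` ([QTSeries-class] with the
#'   post-exclusion validity mask), `excluded`, `bvr`, `meanQt`, `hr`,
#'   `stLevel`, `pvcCount`, `nValid`.
#' @export
analyzeSegment <- function(record, lead = leadNames(record)[1],
                           config = analysisConfig()) {
  fs <- record@fs
  x <- leadSignal(record, lead)
  x <- highpassBaseline(x, fs, config$highpassHz)
  x <- notchMains(x, fs, config$notchHz)
  if (config$lowpass50) x <- lowpass50(x, fs)
  rIdx <- detectRPeaks(x, fs)
  template <- buildTemplate(x, fs, rIdx, config = config)
  template <- annotateTemplate(template, config)
  labels <- classifyBeats(x, fs, rIdx, template, config = config)
  bs <- measureQT(x, fs, rIdx, template, lead = lead, config = config,
                  t0 = record@t0)
  bs@beats$label <- labels
  excl <- exclusionMask(labels, bs@beats$r_time_ms, bs@beats$t_end_ms)
  valid <- bs@beats$aligned & labels == "sinus" &
    !(seq_along(labels) %in% excl) & is.finite(bs@beats$qt_ms)
  qts <- new("QTSeries", beatTimes = bs@beats$r_time_ms,
             qt = bs@beats$qt_ms, valid = valid, lead = lead)
  rr <- diff(bs@beats$r_time_ms)
  sinusPair <- labels[-length(labels)] == "sinus" & labels[-1] == "sinus"
  hr <- if (any(sinusPair)) 60000 / mean(rr[sinusPair]) else NA_real_
  stl <- stLevelLead(x, fs, rIdx, template, labels, bs@beats$aligned,
                     config)
  out <- list(
    lead = lead, beats = bs, template = template, qts = qts,
    excluded = excl,
    bvr = if (sum(valid) >= 2) stvCore(qts@qt, valid, config$denominator)
          else NA_real_,
    meanQt = if (any(valid)) mean(qts@qt[valid]) else NA_real_,
    hr = hr,
    stLevel = if (is.null(stl)) NA_real_ else stl[["level"]],
    pvcCount = sum(labels == "pvc"),
    nValid = sum(valid)
  )
  class(out) <- "SegmentAnalysis"
  out
}

#' @export
print.SegmentAnalysis <- function(x, ...) {
  cat("SegmentAnalysis [", x$lead, "]:", nrow(x$beats@beats), "beats,",
      x$nValid, "valid; BVR", sprintf("%.3f", x$bvr), "ms; mean QT",
      sprintf("%.1f", x$meanQt), "ms; HR", sprintf("%.1f", x$hr),
      "bpm;", x$pvcCount, "PVC\n")
  invisible(x)
}

#' ST-segment deviation between two analyzed segments
#'
#' Per lead, the deviation is the ST level of the segment minus the ST
#' level of the baseline segment (each already referenced to its own
#' PR segment).
#'
#' @param seg,baseline `SegmentAnalysis` objects for the same lead, or
#'   named numeric vectors of per-lead ST levels.
#' @return list with `signed` and `absolute` deviation, mV.
#' @export
stDeviation <- function(seg, baseline) {
  lv <- function(a) if (inherits(a, "SegmentAnalysis")) a$stLevel else a
  d <- lv(seg) - lv(baseline)
  list(signed = d, absolute = abs(d))
}

#' Per-segment, multi-lead repolarization metrics
#'
#' Assembles the per-lead metric bundle over a time window: BVR, mean
#' QT, ST deviation versus a baseline window, plus segment-level heart
#' rate, QT dispersion, cumulative BVR, cumulative absolute ST
#' deviation, maximal BVR and PVC count. Leads whose analysis fails are
#' recorded as absent with the failure reason; metrics aggregate over
#' the remaining leads.
#'
#' @param record an [ECGRecord-class].
#' @param window `c(start, end)` in seconds (absolute), or `NULL` for
#'   the whole record (windows of at least 30 s are expected; 60 s is
#'   the study convention).
#' @param leads lead names to analyze.
#' @param config an [analysisConfig()].
#' @param baselineWindow optional `c(start, end)` of a baseline window
#'   used for ST deviation.
#' @return list of class `SegmentMetrics`: `perLead` (data.frame with
#'   lead, bvr, mean_qt, st_dev, n_valid, pvc_count, status), `hr`,
#'   `qtDispersion`, `cumulativeBvr`, `cumulativeSt`, `maxBvr`,
#'   `pvcCount`.
#' @export
segmentMetrics <- function(record, window = NULL,
                           leads = leadNames(record),
                           config = analysisConfig(),
                           baselineWindow = NULL) {
  seg <- if (is.null(window)) record else
    extractWindow(record, window[1], window[2])
  if (recordDuration(seg) < 30)
    warning("window shorter than 30 s; metrics may be unstable")
  base <- if (is.null(baselineWindow)) NULL else
    extractWindow(record, baselineWindow[1], baselineWindow[2])

  rows <- list(); analyses <- list()
  for (ld in leads) {
    a <- tryCatch(analyzeSegment(seg, ld, config), error = function(e) e)
    if (inherits(a, "error")) {
      rows[[ld]] <- data.frame(lead = ld, bvr = NA_real_,
                               mean_qt = NA_real_, st_dev = NA_real_,
                               n_valid = 0L, pvc_count = NA_integer_,
                               status = conditionMessage(a))
      next
    }
    stdev <- NA_real_
    if (!is.null(base)) {
      b <- tryCatch(analyzeSegment(base, ld, config),
                    error = function(e) NULL)
      if (!is.null(b) && is.finite(a$stLevel) && is.finite(b$stLevel))
        stdev <- a$stLevel - b$stLevel
    }
    analyses[[ld]] <- a
    rows[[ld]] <- data.frame(lead = ld, bvr = a$bvr, mean_qt = a$meanQt,
                             st_dev = stdev, n_valid = a$nValid,
                             pvc_count = a$pvcCount, status = "ok")
  }
  perLead <- do.call(rbind, rows)
  rownames(perLead) <- NULL
  ok <- perLead$status == "ok"
  out <- list(
    perLead = perLead,
    hr = if (length(analyses)) analyses[[1]]$hr else NA_real_,
    qtDispersion = if (sum(is.finite(perLead$mean_qt)) >= 2)
      qtDispersion(perLead$mean_qt) else NA_real_,
    cumulativeBvr = sum(perLead$bvr[ok], na.rm = TRUE),
    cumulativeSt = if (any(is.finite(perLead$st_dev)))
      sum(abs(perLead$st_dev), na.rm = TRUE) else NA_real_,
    maxBvr = if (any(is.finite(perLead$bvr)))
      max(perLead$bvr, na.rm = TRUE) else NA_real_,
    pvcCount = if (any(ok)) max(perLead$pvc_count[ok]) else NA_integer_,
    analyses = analyses
  )
  class(out) <- "SegmentMetrics"
  out
}

#' @export
print.SegmentMetrics <- function(x, ...) {
  ok <- x$perLead$status == "ok"
  cat("SegmentMetrics:", sum(ok), "of", nrow(x$perLead),
      "leads analyzed\n")
  cat("  cumulative BVR", sprintf("%.3f", x$cumulativeBvr),
      "ms | max BVR", sprintf("%.3f", x$maxBvr),
      "ms | QT dispersion", sprintf("%.1f", x$qtDispersion),
      "ms | HR", sprintf("%.1f", x$hr), "bpm\n")
  invisible(x)
}
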