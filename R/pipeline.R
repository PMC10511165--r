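# Study orchestration: time points, pre-VF surge, sampling-rate
# experiment, programmed-stimulation inducibility, cohort reporting.

#' Event log of one experiment
#'
#' @param occlusionTime coronary occlusion time, s.
#' @param vfTime first VF onset, s (NA when no VF occurred).
#' @param reperfusionTime reperfusion time, s (optional).
#' @param group "MI" or "sham".
#' @param matchedVfTime for animals without VF: the matched time point
#'   (same ischemia duration as a matched VF animal), s.
#' @return list of class `EventLog`.
#' @export
eventLog <- function(occlusionTime, vfTime = NA_real_,
                     reperfusionTime = NA_real_,
                     group = c("MI", "sham"),
                     matchedVfTime = NA_real_) {
  group <- match.arg(group)
  if (!is.na(vfTime) && vfTime <= occlusionTime)
    stop("vfTime must be after occlusionTime", call. = FALSE)
  ev <- list(occlusionTime = occlusionTime, vfTime = vfTime,
             reperfusionTime = reperfusionTime, group = group,
             matchedVfTime = matchedVfTime)
  class(ev) <- "EventLog"
  ev
}

#' Read an EventLog from YAML
#' @param path YAML file with keys matching [eventLog()] arguments.
#' @return an `EventLog`.
#' @export
readEventLog <- function(path) do.call(eventLog, yaml::read_yaml(path))

#' Named analysis windows of the study design
#'
#' 60-s windows: `baseline` ends 15 min before occlusion, `ami5` starts
#' 5 min after occlusion, `pre1` ends exactly at VF onset, and `pre5`
#' covers the 5-min-pre-VF mark (by default the window ending at VF - 4
#' min, i.e. centered on that mark's minute; `pre5Mode = "ending"`
#' places it ending at VF - 5 min). For animals without VF the matched
#' time point is used with identical arithmetic. Windows outside the
#' record (or pre-VF windows reaching before the occlusion) are flagged
#' unavailable.
#'
#' @param ev an [eventLog()].
#' @param recordSpan `c(start, end)` of the available record, s.
#' @param config an [analysisConfig()] (for `pre5Mode`).
#' @return data.frame of class `TimepointSet`: window, start_s, end_s,
#'   available, reason.
#' @export
makeTimepoints <- function(ev, recordSpan, config = analysisConfig()) {
  occ <- ev$occlusionTime
  vf <- if (!is.na(ev$vfTime)) ev$vfTime else ev$matchedVfTime
  win <- list(baseline = c(occ - 960, occ - 900),
              ami5 = c(occ + 300, occ + 360))
  if (!is.na(vf)) {
    pre5End <- if (config$pre5Mode == "centered") vf - 240 else vf - 300
    win$pre5 <- c(pre5End - 60, pre5End)
    win$pre1 <- c(vf - 60, vf)
  }
  rows <- lapply(names(win), function(nm) {
    w <- win[[nm]]
    ok <- w[1] >= recordSpan[1] && w[2] <= recordSpan[2]
    reason <- if (!ok) "outside record" else ""
    if (nm %in% c("pre5", "pre1") && w[1] < occ) {
      ok <- FALSE; reason <- "window precedes occlusion (clipped)"
    }
    data.frame(window = nm, start_s = w[1], end_s = w[2],
               available = ok, reason = reason)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("TimepointSet", "data.frame")
  out
}

#' Analyze the study time points of one record
#'
#' Runs the per-segment pipeline on each available window. The analysis
#' lead follows the study's "lead II or V4 as appropriate" rule: the
#' lead with the largest absolute baseline-to-early-ischemia ST
#' deviation among the candidates (falling back to the first candidate
#' when ST cannot be compared), unless `lead` is given explicitly.
#'
#' @param record an [ECGRecord-class].
#' @param ev an [eventLog()].
#' @param lead explicit analysis lead (overrides the rule).
#' @param candidateLeads leads eligible for the rule (default II and
#'   V4).
#' @param config an [analysisConfig()].
#' @return data.frame with one row per window: window, lead, start_s,
#'   end_s, status and the window's metrics (bvr, mean_qt, hr, st_dev,
#'   pvc_count); unavailable/failed windows keep their row with NA
#'   metrics and the reason in `status`.
#' @export
analyzeTimepoints <- function(record, ev, lead = NULL,
                              candidateLeads = c("II", "V4"),
                              config = analysisConfig()) {
  span <- c(record@t0, record@t0 + recordDuration(record))
  tps <- makeTimepoints(ev, span, config)
  candidateLeads <- intersect(candidateLeads, leadNames(record))
  if (is.null(lead)) lead <- selectLead(record, tps, candidateLeads, config)
  baseRow <- tps[tps$window == "baseline", ]
  baseWin <- if (nrow(baseRow) && baseRow$available)
    c(baseRow$start_s, baseRow$end_s) else NULL

  rows <- lapply(seq_len(nrow(tps)), function(i) {
    tp <- tps[i, ]
    na <- data.frame(window = tp$window, lead = lead,
                     start_s = tp$start_s, end_s = tp$end_s,
                     bvr = NA_real_, mean_qt = NA_real_, hr = NA_real_,
                     st_dev = NA_real_, pvc_count = NA_integer_,
                     status = tp$reason)
    if (!tp$available) return(na)
    sm <- tryCatch(
      segmentMetrics(record, c(tp$start_s, tp$end_s), leads = lead,
                     config = config, baselineWindow = baseWin),
      error = function(e) e)
    if (inherits(sm, "error")) { na$status <- conditionMessage(sm); return(na) }
    pl <- sm$perLead[1, ]
    data.frame(window = tp$window, lead = lead, start_s = tp$start_s,
               end_s = tp$end_s, bvr = pl$bvr, mean_qt = pl$mean_qt,
               hr = sm$hr, st_dev = pl$st_dev, pvc_count = pl$pvc_count,
               status = pl$status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Lead rule: largest |baseline -> early-ischemia ST deviation| among the
# candidates.
selectLead <- function(record, tps, candidateLeads, config) {
  if (length(candidateLeads) <= 1)
    return(if (length(candidateLeads)) candidateLeads else
           leadNames(record)[1])
  b <- tps[tps$window == "baseline", ]
  a <- tps[tps$window == "ami5", ]
  if (!nrow(b) || !nrow(a) || !b$available || !a$available)
    return(candidateLeads[1])
  dev <- vapply(candidateLeads, function(ld) {
    out <- tryCatch({
      sb <- analyzeSegment(extractWindow(record, b$start_s, b$end_s), ld,
                           config)
      sa <- analyzeSegment(extractWindow(record, a$start_s, a$end_s), ld,
                           config)
      abs(sa$stLevel - sb$stLevel)
    }, error = function(e) NA_real_)
    out
  }, numeric(1))
  if (all(is.na(dev))) return(candidateLeads[1])
  candidateLeads[which.max(dev)]
}

#' Pre-VF surge detection on the BVR change
#'
#' Flags an imminent-arrhythmia surge when BVR in the final pre-VF
#' minute exceeds BVR at the 5-min-pre-VF window by more than the
#' threshold (default 1.4 ms, configurable; a working point between the
#' reported VF-positive and VF-negative group-mean changes, with no
#' claim of clinical validity).
#'
#' @param bvrPre5,bvrPre1 BVR (ms) of the two windows, measured on the
#'   same lead.
#' @param threshold surge threshold on the change, ms.
#' @param lead,leadPre1 analysis lead of each window; when both are
#'   given they must match.
#' @return list of class `SurgeResult`: `deltaBvr`, `flag`,
#'   `threshold`, `leadUsed`.
#' @export
surgeDetect <- function(bvrPre5, bvrPre1,
                        threshold = analysisConfig()$surgeThresholdMs,
                        lead = NULL, leadPre1 = lead) {
  if (!is.null(lead) && !is.null(leadPre1) && !identical(lead, leadPre1))
    stop("surge windows analyzed on different leads", call. = FALSE)
  delta <- bvrPre1 - bvrPre5
  out <- list(deltaBvr = delta, flag = isTRUE(delta > threshold),
              threshold = threshold,
              leadUsed = if (is.null(lead)) NA_character_ else lead)
  class(out) <- "SurgeResult"
  out
}

#' @export
print.SurgeResult <- function(x, ...) {
  cat("SurgeResult: dBVR =", sprintf("%.3f", x$deltaBvr), "ms;",
      if (x$flag) "SURGE" else "no surge",
      "(threshold", x$threshold, "ms)\n")
  invisible(x)
}

#' Sampling-rate sensitivity experiment
#'
#' Re-runs the full measurement pipeline on the same underlying signal
#' at 200 Hz (downsampled), 1 kHz (as supplied), and 4 kHz (only when a
#' genuinely 4-kHz recording of the same signal is supplied; upsampling
#' is not a substitute). Inputs below 500 Hz are refused because QT
#' variability measurement is unreliable there, unless `force = TRUE`.
#'
#' @param record1k the 1-kHz [ECGRecord-class].
#' @param record4k optional 4-kHz [ECGRecord-class] of the same signal.
#' @param lead analysis lead.
#' @param config an [analysisConfig()].
#' @param force analyze sub-500-Hz input anyway.
#' @return data.frame: fs, bvr, mean_qt, n_valid, ratio_vs_1k.
#' @export
samplingStudy <- function(record1k, record4k = NULL, lead = "II",
                          config = analysisConfig(), force = FALSE) {
  if (record1k@fs < 500 && !force)
    stop("input sampled below 500 Hz: QT-variability measurement ",
         "requires > 500 Hz (use force = TRUE to override)",
         call. = FALSE)
  runs <- list(`200` = resampleRecord(record1k, 200), `1000` = record1k)
  if (!is.null(record4k)) {
    if (record4k@fs != 4000)
      stop("record4k must be sampled at 4000 Hz", call. = FALSE)
    runs$`4000` <- record4k
  }
  rows <- lapply(names(runs), function(nm) {
    a <- analyzeSegment(runs[[nm]], lead, config)
    data.frame(fs = as.numeric(nm), bvr = a$bvr, mean_qt = a$meanQt,
               n_valid = a$nValid)
  })
  out <- do.call(rbind, rows)
  out$ratio_vs_1k <- out$bvr / out$bvr[out$fs == 1000]
  out
}

## ---- programmed electrical stimulation ----

#' Default PES aggressiveness ladder
#'
#' Nine steps enumerating drive-cycle lengths 600, 400 and 350 ms with
#' one to three extrastimuli, from least to most aggressive. The first
#' step is S1 = 600 ms with a single S2 = 400 ms extrastimulus; the
#' last is S1 = 350 ms with S2/S3/S4 = 200/180/150 ms. Intermediate
#' couplings are conventional fill-ins; the inducibility index depends
#' only on the step count and position.
#'
#' @return data.frame: step, drive_ms, couplings (list column, ms).
#' @export
pesLadder <- function() {
  data.frame(
    step = 1:9,
    drive_ms = rep(c(600, 400, 350), each = 3),
    couplings = I(list(
      c(400), c(400, 380), c(400, 380, 360),
      c(250), c(250, 230), c(250, 230, 210),
      c(200), c(200, 180), c(200, 180, 150)))
  )
}

#' Programmed-stimulation outcome
#'
#' @param steps the PES ladder, as from [pesLadder()].
#' @param inducedAtStep step index at which sustained VT/VF was induced,
#'   or NA when the full ladder completed without induction.
#' @param erpS2 effective refractory period from the S2 ladder, ms
#'   (optional).
#' @return list of class `PESOutcome`.
#' @export
pesOutcome <- function(steps = pesLadder(), inducedAtStep = NA_integer_,
                       erpS2 = NA_real_) {
  if (!is.na(inducedAtStep) &&
      (inducedAtStep < 1 || inducedAtStep > nrow(steps)))
    stop("inducedAtStep outside the ladder", call. = FALSE)
  out <- list(steps = steps, inducedAtStep = inducedAtStep, erpS2 = erpS2)
  class(out) <- "PESOutcome"
  out
}

#' Arrhythmia-inducibility index
#'
#' Maps the stimulation step at which sustained VT/VF was induced to a
#' percentage scale: induction at the first (least aggressive) step
#' scores 100%, completing the final (most aggressive) step without
#' induction scores 0%, and induction at step k of an S-step ladder
#' scores `100 * (S - k + 1) / S` (linear in the step).
#'
#' @param pes a [pesOutcome()].
#' @return inducibility index, percent.
#' @examples
#' inducibilityIndex(pesOutcome(inducedAtStep = 1))   # 100
#' inducibilityIndex(pesOutcome())                    # 0 (noninducible)
#' @export
inducibilityIndex <- function(pes) {
  S <- nrow(pes$steps)
  k <- pes$inducedAtStep
  if (is.na(k)) return(0)
  if (k < 1 || k > S) stop("induction step outside the ladder",
                           call. = FALSE)
  100 * (S - k + 1) / S
}

#' Effective refractory period from an S2 capture ladder
#'
#' ERP at the 400-ms drive train: the shortest S2 coupling interval
#' that failed to capture the ventricle. Capture is assumed monotone in
#' S2; a capturing S2 below a non-capturing one sets
#' `monotoneViolation`.
#'
#' @param capture data.frame with columns `s2` (ms) and `captured`
#'   (logical), e.g. a descending test ladder.
#' @return list: `erpMs` (NA at a boundary), `flag` ("" /
#'   "erp_below_tested_range" / "erp_above_tested_range"),
#'   `monotoneViolation`.
#' @export
erpFromDrivetrain <- function(capture) {
  stopifnot(all(c("s2", "captured") %in% names(capture)))
  nonCap <- capture$s2[!capture$captured]
  capd <- capture$s2[capture$captured]
  if (!length(nonCap))
    return(list(erpMs = NA_real_, flag = "erp_below_tested_range",
                monotoneViolation = FALSE))
  if (!length(capd))
    return(list(erpMs = NA_real_, flag = "erp_above_tested_range",
                monotoneViolation = FALSE))
  viol <- any(capd < max(nonCap))
  if (viol) warning("non-monotone capture sequence")
  list(erpMs = min(nonCap), flag = "", monotoneViolation = viol)
}

## ---- cohort reporting ----

#' Write a tidy cohort report
#'
#' @param cohort named list, one element per animal, each a list with
#'   `metrics` (the data.frame from [analyzeTimepoints()]) and optional
#'   `group`.
#' @param dir output directory.
#' @param config the [analysisConfig()] used (hashed into the run log).
#' @param seed seed recorded in the run log.
#' @param plots also write Poincare/trajectory figures (PDF).
#' @return invisibly, the tidy long-format data.frame written to
#'   `metrics.csv` (one row per animal, window, metric; missing windows
#'   keep explicit NA values).
#' @export
reportCohort <- function(cohort, dir, config = analysisConfig(),
                         seed = NA_integer_, plots = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- list()
  for (animal in names(cohort)) {
    m <- cohort[[animal]]$metrics
    grp <- cohort[[animal]]$group %||% NA_character_
    for (i in seq_len(nrow(m)))
      for (metric in c("bvr", "mean_qt", "hr", "st_dev", "pvc_count"))
        long[[length(long) + 1L]] <- data.frame(
          animal = animal, group = grp, window = m$window[i],
          lead = m$lead[i], metric = metric,
          value = as.numeric(m[[metric]][i]))
  }
  tidy <- do.call(rbind, long)
  data.table::fwrite(tidy, file.path(dir, "metrics.csv"), na = "NA")
  wide <- stats::aggregate(value ~ group + window + metric, tidy, mean,
                           na.rm = TRUE, na.action = NULL)
  jsonlite::write_json(wide, file.path(dir, "summary.json"),
                       dataframe = "rows", na = "null", digits = NA)
  jsonlite::write_json(
    list(configHash = configHash(config), seed = seed,
         nAnimals = length(cohort)),
    file.path(dir, "runlog.json"), auto_unbox = TRUE)
  if (plots) {
    pdf(file.path(dir, "trajectories.pdf"), width = 6, height = 4)
    print(plotBvrTrajectory(tidy[tidy$metric == "bvr", ]))
    dev.off()
  }
  invisible(tidy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
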