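# Synthetic multi-lead ECG generation with analytic ground truth.
#
# Beats are sums of Gaussians (P/Q/R/S plus a single-Gaussian T wave,
# ECGSYN-style). Because the T wave is one Gaussian, the tangent-method
# T-end has the closed form tEnd = tPeak + 2*sigmaT: the steepest
# post-peak downslope is the inflection point at tPeak + sigmaT, and the
# tangent there meets the baseline one further sigmaT later. Per-beat QT
# is prescribed by translating the whole T wave in time (shape fixed), so
# the tangent T-end moves by exactly the prescribed amount and the truth
# is defined by the same convention the measurement pipeline uses.

CLINICAL_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                    "V1", "V2", "V3", "V4", "V5", "V6")

#' Default beat morphology
#'
#' Generic 12-lead sum-of-Gaussians beat morphology. Times are in ms
#' relative to the R peak, amplitudes in mV for a lead-II reference beat;
#' per-lead shapes are scalar-scaled copies (no claim of species
#' fidelity). The T wave is a single Gaussian so its tangent T-end is
#' analytic.
#'
#' @param leads lead names (default: the 12 clinical leads).
#' @return list with components `waves` (P/Q/R/S Gaussian parameters),
#'   `t` (T-wave sigma and amplitude), `qrsOnRel`/`qrsOffRel` (QRS onset
#'   and offset, ms relative to R), `rOffsetMs` (R position within a
#'   single-beat frame), `leadScale`, and `pvc` (ectopic-beat morphology:
#'   wide inverted QRS with a discordant T).
#' @export
defaultMorphology <- function(leads = CLINICAL_LEADS) {
  scale <- c(I = 0.6, II = 1, III = 0.45, aVR = -0.85, aVL = 0.3,
             aVF = 0.7, V1 = -0.5, V2 = -0.25, V3 = 0.6, V4 = 1.1,
             V5 = 0.9, V6 = 0.7)
  leadScale <- scale[leads]
  leadScale[is.na(leadScale)] <- 1
  names(leadScale) <- leads
  list(
    waves = data.frame(
      wave   = c("P", "Q", "R", "S"),
      center = c(-160, -25, 0, 30),
      sigma  = c(20, 8, 10, 9),
      amp    = c(0.10, -0.10, 1.00, -0.20)
    ),
    t = list(sigma = 40, amp = 0.30),
    qrsOnRel = -45, qrsOffRel = 52.5,
    rOffsetMs = 400,
    leadScale = leadScale,
    pvc = list(
      waves = data.frame(
        wave   = c("R1", "R2"),
        center = c(0, 28),
        sigma  = c(32, 20),
        amp    = c(-0.85, -0.25)
      ),
      t = list(center = 330, sigma = 55, amp = 0.40)
    )
  )
}

#' Synthetic ECG generator configuration
#'
#' Study-condition defaults: 12-lead sinus rhythm at 1 kHz, mean RR
#' 1000 ms with 25 ms sinus variability, QT 400 ms, and an analytic
#' short-term QT variability target of 0.4 ms (quiet baseline lability).
#'
#' @param fs sampling rate, Hz.
#' @param duration record length, s.
#' @param leads lead names.
#' @param rrMean,rrSd RR-interval mean and SD, ms (RR is truncated at
#'   `rrMean/2` to prevent beat overlap).
#' @param qtBase mean QT, ms.
#' @param qtWhiteSd white (innovation) SD of the per-beat AR(1) QT noise,
#'   ms; ignored when `stvTarget` is given.
#' @param qtArCoef lag-1 autocorrelation of the QT noise, in \[0, 1).
#' @param stvTarget analytic expected sample STV of the generated QT
#'   series, ms; when given, `qtWhiteSd` is calibrated in closed form.
#' @param stvSegments optional data.frame (`start_s`, `end_s`, `stv`)
#'   prescribing a piecewise STV profile (e.g. a pre-VF ramp); beats
#'   outside all segments use `stvTarget`/`qtWhiteSd`.
#' @param pvcSchedule optional data.frame (`beat`, `coupling`, `scale`):
#'   beat index (>= 2) replaced by a premature ventricular complex with
#'   the given coupling interval (ms) and amplitude scale; the following
#'   RR is the compensatory pause `2*rrMean - coupling`.
#' @param stOffset named per-lead ST-segment plateau offset, mV.
#' @param tAmpScale named per-lead T-amplitude multiplier.
#' @param noise list: `wanderAmp` (mV) and `wanderHz` baseline wander,
#'   `broadbandSd` (mV) white noise, `powerlineAmp` (mV) and
#'   `powerlineHz` mains interference.
#' @param seed integer seed; identical configs give bit-identical output,
#'   and beat-level truth is independent of `fs`.
#' @param morphology beat morphology, see [defaultMorphology()].
#' @return validated list of class `SynthConfig`.
#' @export
synthConfig <- function(fs = 1000, duration = 60, leads = CLINICAL_LEADS,
                        rrMean = 1000, rrSd = 25, qtBase = 400,
                        qtWhiteSd = 0, qtArCoef = 0, stvTarget = 0.4,
                        stvSegments = NULL, pvcSchedule = NULL,
                        stOffset = NULL, tAmpScale = NULL,
                        noise = list(), seed = 1L,
                        morphology = defaultMorphology(leads)) {
  noiseDefaults <- list(wanderAmp = 0.05, wanderHz = 0.3,
                        broadbandSd = 0.003, powerlineAmp = 0.005,
                        powerlineHz = 50)
  noise <- modifyList(noiseDefaults, noise)
  stOff <- stats::setNames(rep(0, length(leads)), leads)
  if (!is.null(stOffset)) stOff[names(stOffset)] <- stOffset
  tSc <- stats::setNames(rep(1, length(leads)), leads)
  if (!is.null(tAmpScale)) tSc[names(tAmpScale)] <- tAmpScale
  cfg <- list(fs = fs, duration = duration, leads = leads, rrMean = rrMean,
              rrSd = rrSd, qtBase = qtBase, qtWhiteSd = qtWhiteSd,
              qtArCoef = qtArCoef, stvTarget = stvTarget,
              stvSegments = stvSegments, pvcSchedule = pvcSchedule,
              stOffset = stOff, tAmpScale = tSc, noise = noise,
              seed = as.integer(seed), morphology = morphology)
  class(cfg) <- "SynthConfig"
  validateSynthConfig(cfg)
  cfg
}

validateSynthConfig <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.finite(cfg$fs) || cfg$fs <= 0)
    stop("fs must be positive", call. = FALSE)
  if (!is.finite(cfg$duration) || cfg$duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (!(cfg$rrMean > cfg$qtBase && cfg$qtBase > 0))
    stop("invariant rrMean > qtBase > 0 violated", call. = FALSE)
  if (cfg$qtWhiteSd < 0) stop("qtWhiteSd must be >= 0", call. = FALSE)
  if (cfg$qtArCoef < 0 || cfg$qtArCoef >= 1)
    stop("qtArCoef must be in [0, 1)", call. = FALSE)
  if (!is.null(cfg$stvTarget) && cfg$stvTarget < 0)
    stop("stvTarget must be >= 0", call. = FALSE)
  if (!is.null(cfg$pvcSchedule)) {
    ps <- cfg$pvcSchedule
    stopifnot(all(c("beat", "coupling") %in% names(ps)))
    if (any(ps$beat < 2)) stop("PVC beat index must be >= 2", call. = FALSE)
    if (any(ps$coupling >= cfg$rrMean))
      stop("all PVC coupling intervals must be < rrMean", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a SynthConfig from YAML
#'
#' @param path path to a YAML file whose keys match [synthConfig()]
#'   arguments; `stvSegments` and `pvcSchedule` may be given as lists of
#'   rows.
#' @return a `SynthConfig`.
#' @export
readSynthConfig <- function(path) {
  y <- yaml::read_yaml(path)
  for (tab in c("stvSegments", "pvcSchedule"))
    if (!is.null(y[[tab]]))
      y[[tab]] <- do.call(rbind, lapply(y[[tab]], as.data.frame))
  do.call(synthConfig, y)
}

## ---- low-level waveform assembly ----

# Add amp * gaussian(center, sigma) to a signal matrix, one amplitude per
# column; evaluated only within +/- 4 sigma.
addGaussian <- function(y, fs, centerMs, sigmaMs, ampVec) {
  n <- nrow(y)
  i1 <- max(1L, floor((centerMs - 4 * sigmaMs) / 1000 * fs) + 1L)
  i2 <- min(n, ceiling((centerMs + 4 * sigmaMs) / 1000 * fs) + 1L)
  if (i1 > i2) return(y)
  t <- (seq.int(i1, i2) - 1) / fs * 1000
  g <- exp(-((t - centerMs)^2) / (2 * sigmaMs^2))
  y[i1:i2, ] <- y[i1:i2, , drop = FALSE] + outer(g, ampVec)
  y
}

# Raised-cosine ST pedestal between the QRS offset (J) and T onset.
addPedestal <- function(y, fs, jMs, tOnMs, ampVec, rampMs = 20) {
  n <- nrow(y)
  a <- jMs - rampMs / 2; b <- jMs + rampMs / 2
  c1 <- tOnMs - rampMs / 2; d <- tOnMs + rampMs / 2
  if (c1 <= b) return(y)              # degenerate (very short QT): skip
  i1 <- max(1L, floor(a / 1000 * fs) + 1L)
  i2 <- min(n, ceiling(d / 1000 * fs) + 1L)
  if (i1 > i2) return(y)
  t <- (seq.int(i1, i2) - 1) / fs * 1000
  g <- numeric(length(t))
  up <- t >= a & t < b
  g[up] <- (1 - cos(pi * (t[up] - a) / rampMs)) / 2
  g[t >= b & t <= c1] <- 1
  dn <- t > c1 & t <= d
  g[dn] <- (1 + cos(pi * (t[dn] - c1) / rampMs)) / 2
  y[i1:i2, ] <- y[i1:i2, , drop = FALSE] + outer(g, ampVec)
  y
}

#' Build a single-beat waveform with analytic fiducials
#'
#' One beat of length `rrMean` ms at `fs`, as a sum of Gaussians. The
#' reported tangent T-end follows the closed form `tPeak + 2*sigmaT`.
#'
#' @param morphology see [defaultMorphology()].
#' @param fs sampling rate, Hz.
#' @param rrMean beat-frame length, ms.
#' @param qt prescribed QT (tangent T-end minus QRS onset), ms; `NULL`
#'   places the T wave at 400 ms QT.
#' @param leads lead names.
#' @return list: `waveform` (samples x leads, mV), `fs`, `fiducials`
#'   (named ms from template start: qrsOn, rPeak, qrsOff, tPeak, tEnd),
#'   `qt` (NA when the T amplitude is zero, i.e. QT undefined).
#' @examples
#' b <- makeBeatTemplate(fs = 1000)
#' b$fiducials["tEnd"] - b$fiducials["qrsOn"]  # = prescribed 400 ms QT
#' @export
makeBeatTemplate <- function(morphology = defaultMorphology(leads),
                             fs = 1000, rrMean = 1000, qt = 400,
                             leads = CLINICAL_LEADS) {
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  w <- morphology$waves
  if (any(!is.finite(c(w$center, w$sigma, w$amp, morphology$t$sigma,
                       morphology$t$amp))))
    stop("morphology parameters must be finite", call. = FALSE)
  if (any(w$sigma <= 0) || morphology$t$sigma <= 0)
    stop("wave widths must be positive", call. = FALSE)
  n <- round(rrMean / 1000 * fs)
  y <- matrix(0, n, length(leads), dimnames = list(NULL, leads))
  r0 <- morphology$rOffsetMs
  ls <- morphology$leadScale[leads]
  for (k in seq_len(nrow(w)))
    y <- addGaussian(y, fs, r0 + w$center[k], w$sigma[k], w$amp[k] * ls)
  sigT <- morphology$t$sigma
  tCenter <- r0 + morphology$qrsOnRel + qt - 2 * sigT
  y <- addGaussian(y, fs, tCenter, sigT, morphology$t$amp * ls)
  flatT <- morphology$t$amp == 0
  list(
    waveform = y, fs = fs,
    fiducials = c(qrsOn = r0 + morphology$qrsOnRel, rPeak = r0,
                  qrsOff = r0 + morphology$qrsOffRel,
                  tPeak = if (flatT) NA_real_ else tCenter,
                  tEnd = if (flatT) NA_real_ else tCenter + 2 * sigT),
    qt = if (flatT) NA_real_ else qt
  )
}

## ---- STV calibration ----

# Analytic expectation of the sample STV statistic for a stationary AR(1)
# QT noise with innovation SD sdw and lag-1 coefficient phi, evaluated
# with nValid analyzed beats and nDiff admissible successive differences:
# successive differences are Gaussian with sd(D) = sdw * sqrt(2/(1+phi)),
# E|D| = sd(D) * sqrt(2/pi), and E[STV] = (nDiff/nValid) * E|D| / sqrt(2).
analyticStv <- function(sdw, phi, nValid, nDiff) {
  if (nValid < 2 || nDiff < 1) return(if (sdw == 0) 0 else NA_real_)
  (nDiff / nValid) * sdw * sqrt(2 / ((1 + phi) * pi))
}

calibrateWhiteSd <- function(target, phi, nValid, nDiff) {
  if (target == 0) return(0)
  if (nValid < 2 || nDiff < 1)
    stop("stvTarget not achievable: no admissible QT differences",
         call. = FALSE)
  target * (nValid / nDiff) * sqrt((1 + phi) * pi / 2)
}

# Truth-level exclusion around scheduled PVCs (mirrors exclusionMask()):
# the PVC, its successor, and its predecessor when the PVC falls before
# the predecessor's T end.
truthExcluded <- function(labels, rTimes, qtNominal) {
  n <- length(labels)
  excl <- logical(n)
  for (i in which(labels == "pvc")) {
    excl[i] <- TRUE
    if (i < n) excl[i + 1] <- TRUE
    if (i > 1 && labels[i - 1] == "sinus" &&
        (rTimes[i] - rTimes[i - 1]) < qtNominal)
      excl[i - 1] <- TRUE
  }
  excl
}

## ---- record synthesis ----

#' Synthesize a multi-lead ECG record with known ground truth
#'
#' Generates a sinus beat train with Gaussian RR variability (truncated
#' at `rrMean/2`), per-beat QT = `qtBase` + AR(1) noise, optional
#' scheduled PVCs (early, wide, inverted, with compensatory pause),
#' per-lead ST-segment plateaus, and additive noise. When `stvTarget` is
#' set, the white-noise SD is calibrated so that the analytic expectation
#' of the sample STV of the generated (post-exclusion) QT sequence equals
#' the target exactly; `stvTrue` in the returned truth records that
#' value.
#'
#' The seed drives two independent streams (beat-level truth and sample
#' noise), so the same seed yields the same beat train and QT series at
#' any sampling rate.
#'
#' @param config a `SynthConfig`, see [synthConfig()].
#' @return list with elements `record` ([ECGRecord-class]) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' out <- synthesizeRecord(synthConfig(duration = 20, leads = "II",
#'                                     stvTarget = 1.5, seed = 7))
#' stvTrue(out$truth)
#' @export
synthesizeRecord <- function(config) {
  validateSynthConfig(config)
  cfg <- config
  durMs <- cfg$duration * 1000
  truthSeed <- cfg$seed
  noiseSeed <- as.integer((as.numeric(cfg$seed) * 69069 + 101) %% 2147483647)

  ## --- beat-level truth (fs-independent) ---
  set.seed(truthSeed)
  nMax <- ceiling(durMs / (cfg$rrMean / 2)) + 3L
  rr <- pmax(rnorm(nMax, cfg$rrMean, cfg$rrSd), cfg$rrMean / 2)
  labels <- rep("sinus", nMax)
  coupling <- rep(NA_real_, nMax)
  if (!is.null(cfg$pvcSchedule)) {
    ps <- cfg$pvcSchedule
    if (is.null(ps$scale)) ps$scale <- 1
    for (k in seq_len(nrow(ps))) {
      b <- ps$beat[k]
      rr[b] <- ps$coupling[k]
      if (b + 1 <= nMax) rr[b + 1] <- 2 * cfg$rrMean - ps$coupling[k]
      labels[b] <- "pvc"
      coupling[b] <- ps$coupling[k]
    }
  }
  r <- cumsum(rr)
  margin <- cfg$qtBase + 250            # room for the T wave + tangent search
  keep <- r <= durMs - margin
  r <- r[keep]; labels <- labels[keep]; coupling <- coupling[keep]
  n <- length(r)
  if (n < 2) stop("duration too short for the configured beat train",
                  call. = FALSE)

  excl <- truthExcluded(labels, r, cfg$qtBase)
  validT <- labels == "sinus" & !excl
  nValid <- sum(validT)
  nDiff <- sum(validT[-n] & validT[-1])
  phi <- cfg$qtArCoef

  piecewise <- !is.null(cfg$stvSegments)
  if (piecewise) {
    # per-beat innovation SD from the segment profile (large-n calibration)
    sdwBeat <- rep(
      if (!is.null(cfg$stvTarget))
        cfg$stvTarget * sqrt((1 + phi) * pi / 2) else cfg$qtWhiteSd, n)
    for (k in seq_len(nrow(cfg$stvSegments))) {
      seg <- cfg$stvSegments[k, ]
      inSeg <- r >= seg$start_s * 1000 & r < seg$end_s * 1000
      sdwBeat[inSeg] <- seg$stv * sqrt((1 + phi) * pi / 2)
    }
    stvTrueVal <- NA_real_
  } else if (!is.null(cfg$stvTarget)) {
    sdw <- calibrateWhiteSd(cfg$stvTarget, phi, nValid, nDiff)
    sdwBeat <- rep(sdw, n)
    stvTrueVal <- cfg$stvTarget
  } else {
    sdwBeat <- rep(cfg$qtWhiteSd, n)
    stvTrueVal <- analyticStv(cfg$qtWhiteSd, phi, nValid, nDiff)
  }

  eps <- rnorm(n)
  x <- numeric(n)
  x[1] <- eps[1] * sdwBeat[1] / sqrt(1 - phi^2)
  if (n > 1) for (k in 2:n) x[k] <- phi * x[k - 1] + sdwBeat[k] * eps[k]
  qt <- cfg$qtBase + x
  qt[labels == "pvc"] <- NA_real_

  ## --- waveform assembly ---
  m <- cfg$morphology
  leads <- cfg$leads
  ls <- m$leadScale[leads]
  nS <- round(cfg$duration * cfg$fs)
  y <- matrix(0, nS, length(leads), dimnames = list(NULL, leads))
  sigT <- m$t$sigma
  tAmpVec <- m$t$amp * ls * cfg$tAmpScale[leads]
  anySt <- any(cfg$stOffset != 0)
  for (i in seq_len(n)) {
    if (labels[i] == "sinus") {
      for (k in seq_len(nrow(m$waves)))
        y <- addGaussian(y, cfg$fs, r[i] + m$waves$center[k],
                         m$waves$sigma[k], m$waves$amp[k] * ls)
      tCenter <- r[i] + m$qrsOnRel + qt[i] - 2 * sigT
      y <- addGaussian(y, cfg$fs, tCenter, sigT, tAmpVec)
      if (anySt)
        y <- addPedestal(y, cfg$fs, r[i] + m$qrsOffRel,
                         tCenter - 2.5 * sigT, cfg$stOffset[leads])
    } else {
      sc <- if (is.na(coupling[i])) 1 else
        cfg$pvcSchedule$scale[match(i, cfg$pvcSchedule$beat)]
      if (is.na(sc) || is.null(sc)) sc <- 1
      pw <- m$pvc$waves
      for (k in seq_len(nrow(pw)))
        y <- addGaussian(y, cfg$fs, r[i] + pw$center[k], pw$sigma[k],
                         pw$amp[k] * sc * ls)
      y <- addGaussian(y, cfg$fs, r[i] + m$pvc$t$center, m$pvc$t$sigma,
                       m$pvc$t$amp * sc * ls)
    }
  }

  ## --- additive noise (independent stream) ---
  set.seed(noiseSeed)
  nz <- cfg$noise
  tSec <- (seq_len(nS) - 1) / cfg$fs
  for (l in seq_along(leads)) {
    if (nz$wanderAmp > 0)
      y[, l] <- y[, l] + nz$wanderAmp *
        sin(2 * pi * nz$wanderHz * tSec + runif(1, 0, 2 * pi))
    if (nz$powerlineAmp > 0)
      y[, l] <- y[, l] + nz$powerlineAmp *
        sin(2 * pi * nz$powerlineHz * tSec + runif(1, 0, 2 * pi))
    if (nz$broadbandSd > 0)
      y[, l] <- y[, l] + rnorm(nS, 0, nz$broadbandSd)
  }

  record <- new("ECGRecord", fs = cfg$fs, signal = y, t0 = 0)
  truth <- new("GroundTruth",
    rTimes = r, qtTrue = qt, labels = labels,
    stOffset = cfg$stOffset, stvTrue = stvTrueVal, seed = truthSeed,
    beatInfo = data.frame(r_time_ms = r, qt_ms = qt, label = labels,
                          coupling_ms = coupling),
    morphology = c(m, list(leads = leads,
                           tAmpScale = cfg$tAmpScale[leads])))
  list(record = record, truth = truth)
}

#' Apply ischemic ST/T changes from a given onset
#'
#' From `onsetS` onward (beats whose R time is at or after the onset),
#' shifts the per-lead ST plateau by `stOffsets` and scales the T-wave
#' amplitude by `tScale`. The modification is analytic (the known T-wave
#' Gaussians and pedestals are added to the existing samples), so samples
#' before the onset are bit-identical to the input and per-beat QT truth
#' is unchanged (scaling a Gaussian's amplitude does not move its tangent
#' intersection).
#'
#' @param record an [ECGRecord-class] from [synthesizeRecord()].
#' @param truth the matching [GroundTruth-class].
#' @param stOffsets named per-lead ST offset, mV (unnamed scalar recycles
#'   to all leads).
#' @param tScale T-amplitude multiplier (scalar or named per lead).
#' @param onsetS onset time, s, within the record.
#' @return list(record, truth) with updated ST offsets in the truth.
#' @export
applyIschemia <- function(record, truth, stOffsets, tScale = 1, onsetS) {
  leads <- leadNames(record)
  if (!is.finite(onsetS) || onsetS < record@t0 ||
      onsetS > record@t0 + recordDuration(record))
    stop("onset outside the record", call. = FALSE)
  off <- stats::setNames(rep(0, length(leads)), leads)
  if (is.null(names(stOffsets))) off[] <- stOffsets
  else off[names(stOffsets)] <- stOffsets
  if (any(!is.finite(off))) stop("offsets must be finite", call. = FALSE)
  tSc <- stats::setNames(rep(1, length(leads)), leads)
  if (is.null(names(tScale))) tSc[] <- tScale else tSc[names(tScale)] <- tScale

  m <- truth@morphology
  ls <- m$leadScale[leads]
  sigT <- m$t$sigma
  tAmpVec <- m$t$amp * ls * m$tAmpScale[leads]
  y <- record@signal
  onsetMs <- (onsetS - record@t0) * 1000
  hit <- which(truth@rTimes >= onsetMs)
  for (i in hit) {
    r <- truth@rTimes[i]
    if (truth@labels[i] == "sinus") {
      tCenter <- r + m$qrsOnRel + truth@qtTrue[i] - 2 * sigT
      if (any(off != 0))
        y <- addPedestal(y, record@fs, r + m$qrsOffRel,
                         tCenter - 2.5 * sigT, off)
      if (any(tSc != 1))
        y <- addGaussian(y, record@fs, tCenter, sigT, (tSc - 1) * tAmpVec)
    } else if (any(tSc != 1)) {
      y <- addGaussian(y, record@fs, r + m$pvc$t$center, m$pvc$t$sigma,
                       (tSc - 1) * m$pvc$t$amp * ls)
    }
  }
  rec2 <- record; rec2@signal <- y
  tr2 <- truth; tr2@stOffset <- truth@stOffset[leads] + off
  list(record = rec2, truth = tr2)
}

#' Resample an ECG record
#'
#' Rational-rate conversion `fsNew/fs = p/q`: upsampling by `p` uses
#' polyphase FIR interpolation (`signal::resample`); downsampling by `q`
#' applies a zero-phase 8th-order Butterworth anti-alias low-pass at 80%
#' of the new Nyquist frequency before taking every `q`-th sample. Both
#' down- and upsampling are supported.
#'
#' @param record an [ECGRecord-class].
#' @param fsNew target sampling rate, Hz.
#' @return resampled [ECGRecord-class] with lead names and `t0`
#'   preserved; the sample count scales by `fsNew/fs` within one sample.
#' @export
resampleRecord <- function(record, fsNew) {
  if (!is.finite(fsNew) || fsNew <= 0)
    stop("fsNew must be positive", call. = FALSE)
  if (fsNew == record@fs) return(record)
  frac <- ratApprox(fsNew / record@fs)
  p <- frac[1]; q <- frac[2]
  nOut <- round(nSamples(record) * fsNew / record@fs)
  out <- matrix(0, nOut, ncol(record@signal),
                dimnames = list(NULL, colnames(record@signal)))
  aa <- if (q > 1) signal::butter(8, 0.8 / q, type = "low") else NULL
  for (l in seq_len(ncol(out))) {
    z <- record@signal[, l]
    if (p > 1) z <- signal::resample(z, p, 1)
    if (q > 1) {
      z <- as.numeric(signal::filtfilt(aa, z))
      z <- z[seq(1, length(z), by = q)]
    }
    if (length(z) >= nOut) out[, l] <- z[seq_len(nOut)]
    else out[seq_along(z), l] <- z
  }
  new("ECGRecord", fs = fsNew, signal = out, t0 = record@t0)
}

# Small rational approximation p/q of a positive ratio.
ratApprox <- function(x, maxDen = 1000) {
  for (q in seq_len(maxDen)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("cannot express rate ratio as a small rational", call. = FALSE)
}
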