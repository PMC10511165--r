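# S4 containers for the ECG analysis pipeline.

#' ECGRecord: a multi-lead ECG waveform
#'
#' Holds a multi-lead ECG as a numeric matrix (rows = samples, columns =
#' leads, amplitudes in mV) together with its sampling rate and the record
#' start time.
#'
#' @slot fs sampling rate, Hz.
#' @slot signal numeric matrix, one column per lead, amplitudes in mV;
#'   column names are the lead names.
#' @slot t0 start time of the first sample, seconds.
#'
#' @seealso [ecgRecord()], [synthesizeRecord()], [resampleRecord()]
#' @exportClass ECGRecord
setClass("ECGRecord",
  representation(fs = "numeric", signal = "matrix", t0 = "numeric"),
  prototype(fs = 1000, signal = matrix(numeric(0), 0, 0), t0 = 0)
)

setValidity("ECGRecord", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!is.numeric(object@signal))
    msg <- c(msg, "signal must be a numeric matrix")
  if (ncol(object@signal) > 0 && is.null(colnames(object@signal)))
    msg <- c(msg, "signal columns must be named by lead")
  if (anyNA(object@signal) || any(!is.finite(object@signal)))
    msg <- c(msg, "all samples must be finite")
  if (length(object@t0) != 1 || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct an ECGRecord
#'
#' @param signal numeric matrix (samples x leads) in mV, or a numeric
#'   vector for a single lead.
#' @param fs sampling rate in Hz.
#' @param leadNames lead names; defaults to the column names of `signal`.
#' @param t0 start time in seconds.
#' @return An [ECGRecord-class] object.
#' @examples
#' rec <- ecgRecord(cbind(II = sin(seq(0, 10, by = 0.001))), fs = 1000)
#' nSamples(rec)
#' @export
ecgRecord <- function(signal, fs, leadNames = colnames(signal), t0 = 0) {
  if (is.null(dim(signal))) signal <- matrix(signal, ncol = 1)
  if (is.null(leadNames)) leadNames <- paste0("L", seq_len(ncol(signal)))
  colnames(signal) <- leadNames
  new("ECGRecord", fs = as.numeric(fs), signal = signal, t0 = as.numeric(t0))
}

#' GroundTruth: known truth channel of a synthetic record
#'
#' Records everything the generator knows about a synthetic ECG: beat
#' times, true per-beat QT intervals defined by the tangent convention,
#' beat labels, ST offsets, and the analytic expected value of the
#' sample STV statistic of the generated QT sequence.
#'
#' @slot rTimes R-wave times, ms, strictly increasing.
#' @slot qtTrue true per-beat QT, ms (NA for PVC beats).
#' @slot labels per-beat label, "sinus" or "pvc".
#' @slot stOffset named per-lead ST offset, mV.
#' @slot stvTrue analytic expectation of the sample STV of `qtTrue`
#'   (ms; NA when the QT process is piecewise non-stationary).
#' @slot seed integer seed used for generation.
#' @slot beatInfo per-beat bookkeeping data.frame (r_time_ms, qt_ms,
#'   label, coupling_ms).
#' @slot morphology generator morphology parameters (see
#'   [defaultMorphology()]); used by [applyIschemia()] to modify T waves
#'   analytically.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    rTimes = "numeric", qtTrue = "numeric", labels = "character",
    stOffset = "numeric", stvTrue = "numeric", seed = "integer",
    beatInfo = "data.frame", morphology = "list"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  n <- length(object@rTimes)
  if (length(object@qtTrue) != n || length(object@labels) != n)
    msg <- c(msg, "rTimes, qtTrue and labels must have equal length")
  if (n > 1 && any(diff(object@rTimes) <= 0))
    msg <- c(msg, "rTimes must be strictly increasing")
  if (!all(object@labels %in% c("sinus", "pvc")))
    msg <- c(msg, "labels must be 'sinus' or 'pvc'")
  if (length(object@stvTrue) == 1 && !is.na(object@stvTrue) &&
      object@stvTrue < 0)
    msg <- c(msg, "stvTrue must be >= 0")
  if (length(msg)) msg else TRUE
})

#' BeatTemplate: an averaged beat with annotated fiducials
#'
#' @slot waveform averaged single-beat waveform, mV.
#' @slot fs sampling rate, Hz.
#' @slot fiducials named numeric vector of fiducial times in ms relative
#'   to template start: qrsOn, rPeak, qrsOff, tPeak, tEnd (NA until
#'   [annotateTemplate()] is run).
#' @slot nBeats number of beats averaged.
#'
#' @exportClass BeatTemplate
setClass("BeatTemplate",
  representation(waveform = "numeric", fs = "numeric",
                 fiducials = "numeric", nBeats = "integer")
)

setValidity("BeatTemplate", function(object) {
  msg <- character(0)
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  f <- object@fiducials
  need <- c("qrsOn", "rPeak", "qrsOff", "tPeak", "tEnd")
  if (!all(need %in% names(f)))
    msg <- c(msg, paste("fiducials must contain", paste(need, collapse = ", ")))
  else if (!anyNA(f[need])) {
    if (!(f["qrsOn"] < f["rPeak"] && f["rPeak"] < f["tPeak"] &&
          f["tPeak"] < f["tEnd"]))
      msg <- c(msg, "fiducial ordering qrsOn < rPeak < tPeak < tEnd violated")
  }
  if (length(msg)) msg else TRUE
})

#' QTSeries: ordered per-beat QT intervals with validity mask
#'
#' The per-beat QT series of one lead, after measurement and (optionally)
#' rhythm-based exclusion. Houses the QT(n) values entering the STV
#' statistic.
#'
#' @slot beatTimes beat (R-wave) times, ms, strictly increasing.
#' @slot qt per-beat QT, ms (NA where measurement failed).
#' @slot valid logical per-beat flag; only valid beats enter [stv()].
#' @slot lead lead name.
#'
#' @seealso [stv()], [poincarePairs()]
#' @exportClass QTSeries
setClass("QTSeries",
  representation(beatTimes = "numeric", qt = "numeric",
                 valid = "logical", lead = "character")
)

setValidity("QTSeries", function(object) {
  msg <- character(0)
  n <- length(object@beatTimes)
  if (length(object@qt) != n || length(object@valid) != n)
    msg <- c(msg, "beatTimes, qt and valid must have equal length")
  if (n > 1 && any(diff(object@beatTimes) <= 0))
    msg <- c(msg, "beatTimes must be strictly increasing")
  if (any(object@valid & (is.na(object@qt) | object@qt <= 0)))
    msg <- c(msg, "valid beats must have positive, non-missing qt")
  if (length(msg)) msg else TRUE
})

#' Construct a QTSeries
#'
#' @param beatTimes beat times in ms.
#' @param qt per-beat QT in ms.
#' @param valid logical validity mask (default: all finite qt).
#' @param lead lead name.
#' @return A [QTSeries-class].
#' @examples
#' qts <- qtSeries(seq(0, 3000, by = 1000), c(400, 410, 400, 410))
#' stv(qts)
#' @export
qtSeries <- function(beatTimes, qt, valid = is.finite(qt), lead = "II") {
  new("QTSeries", beatTimes = as.numeric(beatTimes), qt = as.numeric(qt),
      valid = as.logical(valid), lead = lead)
}
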