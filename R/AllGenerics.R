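# Generics and accessors.

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("leadNames", function(x) standardGeneric("leadNames"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("recordDuration", function(x) standardGeneric("recordDuration"))
#' @rdname accessors
#' @export
setGeneric("leadSignal", function(x, lead) standardGeneric("leadSignal"))
#' @rdname accessors
#' @export
setGeneric("rTimes", function(x) standardGeneric("rTimes"))
#' @rdname accessors
#' @export
setGeneric("qtValues", function(x) standardGeneric("qtValues"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("beatLabels", function(x) standardGeneric("beatLabels"))
#' @rdname accessors
#' @export
setGeneric("stvTrue", function(x) standardGeneric("stvTrue"))
#' @rdname accessors
#' @export
setGeneric("fiducials", function(x) standardGeneric("fiducials"))

#' Short-term variability (BVR) of a QT series
#'
#' @param x a [QTSeries-class] or numeric vector of per-beat QT (ms).
#' @param ... further arguments, see methods.
#' @return BVR in ms.
#' @export
setGeneric("stv", function(x, ...) standardGeneric("stv"))

#' Poincare pairs of a QT series
#'
#' @param x a [QTSeries-class] or numeric vector.
#' @param ... further arguments.
#' @return data.frame with columns `qt` (QT(n)) and `qtNext` (QT(n+1)).
#' @export
setGeneric("poincarePairs", function(x, ...) standardGeneric("poincarePairs"))

## ---- accessor methods ----

#' Accessors for stvqt S4 containers
#'
#' `samplingRate`, `leadNames`, `nSamples`, `recordDuration` and
#' `leadSignal` read an [ECGRecord-class]; `rTimes`, `qtValues`,
#' `validMask`, `beatLabels` read beat-level objects; `stvTrue` returns
#' the analytic STV of a [GroundTruth-class]; `fiducials` returns the
#' annotated fiducial times of a [BeatTemplate-class].
#'
#' @param x an stvqt object.
#' @param lead lead name (for `leadSignal`).
#' @name accessors
NULL

#' @rdname accessors
setMethod("samplingRate", "ECGRecord", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "BeatTemplate", function(x) x@fs)
#' @rdname accessors
setMethod("leadNames", "ECGRecord", function(x) colnames(x@signal))
#' @rdname accessors
setMethod("nSamples", "ECGRecord", function(x) nrow(x@signal))
#' @rdname accessors
setMethod("recordDuration", "ECGRecord", function(x) nrow(x@signal) / x@fs)
#' @rdname accessors
setMethod("leadSignal", "ECGRecord", function(x, lead) {
  if (!lead %in% colnames(x@signal))
    stop("lead '", lead, "' not present in record", call. = FALSE)
  x@signal[, lead]
})
#' @rdname accessors
setMethod("rTimes", "GroundTruth", function(x) x@rTimes)
#' @rdname accessors
setMethod("rTimes", "QTSeries", function(x) x@beatTimes)
#' @rdname accessors
setMethod("qtValues", "GroundTruth", function(x) x@qtTrue)
#' @rdname accessors
setMethod("qtValues", "QTSeries", function(x) x@qt)
#' @rdname accessors
setMethod("validMask", "QTSeries", function(x) x@valid)
#' @rdname accessors
setMethod("beatLabels", "GroundTruth", function(x) x@labels)
#' @rdname accessors
setMethod("stvTrue", "GroundTruth", function(x) x@stvTrue)
#' @rdname accessors
setMethod("fiducials", "BeatTemplate", function(x) x@fiducials)

## ---- show methods ----

setMethod("show", "ECGRecord", function(object) {
  cat("ECGRecord:", ncol(object@signal), "lead(s),",
      nrow(object@signal), "samples @", object@fs, "Hz (",
      sprintf("%.1f", recordDuration(object)), "s )\n")
  cat("  leads:", paste(colnames(object@signal), collapse = ", "), "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@rTimes), "beats (",
      sum(object@labels == "pvc"), "PVC );",
      "analytic STV =", format(object@stvTrue, digits = 4), "ms\n")
})

setMethod("show", "BeatTemplate", function(object) {
  cat("BeatTemplate:", length(object@waveform), "samples @", object@fs,
      "Hz, averaged over", object@nBeats, "beats\n")
  f <- object@fiducials
  if (!anyNA(f)) {
    cat("  fiducials (ms): qrsOn", sprintf("%.1f", f["qrsOn"]),
        "| R", sprintf("%.1f", f["rPeak"]),
        "| tPeak", sprintf("%.1f", f["tPeak"]),
        "| tEnd", sprintf("%.1f", f["tEnd"]), "\n")
    cat("  template QT:", sprintf("%.1f", f["tEnd"] - f["qrsOn"]), "ms\n")
  }
})

setMethod("show", "QTSeries", function(object) {
  cat("QTSeries [", object@lead, "]:", length(object@qt), "beats,",
      sum(object@valid), "valid; mean QT",
      sprintf("%.1f", mean(object@qt[object@valid])), "ms\n")
})
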