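# Record and truth serialization: CSV signal + JSON sidecar + truth CSV.

#' Write an ECG record (and optional truth) to disk
#'
#' Writes `<name>.csv` (one column per lead, mV, rounded to 1e-6 mV),
#' `<name>.json` (sidecar with `fs`, `leads`, `t0`) and, when a truth is
#' supplied, `<name>_truth.csv` (`beat_time_ms`, `label`, `qt_true_ms`).
#'
#' @param record an [ECGRecord-class].
#' @param path output directory (created if missing).
#' @param name file stem.
#' @param truth optional [GroundTruth-class].
#' @return invisibly, the written paths.
#' @export
writeRecord <- function(record, path, name = "record", truth = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sigPath <- file.path(path, paste0(name, ".csv"))
  sidePath <- file.path(path, paste0(name, ".json"))
  data.table::fwrite(data.table::as.data.table(round(record@signal, 6)),
                     sigPath)
  jsonlite::write_json(
    list(fs = record@fs, leads = leadNames(record), t0 = record@t0),
    sidePath, auto_unbox = TRUE, digits = NA)
  paths <- c(signal = sigPath, sidecar = sidePath)
  if (!is.null(truth)) {
    trPath <- file.path(path, paste0(name, "_truth.csv"))
    data.table::fwrite(data.frame(beat_time_ms = truth@rTimes,
                                  label = truth@labels,
                                  qt_true_ms = truth@qtTrue), trPath)
    paths <- c(paths, truth = trPath)
  }
  invisible(paths)
}

#' Read an ECG record written by [writeRecord()]
#'
#' @param path directory containing the files.
#' @param name file stem.
#' @return list with `record` ([ECGRecord-class]) and `truth` (a partial
#'   [GroundTruth-class], or `NULL` when no truth table is present).
#' @export
readRecord <- function(path, name = "record") {
  sidePath <- file.path(path, paste0(name, ".json"))
  sigPath <- file.path(path, paste0(name, ".csv"))
  if (!file.exists(sidePath)) stop("sidecar not found: ", sidePath,
                                   call. = FALSE)
  side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
  for (field in c("fs", "leads", "t0"))
    if (is.null(side[[field]]))
      stop("sidecar field '", field, "' is missing in ", sidePath,
           call. = FALSE)
  sig <- as.matrix(data.table::fread(sigPath))
  if (!identical(colnames(sig), as.character(side$leads)))
    sig <- sig[, as.character(side$leads), drop = FALSE]
  record <- ecgRecord(sig, fs = side$fs, leadNames = side$leads,
                      t0 = side$t0)
  trPath <- file.path(path, paste0(name, "_truth.csv"))
  truth <- NULL
  if (file.exists(trPath)) {
    tr <- data.table::fread(trPath, data.table = FALSE)
    truth <- new("GroundTruth",
      rTimes = tr$beat_time_ms, qtTrue = tr$qt_true_ms,
      labels = tr$label,
      stOffset = stats::setNames(rep(0, ncol(sig)), colnames(sig)),
      stvTrue = NA_real_, seed = NA_integer_,
      beatInfo = data.frame(r_time_ms = tr$beat_time_ms,
                            qt_ms = tr$qt_true_ms, label = tr$label,
                            coupling_ms = NA_real_),
      morphology = list())
  }
  list(record = record, truth = truth)
}
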