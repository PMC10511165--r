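# Analysis configuration with study defaults.

#' Analysis pipeline configuration
#'
#' Tunable parameters of the measurement pipeline, with defaults used
#' throughout the package. All thresholds are surfaced here and in the
#' YAML interface ([readAnalysisConfig()]).
#'
#' @param lowpass50 apply a zero-phase 4th-order 50-Hz Butterworth
#'   low-pass before analysis (mirrors the recording systems' hardware
#'   filter).
#' @param highpassHz zero-phase 2nd-order Butterworth high-pass corner
#'   removing baseline wander before analysis, Hz (0 disables; default
#'   0.5, the conventional diagnostic-ECG baseline corner).
#' @param notchHz mains-interference notch center frequency, Hz
#'   (zero-phase band-stop, +/- 2 Hz; 0 disables; default 50).
#' @param templateCorrMin minimum correlation with the running average
#'   for a beat to enter the template (default 0.9).
#' @param beatCorrMin minimum segment-alignment correlation for a beat's
#'   QT to be considered valid (default 0.8).
#' @param prematurityFactor RR fraction of the trailing sinus mean below
#'   which a beat is premature (default 0.80).
#' @param morphCorrMin template correlation below which a premature beat
#'   is called a PVC (default 0.8).
#' @param minTemplateBeats minimum sinus beats required for a template.
#' @param maxTemplateBeats beats entering the template average are
#'   capped at this count (evenly subsampled); averaging gains little
#'   beyond ~100 beats while alignment cost grows linearly.
#' @param alignSearchMs half-width of the cross-correlation search, ms.
#' @param onsetWinMs QRS-onset re-alignment segment length, ms.
#' @param tEndWinMs T-end re-alignment segment length, ms.
#' @param tEndSearchMs tangent-method search window after the T peak, ms.
#' @param stWindowMs ST measurement window relative to the J point, ms.
#' @param prWindowMs PR (isoelectric reference) window relative to QRS
#'   onset, ms.
#' @param denominator STV denominator convention: `"beats"` (number of
#'   QT intervals analyzed; default) or `"differences"`.
#' @param surgeThresholdMs pre-VF surge detection threshold on the BVR
#'   change, ms.
#' @param pre5Mode placement of the "5 min pre-VF" 60-s window:
#'   `"centered"` (ends at VF - 4 min; default) or `"ending"` (ends at
#'   VF - 5 min).
#' @return list of class `AnalysisConfig`.
#' @export
analysisConfig <- function(lowpass50 = TRUE, highpassHz = 0.5,
                           notchHz = 50, templateCorrMin = 0.9,
                           beatCorrMin = 0.8, prematurityFactor = 0.80,
                           morphCorrMin = 0.8, minTemplateBeats = 8,
                           alignSearchMs = 20, onsetWinMs = 60,
                           tEndWinMs = 120, tEndSearchMs = 200,
                           maxTemplateBeats = 120,
                           stWindowMs = c(60, 80), prWindowMs = c(-30, -5),
                           denominator = c("beats", "differences"),
                           surgeThresholdMs = 1.4,
                           pre5Mode = c("centered", "ending")) {
  cfg <- list(lowpass50 = lowpass50, highpassHz = highpassHz,
              notchHz = notchHz, templateCorrMin = templateCorrMin,
              beatCorrMin = beatCorrMin,
              prematurityFactor = prematurityFactor,
              morphCorrMin = morphCorrMin,
              minTemplateBeats = minTemplateBeats,
              maxTemplateBeats = maxTemplateBeats,
              alignSearchMs = alignSearchMs, onsetWinMs = onsetWinMs,
              tEndWinMs = tEndWinMs, tEndSearchMs = tEndSearchMs,
              stWindowMs = stWindowMs, prWindowMs = prWindowMs,
              denominator = match.arg(denominator),
              surgeThresholdMs = surgeThresholdMs,
              pre5Mode = match.arg(pre5Mode))
  class(cfg) <- "AnalysisConfig"
  cfg
}

#' Read an AnalysisConfig from YAML
#'
#' Accepts either flat keys matching [analysisConfig()] arguments or the
#' sectioned layout (`fiducials:`, `rhythm:`, `metrics:`, `pipeline:`)
#' whose entries are merged into the flat configuration.
#'
#' @param path path to the YAML file.
#' @return an `AnalysisConfig`.
#' @export
readAnalysisConfig <- function(path) {
  y <- yaml::read_yaml(path)
  flat <- list()
  for (key in names(y)) {
    if (key %in% c("fiducials", "rhythm", "metrics", "pipeline"))
      flat <- modifyList(flat, y[[key]])
    else flat[[key]] <- y[[key]]
  }
  known <- names(formals(analysisConfig))
  unknown <- setdiff(names(flat), known)
  if (length(unknown))
    warning("ignoring unknown config keys: ",
            paste(unknown, collapse = ", "))
  do.call(analysisConfig, flat[intersect(names(flat), known)])
}

# md5 of the canonical YAML rendering of a config (for run logs).
configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}
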