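# Figures: Poincare plots and BVR trajectories.

#' Poincare plot of a QT series
#'
#' QT(n+1) against QT(n) over admissible successive pairs; increased
#' beat-to-beat lability widens the cloud perpendicular to the identity
#' line.
#'
#' @param qts a [QTSeries-class].
#' @return a ggplot object.
#' @export
plotPoincare <- function(qts) {
  p <- poincarePairs(qts)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$qt, y = .data$qtNext)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "QT(n) [ms]", y = "QT(n+1) [ms]",
                  title = paste("Poincare plot, lead", qts@lead)) +
    ggplot2::theme_minimal()
}

#' BVR trajectory across study windows
#'
#' @param tidy long-format data.frame with columns `animal`, `window`,
#'   `value` (BVR, ms), e.g. the BVR rows of [reportCohort()]'s output.
#' @param windowOrder window display order.
#' @return a ggplot object.
#' @export
plotBvrTrajectory <- function(tidy,
                              windowOrder = c("baseline", "ami5",
                                              "pre5", "pre1")) {
  tidy$window <- factor(tidy$window,
                        levels = intersect(windowOrder,
                                           unique(tidy$window)))
  ggplot2::ggplot(tidy, ggplot2::aes(x = .data$window, y = .data$value,
                                     group = .data$animal)) +
    ggplot2::geom_line(alpha = 0.5, colour = "grey40") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = NULL, y = "BVR [ms]") +
    ggplot2::theme_minimal()
}
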