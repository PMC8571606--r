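#' Plot a prediction against observations
#'
#' Base-graphics figure in the style of the propagation-experiment panels:
#' the deterministic forecast as a full line, observed focal frequencies as
#' points joined by a dotted line.
#'
#' @param predicted A `frequency_trajectory` (the forecast).
#' @param observed Optional `frequency_trajectory` of measurements.
#' @param main Plot title.
#' @return Invisibly, `NULL`. Draws on the active device.
#' @export
plot_prediction_vs_observation <- function(predicted, observed = NULL,
                                           main = "Focal strain frequency") {
  stopifnot(inherits(predicted, "frequency_trajectory"))
  graphics::plot(predicted$generation, focal_frequencies(predicted),
                 type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "Generations", ylab = "Focal frequency", main = main)
  if (!is.null(observed)) {
    graphics::points(observed$generation, focal_frequencies(observed), pch = 19)
    graphics::lines(observed$generation, focal_frequencies(observed), lty = 3)
  }
  graphics::abline(h = c(0.01, 0.99), col = "grey70", lty = 2)
  invisible(NULL)
}
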