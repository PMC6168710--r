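#' Plot accuracy as a function of stimulation length
#'
#' @param curves A single `accuracy_curve` or a named list of them (the
#'   names become the legend).
#' @param chance Chance level drawn as a dashed line (default 1/6).
#' @return A ggplot object.
#' @export
plot_accuracy_curve <- function(curves, chance = 1 / 6) {
  if (inherits(curves, "accuracy_curve")) curves <- list(decoder = curves)
  df <- do.call(rbind, lapply(names(curves), function(nm)
    data.frame(decoder = nm, length = curves[[nm]]$length,
               accuracy = curves[[nm]]$accuracy)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$accuracy,
                                   colour = .data$decoder)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "stimulation length (s)", y = "accuracy") +
    ggplot2::theme_minimal()
}

#' Rose histogram of phase angles
#'
#' Circular histogram of trial-wise phase deviations, as used to compare
#' the phase variability of cortical and scalp recordings.
#'
#' @param angles Angles in radians.
#' @param bins Number of angular bins (default 24).
#' @return A ggplot object.
#' @export
plot_phase_rose <- function(angles, bins = 24) {
  df <- data.frame(angle = (angles %% (2 * pi)) * 180 / pi)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle)) +
    ggplot2::geom_histogram(breaks = seq(0, 360, length.out = bins + 1),
                            fill = "steelblue", colour = "white") +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = NULL, y = "trials") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
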