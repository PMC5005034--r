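#' Plot a genomic interaction track
#'
#' Windowed scores as bars across the covered region. Difference tracks are
#' coloured by sign (gained contacts above zero, lost below), matching the
#' usual rendering of 4C subtraction tracks.
#'
#' @param object A `genomic_track`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genomic_track <- function(object, ...) {
  df <- as_tibble(object)
  df$gained <- df$score >= 0
  p <- ggplot2::ggplot(df, ggplot2::aes(
    xmin = .data$start, xmax = .data$end,
    ymin = pmin(.data$score, 0), ymax = pmax(.data$score, 0)
  ))
  if (attr(object, "normalisation") == "difference") {
    p <- p +
      ggplot2::geom_rect(ggplot2::aes(fill = .data$gained), show.legend = FALSE) +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b")) +
      ggplot2::geom_hline(yintercept = 0, linewidth = 0.3)
  } else {
    p <- p + ggplot2::geom_rect(fill = "grey30")
  }
  p +
    ggplot2::labs(
      x = "position (bp)",
      y = paste0("score (", attr(object, "normalisation"), ")"),
      title = attr(object, "sample_name"),
      subtitle = paste0(attr(object, "scheme"), " windows")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted qPCR standard curve
#'
#' Standards as points over the fitted `Ct ~ log10(quantity)` line.
#'
#' @param object A `standard_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.standard_curve <- function(object, ...) {
  df <- object$standards
  ggplot2::ggplot(df, ggplot2::aes(log10(.data$quantity), .data$ct)) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "log10(quantity)", y = "Ct",
      title = sprintf("slope %.3f, intercept %.2f, r² %.4f",
                      object$slope, object$intercept, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a simulated contact profile
#'
#' Per-fragment contact probabilities against fragment midpoint, showing the
#' distance decay around the bait and any planted enhancer folds.
#'
#' @param object An `interaction_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interaction_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$start + df$end) / 2
  ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$probability)) +
    ggplot2::geom_col(width = df$end - df$start, fill = "grey30") +
    ggplot2::labs(x = "fragment midpoint (bp)", y = "contact probability",
                  title = paste("condition", attr(object, "condition"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
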