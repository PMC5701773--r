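#' Interferogram for one analyte
#'
#' An interferogram visualises whether an intervention's mean percent
#' difference (MD) is analytically or clinically meaningful: the MD is drawn
#' as a bar against two horizontal reference lines, the desirable imprecision
#' specification (DSI, dashed) and the reference change value (RCV, solid).
#' A bar between the lines marks a change beyond the analytical goal but
#' within combined analytical plus biological noise; a bar beyond the RCV
#' line marks a clinically significant change. For analytes whose MD is
#' negative the reference lines are mirrored below zero so the comparison
#' stays a magnitude comparison.
#'
#' @param assessment a [ChangeAssessment-class] with finite MD, DSI and RCV.
#' @return A \code{ggplot} object; inspect or add layers before rendering.
#' @seealso [renderInterferogram()] to write the image file.
#' @export
plotInterferogram <- function(assessment) {
  stopifnot(methods::is(assessment, "ChangeAssessment"))
  md <- assessment@meanMD
  if (!all(is.finite(c(md, assessment@dsi, assessment@rcv)))) {
    stop("assessment must have finite MD, DSI and RCV", call. = FALSE)
  }
  side <- if (md < 0) -1 else 1
  df <- data.frame(what = "MD", md = md)
  thresholds <- data.frame(
    threshold = c("DSI", "RCV"),
    value = side * c(assessment@dsi, assessment@rcv)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$what, y = .data$md)) +
    ggplot2::geom_col(width = 0.4, fill = "grey35") +
    ggplot2::geom_hline(
      data = thresholds,
      ggplot2::aes(yintercept = .data$value, linetype = .data$threshold)
    ) +
    ggplot2::scale_linetype_manual(values = c(DSI = "dashed", RCV = "solid"),
                                   name = NULL) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      title = sprintf("%s (%s)", assessment@displayName, assessment@unit),
      subtitle = sprintf("MD %.1f%%  DSI %.1f%%  RCV %.1f%%",
                         reportRound(md), reportRound(assessment@dsi),
                         reportRound(assessment@rcv)),
      x = NULL, y = "Mean difference (%)"
    ) +
    ggplot2::theme_classic()
}

#' Render an interferogram to an image file
#'
#' @param assessment a [ChangeAssessment-class].
#' @param path output image path; the format follows the extension
#'   (png, pdf, svg, ... — anything \code{ggplot2::ggsave} understands).
#' @param width,height device size in inches.
#' @return Invisibly, the \code{ggplot} object that was written.
#' @export
renderInterferogram <- function(assessment, path, width = 3.5, height = 4) {
  p <- plotInterferogram(assessment)
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = 150)
  invisible(p)
}
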