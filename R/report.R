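#' Format a p-value for report display
#'
#' Three decimals with a display floor: anything below 0.001 renders as
#' "0.001", matching the convention of clinical-chemistry results tables.
#'
#' @param p numeric vector of p-values.
#' @return Character vector.
#' @export
formatPValue <- function(p) {
  sprintf("%.3f", pmax(p, 0.001))
}

#' Classify changes from summary numbers
#'
#' Applies the three-tier significance rule directly to per-analyte summary
#' quantities — useful when only a published results table (MD, DSI, RCV, P)
#' is available rather than raw paired measurements. Vectorised.
#'
#' @param mean_md mean percent difference(s).
#' @param dsi,rcv thresholds, percent.
#' @param p two-sided p-value(s); \code{NA} leaves the statistical flag
#'   \code{NA}.
#' @param config an [AnalysisConfig-class] (controls alpha and whether the
#'   comparison uses the absolute or signed MD).
#' @return A \code{data.frame} with logical columns
#'   \code{statistically_significant}, \code{exceeds_dsi},
#'   \code{clinically_significant}.
#' @examples
#' classifyChange(mean_md = c(2.2, -6.5), dsi = c(1.4, 10.0),
#'                rcv = c(8.0, 56.0), p = c(0.001, 0.002))
#' @export
classifyChange <- function(mean_md, dsi, rcv, p = NA_real_,
                           config = analysisConfig()) {
  md_cmp <- if (config@mdComparison == "absolute") abs(mean_md) else mean_md
  data.frame(
    statistically_significant = p < config@alpha,
    exceeds_dsi = md_cmp > dsi,
    clinically_significant = md_cmp > rcv
  )
}

.report_columns <- c("analyte_id", "display_name", "unit", "n",
                     "median_t0", "q1_t0", "q3_t0",
                     "median_t1", "q1_t1", "q3_t1",
                     "p", "mean_md", "dsi", "rcv",
                     "statistically_significant", "exceeds_dsi",
                     "clinically_significant")

#' Write an assessment report
#'
#' Two styles:
#' \itemize{
#'   \item \code{"tidy"}: one machine-readable CSV row per analyte with all
#'     numeric fields at full precision; reloads numerically intact.
#'   \item \code{"wide"}: a fixed-layout results table in the style of a
#'     clinical-chemistry publication — values at one decimal (half away
#'     from zero), medians with the interquartile range in parentheses,
#'     p-values at three decimals floored at 0.001, and the mean difference
#'     suffixed \code{*} when it exceeds the analyte's DSI.
#' }
#'
#' @param assessments the \link[S4Vectors]{DataFrame} from [assessPanel()]
#'   (or anything coercible with the same columns); must be non-empty.
#' @param path destination file path.
#' @param style \code{"tidy"} (default) or \code{"wide"}.
#' @return Invisibly, \code{path}.
#' @export
writeReport <- function(assessments, path, style = c("tidy", "wide")) {
  style <- match.arg(style)
  df <- as.data.frame(assessments)
  missing_cols <- setdiff(.report_columns, colnames(df))
  if (length(missing_cols) > 0L) {
    stop("assessment table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("no assessments to report", call. = FALSE)
  if (style == "tidy") {
    utils::write.csv(df[, .report_columns], path, row.names = FALSE,
                     fileEncoding = "UTF-8")
    return(invisible(path))
  }
  fmt_iqr <- function(m, q1, q3) sprintf("%g (%g-%g)", m, q1, q3)
  star <- ifelse(df$exceeds_dsi, "*", "")
  wide <- data.frame(
    Analyte = sprintf("%s (%s)", df$display_name, df$unit),
    `DSI (%)` = sprintf("%.1f", reportRound(df$dsi)),
    `Basal values (T0)` = fmt_iqr(df$median_t0, df$q1_t0, df$q3_t0),
    `Values after intervention (T1)` = fmt_iqr(df$median_t1, df$q1_t1, df$q3_t1),
    P = formatPValue(df$p),
    `Mean difference (%)` = paste0(sprintf("%.1f", reportRound(df$mean_md)), star),
    `RCV (%)` = sprintf("%.1f", reportRound(df$rcv)),
    check.names = FALSE
  )
  lines <- c(paste(colnames(wide), collapse = "\t"),
             apply(wide, 1L, paste, collapse = "\t"))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read back a tidy report
#'
#' @param path a CSV written by \code{writeReport(style = "tidy")}.
#' @return A \code{data.frame} with the same columns.
#' @export
readReport <- function(path) {
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
}
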