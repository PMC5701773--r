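#' Create an analysis configuration
#'
#' @param z normal quantile for the RCV confidence level; 1.96 corresponds to
#'   95\% bidirectional confidence.
#' @param alpha significance level for the signed-rank test.
#' @param exactTestMaxN largest effective n for exact enumeration of the
#'   signed-rank null; beyond it the tie-corrected normal approximation with
#'   continuity correction is used.
#' @param mdComparison compare \code{"absolute"} (default) or \code{"signed"}
#'   mean percent difference against the DSI/RCV thresholds. The study-style
#'   default is absolute: a decrease of 10\% is as much of a change as an
#'   increase of 10\%.
#'
#' @return An [AnalysisConfig-class].
#' @examples
#' analysisConfig()
#' analysisConfig(alpha = 0.01, mdComparison = "signed")
#' @export
analysisConfig <- function(z = 1.96, alpha = 0.05, exactTestMaxN = 25L,
                           mdComparison = c("absolute", "signed")) {
  mdComparison <- match.arg(mdComparison)
  new("AnalysisConfig", z = as.numeric(z), alpha = as.numeric(alpha),
      exactTestMaxN = as.integer(exactTestMaxN), mdComparison = mdComparison)
}

#' Read an analysis configuration from a YAML file
#'
#' The file is a flat key-value mapping; recognised keys are \code{z},
#' \code{alpha}, \code{exact_test_max_n} and \code{md_comparison}. Missing
#' keys keep their defaults; unknown keys raise an error. Arguments passed in
#' \code{...} override the file (the CLI uses this for flag overrides).
#'
#' @param path YAML file path.
#' @param ... overrides forwarded to [analysisConfig()].
#' @return An [AnalysisConfig-class].
#' @export
readAnalysisConfig <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  key_map <- c(z = "z", alpha = "alpha", exact_test_max_n = "exactTestMaxN",
               md_comparison = "mdComparison")
  unknown <- setdiff(names(cfg), names(key_map))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- stats::setNames(cfg, key_map[names(cfg)])
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(analysisConfig, args)
}

#' @export
setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n",
      sprintf("  z:             %.4g\n", object@z),
      sprintf("  alpha:         %.4g\n", object@alpha),
      sprintf("  exactTestMaxN: %d\n", object@exactTestMaxN),
      sprintf("  mdComparison:  %s\n", object@mdComparison), sep = "")
})
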