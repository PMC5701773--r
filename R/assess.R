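#' Median and interquartile range of a measurement vector
#'
#' Quartiles follow the linear-interpolation convention
#' (\code{stats::quantile} type 7), the default of mainstream statistical
#' software.
#'
#' @param values non-empty numeric vector.
#' @return Named numeric vector \code{c(median, q1, q3)}.
#' @examples
#' summarizeMeasurements(c(1, 2, 3, 4, 5))  # 3, 2, 4
#' @export
summarizeMeasurements <- function(values) {
  if (length(values) == 0L) stop("empty measurement vector", call. = FALSE)
  if (anyNA(values)) stop("measurements must not be missing", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.5, 0.25, 0.75), names = FALSE,
                       type = 7)
  c(median = q[1L], q1 = q[2L], q3 = q[3L])
}

# The three-tier rule: statistical (p < alpha), analytical (MD beyond DSI),
# clinical (MD beyond RCV). Comparison uses |MD| by default; "signed"
# compares the raw MD, making any decrease non-significant.
.classify <- function(mean_md, dsi, rcv, p, config) {
  md_cmp <- if (config@mdComparison == "absolute") abs(mean_md) else mean_md
  list(
    statisticallySignificant = p < config@alpha,
    exceedsDSI = md_cmp > dsi,
    clinicallySignificant = md_cmp > rcv
  )
}

#' Assess one analyte's paired measurements
#'
#' Runs the full per-analyte procedure: basal and post-intervention medians
#' with quartiles, exact Wilcoxon signed-rank test, mean percent difference
#' (MD), DSI and RCV thresholds from the analyte's CVs, and the three-tier
#' significance classification — statistically significant when p < alpha,
#' exceeding the analytical goal when MD is beyond DSI, clinically
#' significant when MD is beyond RCV. A panel in which every subject's two
#' measurements are identical carries no signed-rank information; it is
#' reported as "no change" with p = 1 and a warning rather than an error, so
#' panel-level runs stay total.
#'
#' @param t0,t1 paired measurement vectors for one analyte (>= 2 pairs).
#' @param spec a single-row [AnalyteRegistry-class] (or the full registry
#'   plus \code{analyteId} selecting the row).
#' @param config an [AnalysisConfig-class].
#' @param analyteId optional id selecting the registry row.
#' @return A [ChangeAssessment-class].
#' @export
assessAnalyte <- function(t0, t1, spec, config = analysisConfig(),
                          analyteId = NULL) {
  stopifnot(methods::is(spec, "AnalyteRegistry"))
  if (!is.null(analyteId)) {
    hit <- match(analyteId, spec$analyte_id)
    if (is.na(hit)) stop("analyte '", analyteId, "' not in registry", call. = FALSE)
    spec <- spec[hit, ]
  }
  if (nrow(spec) != 1L) stop("'spec' must be a single registry row", call. = FALSE)
  if (length(t0) < 2L) stop("need at least 2 measurement pairs", call. = FALSE)
  s0 <- summarizeMeasurements(t0)
  s1 <- summarizeMeasurements(t1)
  p <- if (all(t1 - t0 == 0)) {
    warning("analyte '", spec$analyte_id,
            "': all differences zero; no change detected, P reported as 1.00",
            call. = FALSE)
    1
  } else {
    wilcoxonSignedRank(t0, t1, config = config)@pTwoSided
  }
  md <- meanDifference(t0, t1)
  dsi <- computeDSI(spec$cv_i)
  rcv <- computeRCV(spec$cv_a, spec$cv_i, z = config@z)
  flags <- .classify(md$meanMD, dsi, rcv, p, config)
  methods::new("ChangeAssessment",
    analyteId = spec$analyte_id, displayName = spec$display_name,
    unit = spec$unit, n = length(t0),
    medianT0 = s0[["median"]], q1T0 = s0[["q1"]], q3T0 = s0[["q3"]],
    medianT1 = s1[["median"]], q1T1 = s1[["q1"]], q3T1 = s1[["q3"]],
    pTwoSided = p, meanMD = md$meanMD, dsi = dsi, rcv = rcv,
    statisticallySignificant = flags$statisticallySignificant,
    exceedsDSI = flags$exceedsDSI,
    clinicallySignificant = flags$clinicallySignificant)
}

#' @export
setMethod("show", "ChangeAssessment", function(object) {
  star <- if (object@exceedsDSI) "*" else ""
  cat(sprintf("ChangeAssessment: %s (%s), n = %d\n",
              object@displayName, object@unit, object@n),
      sprintf("  T0 %g (%g-%g)  T1 %g (%g-%g)\n",
              object@medianT0, object@q1T0, object@q3T0,
              object@medianT1, object@q1T1, object@q3T1),
      sprintf("  P = %s  MD = %g%%%s  DSI = %g%%  RCV = %g%%\n",
              formatPValue(object@pTwoSided), reportRound(object@meanMD), star,
              reportRound(object@dsi), reportRound(object@rcv)),
      sprintf("  statistically significant: %s; clinically significant: %s\n",
              object@statisticallySignificant, object@clinicallySignificant),
      sep = "")
})

.assessment_row <- function(a) {
  S4Vectors::DataFrame(
    analyte_id = a@analyteId, display_name = a@displayName, unit = a@unit,
    n = a@n,
    median_t0 = a@medianT0, q1_t0 = a@q1T0, q3_t0 = a@q3T0,
    median_t1 = a@medianT1, q1_t1 = a@q1T1, q3_t1 = a@q3T1,
    p = a@pTwoSided, mean_md = a@meanMD, dsi = a@dsi, rcv = a@rcv,
    statistically_significant = a@statisticallySignificant,
    exceeds_dsi = a@exceedsDSI,
    clinically_significant = a@clinicallySignificant
  )
}

#' Assess every analyte of a paired panel
#'
#' Maps [assessAnalyte()] over a panel. Every panel analyte must be present
#' in the registry; assessments come back in registry order.
#'
#' @param panel a [PairedPanel-class].
#' @param registry an [AnalyteRegistry-class] covering all panel analytes.
#' @param config an [AnalysisConfig-class].
#' @return A \link[S4Vectors]{DataFrame} with one row per analyte (columns as
#'   in \code{\link{ChangeAssessment-class}}, snake_case). Deterministic given
#'   its inputs.
#' @export
assessPanel <- function(panel, registry, config = analysisConfig()) {
  stopifnot(methods::is(panel, "PairedPanel"),
            methods::is(registry, "AnalyteRegistry"))
  missing_ids <- setdiff(rownames(panel), registry$analyte_id)
  if (length(missing_ids) > 0L) {
    stop("panel analyte(s) missing from registry: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  ids <- intersect(registry$analyte_id, rownames(panel))
  t0 <- basalValues(panel)
  t1 <- postValues(panel)
  rows <- lapply(ids, function(id) {
    .assessment_row(assessAnalyte(t0[id, ], t1[id, ], registry,
                                  config = config, analyteId = id))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$analyte_id
  S4Vectors::metadata(out) <- list(config = config)
  out
}
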