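#' @import methods
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Per-analyte variation registry
#'
#' An \code{AnalyteRegistry} is a \link[S4Vectors]{DataFrame} with one row per
#' analyte and the columns \code{analyte_id}, \code{display_name}, \code{unit},
#' \code{cv_a} (analytical coefficient of variation, percent), \code{cv_i}
#' (within-subject biological variation, percent) and \code{cv_g} (optional
#' between-subject biological variation, percent; \code{NA} when unknown).
#' Units are opaque labels: every statistic in this package is scale-free
#' (percent CVs and percent differences), so no unit conversion is ever done.
#'
#' @slot .Data,rownames,nrows,listData,elementType,elementMetadata,metadata
#'   inherited from \code{DFrame}.
#' @seealso [AnalyteRegistry()], [loadRegistry()], [waterIntakeRegistry()]
#' @export
setClass("AnalyteRegistry", contains = "DFrame")

.registry_columns <- c("analyte_id", "display_name", "unit", "cv_a", "cv_i", "cv_g")

setValidity("AnalyteRegistry", function(object) {
  msgs <- character()
  missing_cols <- setdiff(.registry_columns, colnames(object))
  if (length(missing_cols) > 0L) {
    return(paste("missing registry column(s):", paste(missing_cols, collapse = ", ")))
  }
  if (!is.character(object$analyte_id)) {
    msgs <- c(msgs, "'analyte_id' must be character")
  }
  if (anyDuplicated(object$analyte_id)) {
    dup <- unique(object$analyte_id[duplicated(object$analyte_id)])
    msgs <- c(msgs, paste("duplicate analyte_id:", paste(dup, collapse = ", ")))
  }
  if (!is.numeric(object$cv_a) || !is.numeric(object$cv_i) || !is.numeric(object$cv_g)) {
    msgs <- c(msgs, "'cv_a', 'cv_i' and 'cv_g' must be numeric")
  } else {
    if (anyNA(object$cv_a) || any(object$cv_a < 0)) {
      msgs <- c(msgs, "'cv_a' must be >= 0 and non-missing")
    }
    if (anyNA(object$cv_i) || any(object$cv_i <= 0)) {
      msgs <- c(msgs, "'cv_i' must be > 0 and non-missing")
    }
    if (any(!is.na(object$cv_g) & object$cv_g <= 0)) {
      msgs <- c(msgs, "'cv_g' must be > 0 when present")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Analysis constants for the interference assessment
#'
#' Holds the study-level constants: the normal quantile \code{z} used in the
#' reference change value (1.96 for 95\% bidirectional confidence), the
#' significance level \code{alpha} for the Wilcoxon signed-rank test, the
#' largest effective sample size at which the exact signed-rank null is
#' enumerated, and whether the mean-difference classification compares the
#' signed or the absolute mean percent difference against DSI/RCV.
#'
#' @slot z positive numeric, normal quantile (default 1.96).
#' @slot alpha significance level in (0, 1) (default 0.05).
#' @slot exactTestMaxN integer >= 5; exact enumeration is used for effective
#'   sample sizes up to this value, the tie-corrected normal approximation
#'   with continuity correction beyond it (default 25).
#' @slot mdComparison \code{"absolute"} (default) or \code{"signed"}.
#' @seealso [analysisConfig()]
#' @export
setClass("AnalysisConfig",
  representation(
    z = "numeric",
    alpha = "numeric",
    exactTestMaxN = "integer",
    mdComparison = "character"
  ),
  prototype(
    z = 1.96,
    alpha = 0.05,
    exactTestMaxN = 25L,
    mdComparison = "absolute"
  )
)

setValidity("AnalysisConfig", function(object) {
  msgs <- character()
  if (length(object@z) != 1L || !is.finite(object@z) || object@z <= 0) {
    msgs <- c(msgs, "'z' must be a single positive number")
  }
  if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
      object@alpha <= 0 || object@alpha >= 1) {
    msgs <- c(msgs, "'alpha' must lie strictly between 0 and 1")
  }
  if (length(object@exactTestMaxN) != 1L || is.na(object@exactTestMaxN) ||
      object@exactTestMaxN < 5L) {
    msgs <- c(msgs, "'exactTestMaxN' must be an integer >= 5")
  }
  if (length(object@mdComparison) != 1L ||
      !object@mdComparison %in% c("absolute", "signed")) {
    msgs <- c(msgs, "'mdComparison' must be \"absolute\" or \"signed\"")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of a paired signed-rank test
#'
#' @slot wPlus sum of the ranks of positive differences (mid-ranks under ties,
#'   so possibly half-integer).
#' @slot nEffective number of pairs remaining after zero-difference handling.
#' @slot pTwoSided two-sided p-value in (0, 1].
#' @slot method \code{"exact"} or \code{"normal_approximation"}.
#' @slot zerosDropped number of zero differences removed before ranking.
#' @seealso [wilcoxonSignedRank()]
#' @export
setClass("TestResult",
  representation(
    wPlus = "numeric",
    nEffective = "integer",
    pTwoSided = "numeric",
    method = "character",
    zerosDropped = "integer"
  )
)

setValidity("TestResult", function(object) {
  msgs <- character()
  # under Pratt-style zero handling the ranks of the nonzero differences are
  # taken from the joint ranking, so the ceiling includes the zeros
  n_rank <- object@nEffective + object@zerosDropped
  maxw <- n_rank * (n_rank + 1) / 2
  if (object@wPlus < 0 || object@wPlus > maxw) {
    msgs <- c(msgs, "wPlus outside [0, n(n+1)/2]")
  }
  if (!is.finite(object@pTwoSided) || object@pTwoSided <= 0 || object@pTwoSided > 1) {
    msgs <- c(msgs, "pTwoSided must lie in (0, 1]")
  }
  if (!object@method %in% c("exact", "normal_approximation")) {
    msgs <- c(msgs, "unknown method")
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-analyte change assessment
#'
#' One row of the study-style results table: sample size, basal and
#' post-intervention medians with interquartile ranges, the two-sided
#' signed-rank p-value, the mean percent difference (MD), the desirable
#' imprecision specification (DSI), the reference change value (RCV), and the
#' three significance flags. Because DSI < RCV always holds, a clinically
#' significant assessment (|MD| beyond RCV) necessarily also exceeds DSI; this
#' is asserted at construction.
#'
#' @slot analyteId,displayName,unit identity of the analyte.
#' @slot n number of paired subjects.
#' @slot medianT0,q1T0,q3T0 basal median and quartiles, analyte units.
#' @slot medianT1,q1T1,q3T1 post-intervention median and quartiles.
#' @slot pTwoSided two-sided Wilcoxon signed-rank p-value.
#' @slot meanMD mean of the per-subject percent differences, percent.
#' @slot dsi,rcv thresholds, percent.
#' @slot statisticallySignificant p < alpha.
#' @slot exceedsDSI MD beyond the DSI threshold.
#' @slot clinicallySignificant MD beyond the RCV threshold.
#' @seealso [assessAnalyte()], [assessPanel()]
#' @export
setClass("ChangeAssessment",
  representation(
    analyteId = "character",
    displayName = "character",
    unit = "character",
    n = "integer",
    medianT0 = "numeric", q1T0 = "numeric", q3T0 = "numeric",
    medianT1 = "numeric", q1T1 = "numeric", q3T1 = "numeric",
    pTwoSided = "numeric",
    meanMD = "numeric",
    dsi = "numeric",
    rcv = "numeric",
    statisticallySignificant = "logical",
    exceedsDSI = "logical",
    clinicallySignificant = "logical"
  )
)

setValidity("ChangeAssessment", function(object) {
  msgs <- character()
  if (object@dsi <= 0 || object@rcv <= 0) {
    msgs <- c(msgs, "dsi and rcv must be positive")
  }
  if (object@clinicallySignificant && !object@exceedsDSI) {
    msgs <- c(msgs, "clinicallySignificant implies exceedsDSI (DSI < RCV)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Paired basal / post-intervention analyte panel
#'
#' A \code{PairedPanel} is a \link[SummarizedExperiment]{SummarizedExperiment}
#' whose rows are analytes, whose columns are subjects, and whose two assays
#' \code{"t0"} (basal) and \code{"t1"} (post-intervention) carry the paired
#' measurements in the analyte's own units. The crossing is complete: every
#' subject has both measurements for every analyte, and all values are
#' positive (the basal value is the denominator of every percent difference).
#'
#' @seealso [PairedPanel()], [readPanel()], [simulatePanel()]
#' @export
setClass("PairedPanel", contains = "SummarizedExperiment")

setValidity("PairedPanel", function(object) {
  msgs <- character()
  anames <- SummarizedExperiment::assayNames(object)
  if (!all(c("t0", "t1") %in% anames)) {
    return("assays 't0' and 't1' are required")
  }
  t0 <- SummarizedExperiment::assay(object, "t0")
  t1 <- SummarizedExperiment::assay(object, "t1")
  if (anyNA(t0) || anyNA(t1)) {
    msgs <- c(msgs, "measurements must not be missing (complete crossing)")
  } else {
    if (any(t0 <= 0)) msgs <- c(msgs, "basal (t0) values must be positive")
    if (any(t1 < 0)) msgs <- c(msgs, "post (t1) values must be non-negative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msgs <- c(msgs, "rows must carry unique analyte identifiers")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
    msgs <- c(msgs, "columns must carry unique subject identifiers")
  }
  if (length(msgs)) msgs else TRUE
})

#' Simulation settings for a paired panel
#'
#' Describes the generative model used by [simulatePanel()]: each subject's
#' homeostatic set point scatters around the population central value with
#' between-subject CV (\code{cv_g}), each phase adds independent within-subject
#' biological fluctuation (CV \code{cv_i}) and analytical noise (CV
#' \code{cv_a}), and the post-intervention value is additionally shifted by a
#' signed percent effect \code{delta}.
#'
#' @slot nSubjects integer >= 2 (study design default 20).
#' @slot registry an [AnalyteRegistry-class] supplying per-analyte CVs.
#' @slot setPoints named numeric, population central value per analyte
#'   (positive, analyte units).
#' @slot cvGDefault percent used when the registry has no \code{cv_g}.
#' @slot delta named numeric, induced signed percent shift at t1 per analyte.
#' @slot seed integer master seed; fixed seed gives bit-identical panels.
#' @slot distribution \code{"normal"} (truncated relative-noise factors,
#'   default) or \code{"lognormal"}.
#' @seealso [simulationConfig()], [simulatePanel()]
#' @export
setClass("SimulationConfig",
  representation(
    nSubjects = "integer",
    registry = "AnalyteRegistry",
    setPoints = "numeric",
    cvGDefault = "numeric",
    delta = "numeric",
    seed = "integer",
    distribution = "character"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  ids <- object@registry$analyte_id
  if (length(object@nSubjects) != 1L || is.na(object@nSubjects) ||
      object@nSubjects < 2L) {
    msgs <- c(msgs, "'nSubjects' must be an integer >= 2")
  }
  if (is.null(names(object@setPoints)) || !setequal(names(object@setPoints), ids)) {
    msgs <- c(msgs, "'setPoints' must be named for exactly the registry analytes")
  } else if (anyNA(object@setPoints) || any(object@setPoints <= 0)) {
    msgs <- c(msgs, "'setPoints' must be positive")
  }
  if (is.null(names(object@delta)) || !setequal(names(object@delta), ids)) {
    msgs <- c(msgs, "'delta' must be named for exactly the registry analytes")
  }
  if (length(object@cvGDefault) != 1L || is.na(object@cvGDefault) ||
      object@cvGDefault <= 0) {
    msgs <- c(msgs, "'cvGDefault' must be a positive percent")
  }
  if (length(object@seed) != 1L || is.na(object@seed)) {
    msgs <- c(msgs, "'seed' must be a single integer")
  }
  if (length(object@distribution) != 1L ||
      !object@distribution %in% c("normal", "lognormal")) {
    msgs <- c(msgs, "'distribution' must be \"normal\" or \"lognormal\"")
  }
  if (length(msgs)) msgs else TRUE
})
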