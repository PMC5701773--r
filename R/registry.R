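#' Construct an analyte registry
#'
#' @param analyte_id character vector of unique short analyte tokens.
#' @param display_name human-readable analyte names (defaults to the ids).
#' @param unit unit labels; opaque, never converted.
#' @param cv_a analytical coefficients of variation, percent (>= 0).
#' @param cv_i within-subject biological variation, percent (> 0).
#' @param cv_g optional between-subject biological variation, percent;
#'   \code{NA} where unknown (only the simulator uses it).
#'
#' @return An [AnalyteRegistry-class] with one row per analyte.
#' @examples
#' AnalyteRegistry("urea", "Urea", "mmol/L", cv_a = 3.0, cv_i = 12.1)
#' @export
AnalyteRegistry <- function(analyte_id, display_name = analyte_id,
                            unit = "", cv_a, cv_i, cv_g = NA_real_) {
  n <- length(analyte_id)
  df <- S4Vectors::DataFrame(
    analyte_id = as.character(analyte_id),
    display_name = rep_len(as.character(display_name), n),
    unit = rep_len(as.character(unit), n),
    cv_a = rep_len(as.numeric(cv_a), n),
    cv_i = rep_len(as.numeric(cv_i), n),
    cv_g = rep_len(as.numeric(cv_g), n)
  )
  rownames(df) <- df$analyte_id
  new("AnalyteRegistry", df)
}

#' @describeIn AnalyteRegistry analyte identifiers of a registry.
#' @param x an \code{AnalyteRegistry}.
#' @export
analyteIds <- function(x) x$analyte_id

#' @describeIn AnalyteRegistry analytical CVs (percent), named by analyte.
#' @export
cvA <- function(x) stats::setNames(x$cv_a, x$analyte_id)

#' @describeIn AnalyteRegistry within-subject biological CVs (percent).
#' @export
cvI <- function(x) stats::setNames(x$cv_i, x$analyte_id)

#' @describeIn AnalyteRegistry between-subject biological CVs (percent;
#'   \code{NA} where the registry does not carry one).
#' @export
cvG <- function(x) stats::setNames(x$cv_g, x$analyte_id)

#' @export
setMethod("show", "AnalyteRegistry", function(object) {
  cat(sprintf("AnalyteRegistry with %d analyte(s)\n", nrow(object)))
  methods::callNextMethod()
})

.parse_cv <- function(raw, field, rows, strict, positive = FALSE) {
  suppressWarnings(val <- as.numeric(raw))
  bad <- !is.na(raw) & trimws(raw) != "" & trimws(raw) != "NA" & is.na(val)
  empty <- is.na(raw) | trimws(raw) %in% c("", "NA")
  if (field != "cv_g") bad <- bad | empty
  if (any(bad)) {
    if (strict || !all(empty[bad])) {
      stop(sprintf("registry row %d: field '%s' is not numeric (got \"%s\")",
                   rows[which(bad)[1L]], field, raw[which(bad)[1L]]),
           call. = FALSE)
    }
  }
  val
}

#' Read an analyte registry from a CSV file
#'
#' The file must have a header line naming
#' \code{analyte_id,display_name,unit,cv_a,cv_i,cv_g}; an empty \code{cv_g}
#' cell means "not available". A header-only file yields an empty registry.
#'
#' @param path path to the registry CSV.
#' @param strict when \code{TRUE} (default) reject duplicate analyte ids and
#'   non-numeric CV cells with an error naming the offending row; when
#'   \code{FALSE}, offending rows are dropped with a warning.
#'
#' @return An [AnalyteRegistry-class].
#' @examples
#' reg <- loadRegistry(system.file("extdata", "water_intake_registry.csv",
#'                                 package = "RCVassess"))
#' nrow(reg)
#' @export
loadRegistry <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    stop("registry file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(.registry_columns, colnames(raw))
  if (length(missing_cols) > 0L) {
    stop("registry header lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(AnalyteRegistry(character(), character(), character(),
                           numeric(), numeric(), numeric()))
  }
  rows <- seq_len(nrow(raw)) + 1L  # header is line 1
  cv_a <- .parse_cv(raw$cv_a, "cv_a", rows, strict)
  cv_i <- .parse_cv(raw$cv_i, "cv_i", rows, strict)
  cv_g <- .parse_cv(raw$cv_g, "cv_g", rows, strict)
  keep <- !is.na(cv_a) & !is.na(cv_i)
  if (strict) {
    dup <- duplicated(raw$analyte_id)
    if (any(dup)) {
      stop(sprintf("registry row %d: duplicate analyte_id '%s'",
                   rows[which(dup)[1L]], raw$analyte_id[which(dup)[1L]]),
           call. = FALSE)
    }
  } else {
    drop <- duplicated(raw$analyte_id) | !keep
    if (any(drop)) {
      warning(sprintf("dropping %d invalid/duplicate registry row(s)", sum(drop)),
              call. = FALSE)
    }
    keep <- keep & !duplicated(raw$analyte_id)
    raw <- raw[keep, , drop = FALSE]
    cv_a <- cv_a[keep]; cv_i <- cv_i[keep]; cv_g <- cv_g[keep]
  }
  AnalyteRegistry(raw$analyte_id, raw$display_name, raw$unit,
                  cv_a, cv_i, cv_g)
}

#' Write an analyte registry to a CSV file
#'
#' Round-trips with [loadRegistry()] field-for-field; an absent \code{cv_g}
#' is written as an empty cell and reloads as \code{NA}, never as 0.
#'
#' @param registry an [AnalyteRegistry-class]; must be non-empty.
#' @param path destination file path.
#' @return Invisibly, \code{path}.
#' @export
saveRegistry <- function(registry, path) {
  stopifnot(methods::is(registry, "AnalyteRegistry"))
  if (nrow(registry) == 0L) {
    stop("refusing to write an empty registry", call. = FALSE)
  }
  df <- as.data.frame(registry)[, .registry_columns]
  utils::write.csv(df, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' Bundled registry: 16 clinical chemistry analytes from a water-intake study
#'
#' The package ships the per-analyte variation data of a published
#' preanalytical study of 300 mL water intake one hour before phlebotomy:
#' analytical CVs from the originating laboratory's internal quality control
#' and within-subject biological CVs from the Westgard biological-variation
#' database, for 16 routine serum/plasma analytes (glucose, total proteins,
#' urea, creatinine, cystatin C, total bilirubin, total cholesterol, HDL and
#' LDL cholesterol, triglycerides, uric acid, hsCRP, GGT, AST, ALT, LD).
#'
#' @return An [AnalyteRegistry-class] with 16 rows. \code{cv_g} is absent
#'   (the study did not report between-subject variation); the simulator
#'   substitutes its own default.
#' @examples
#' waterIntakeRegistry()
#' @export
waterIntakeRegistry <- function() {
  loadRegistry(system.file("extdata", "water_intake_registry.csv",
                           package = "RCVassess", mustWork = TRUE))
}

#' Bundled published summary of the water-intake study
#'
#' Per-analyte published summary statistics of the same study as
#' [waterIntakeRegistry()]: basal and post-intake medians with quartiles,
#' two-sided Wilcoxon p-values, mean percent differences (MD), and the
#' published DSI and RCV thresholds, as printed (one decimal). The raw
#' per-subject measurements were never released, so these printed summaries
#' are the only real-data surface available: the package uses the medians as
#' default simulation set points and the printed MD/DSI/RCV columns to
#' reproduce the study's significance classification.
#'
#' @return A \code{data.frame} with 16 rows and columns \code{analyte_id},
#'   \code{median_t0}, \code{q1_t0}, \code{q3_t0}, \code{median_t1},
#'   \code{q1_t1}, \code{q3_t1}, \code{p}, \code{mean_md}, \code{dsi},
#'   \code{rcv}.
#' @export
waterIntakeSummary <- function() {
  utils::read.csv(system.file("extdata", "water_intake_study_summary.csv",
                              package = "RCVassess", mustWork = TRUE),
                  fileEncoding = "UTF-8")
}
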