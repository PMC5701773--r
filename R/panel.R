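#' Construct a paired panel
#'
#' @param t0,t1 numeric matrices, analytes in rows and subjects in columns,
#'   with matching dimnames: basal and post-intervention measurements.
#' @param registry optional [AnalyteRegistry-class]; when given, its rows for
#'   the panel analytes are attached as row metadata.
#' @return A [PairedPanel-class].
#' @examples
#' t0 <- matrix(c(4.8, 73), 2, 3, dimnames = list(c("glc", "tp"), paste0("s", 1:3)))
#' PairedPanel(t0 = t0, t1 = t0 * 1.02)
#' @export
PairedPanel <- function(t0, t1, registry = NULL) {
  t0 <- as.matrix(t0)
  t1 <- as.matrix(t1)
  if (!identical(dim(t0), dim(t1)) || !identical(dimnames(t0), dimnames(t1))) {
    stop("'t0' and 't1' must be matrices with identical dimnames", call. = FALSE)
  }
  row_data <- NULL
  if (!is.null(registry)) {
    stopifnot(methods::is(registry, "AnalyteRegistry"))
    hit <- match(rownames(t0), registry$analyte_id)
    if (!anyNA(hit)) row_data <- registry[hit, ]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(t0 = t0, t1 = t1),
    rowData = row_data
  )
  methods::new("PairedPanel", se)
}

#' @describeIn PairedPanel basal (t0) measurement matrix.
#' @param x a \code{PairedPanel}.
#' @export
basalValues <- function(x) SummarizedExperiment::assay(x, "t0")

#' @describeIn PairedPanel post-intervention (t1) measurement matrix.
#' @export
postValues <- function(x) SummarizedExperiment::assay(x, "t1")

#' @describeIn PairedPanel subject identifiers (column names).
#' @export
subjectIds <- function(x) colnames(x)

#' @export
setMethod("show", "PairedPanel", function(object) {
  cat(sprintf("PairedPanel: %d analyte(s) x %d subject(s), assays t0/t1\n",
              nrow(object), ncol(object)))
  methods::callNextMethod()
})

#' Read a paired panel from CSV
#'
#' Accepts two dialects and normalises both to a [PairedPanel-class]:
#' \itemize{
#'   \item tidy: columns \code{subject_id,analyte_id,phase,value} with
#'     \code{phase} in \{T0, T1\} (case-insensitive);
#'   \item wide: columns \code{subject_id,analyte_id,t0,t1}.
#' }
#' The crossing must be complete: every subject needs both phases of every
#' analyte, exactly once.
#'
#' @param path CSV file path.
#' @return A [PairedPanel-class]; analyte order follows first appearance.
#' @export
readPanel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  cols <- colnames(df)
  if (all(c("subject_id", "analyte_id", "phase", "value") %in% cols)) {
    phase <- toupper(trimws(df$phase))
    if (!all(phase %in% c("T0", "T1"))) {
      stop("panel 'phase' must be T0 or T1", call. = FALSE)
    }
    wide <- stats::reshape(
      data.frame(subject_id = as.character(df$subject_id),
                 analyte_id = as.character(df$analyte_id),
                 phase = phase, value = as.numeric(df$value)),
      idvar = c("subject_id", "analyte_id"), timevar = "phase",
      direction = "wide"
    )
    names(wide)[names(wide) == "value.T0"] <- "t0"
    names(wide)[names(wide) == "value.T1"] <- "t1"
  } else if (all(c("subject_id", "analyte_id", "t0", "t1") %in% cols)) {
    wide <- data.frame(subject_id = as.character(df$subject_id),
                       analyte_id = as.character(df$analyte_id),
                       t0 = as.numeric(df$t0), t1 = as.numeric(df$t1))
  } else {
    stop("panel file must be tidy (subject_id,analyte_id,phase,value) or ",
         "wide (subject_id,analyte_id,t0,t1)", call. = FALSE)
  }
  if (anyDuplicated(wide[c("subject_id", "analyte_id")])) {
    stop("duplicate (subject, analyte) measurement", call. = FALSE)
  }
  analytes <- unique(wide$analyte_id)
  subjects <- unique(wide$subject_id)
  t0 <- matrix(NA_real_, length(analytes), length(subjects),
               dimnames = list(analytes, subjects))
  t1 <- t0
  t0[cbind(wide$analyte_id, wide$subject_id)] <- wide$t0
  t1[cbind(wide$analyte_id, wide$subject_id)] <- wide$t1
  PairedPanel(t0 = t0, t1 = t1)
}

#' Write a paired panel to CSV
#'
#' @param panel a [PairedPanel-class].
#' @param path destination path.
#' @param style \code{"tidy"} (default; \code{subject_id,analyte_id,phase,value})
#'   or \code{"wide"} (\code{subject_id,analyte_id,t0,t1}). Both reload with
#'   [readPanel()].
#' @return Invisibly, \code{path}.
#' @export
writePanel <- function(panel, path, style = c("tidy", "wide")) {
  style <- match.arg(style)
  stopifnot(methods::is(panel, "PairedPanel"))
  t0 <- basalValues(panel)
  t1 <- postValues(panel)
  grid <- expand.grid(analyte_id = rownames(panel), subject_id = colnames(panel),
                      stringsAsFactors = FALSE)
  wide <- data.frame(subject_id = grid$subject_id, analyte_id = grid$analyte_id,
                     t0 = t0[cbind(grid$analyte_id, grid$subject_id)],
                     t1 = t1[cbind(grid$analyte_id, grid$subject_id)])
  out <- if (style == "wide") {
    wide
  } else {
    data.frame(subject_id = rep(wide$subject_id, 2L),
               analyte_id = rep(wide$analyte_id, 2L),
               phase = rep(c("T0", "T1"), each = nrow(wide)),
               value = c(wide$t0, wide$t1))
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
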