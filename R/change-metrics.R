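#' Reference change value (RCV)
#'
#' The smallest percent difference between two serial measurements of the
#' same subject that exceeds the combined analytical and within-subject
#' biological noise at the chosen confidence:
#' \deqn{RCV = \sqrt{2}\, Z \sqrt{CV_A^2 + CV_I^2}}
#' The \eqn{\sqrt{2}} accounts for two measurements each carrying the full
#' noise. Vectorised over analytes.
#'
#' @param cv_a analytical CV, percent (>= 0).
#' @param cv_i within-subject biological CV, percent (> 0).
#' @param z normal quantile (default 1.96, 95\% bidirectional confidence).
#' @return Unrounded RCV, percent. Use [reportRound()] for the one-decimal
#'   display convention.
#' @examples
#' computeRCV(3.0, 12.1)          # urea: 34.55... -> prints 34.6
#' reportRound(computeRCV(1.3, 42.2))  # hsCRP: 117.0
#' @export
computeRCV <- function(cv_a, cv_i, z = 1.96) {
  if (any(!is.finite(cv_a)) || any(cv_a < 0)) {
    stop("'cv_a' must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(cv_i)) || any(cv_i <= 0)) {
    stop("'cv_i' must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(z)) || any(z <= 0)) {
    stop("'z' must be finite and > 0", call. = FALSE)
  }
  sqrt(2) * z * sqrt(cv_a^2 + cv_i^2)
}

#' Desirable specification for imprecision (DSI)
#'
#' The classical performance goal for analytical imprecision derived from
#' biological variation: half the within-subject biological CV.
#'
#' @inheritParams computeRCV
#' @return Unrounded DSI, percent.
#' @examples
#' reportRound(computeDSI(21.8))  # total bilirubin: 10.9
#' @export
computeDSI <- function(cv_i) {
  if (any(!is.finite(cv_i)) || any(cv_i <= 0)) {
    stop("'cv_i' must be finite and > 0", call. = FALSE)
  }
  0.5 * cv_i
}

#' Round for report display, half away from zero
#'
#' Display convention used throughout the reports: round to \code{digits}
#' decimals with ties going away from zero (so 6.05 renders 6.1, -6.05
#' renders -6.1), unlike base \code{round()}'s round-half-even. Internal
#' computation always keeps full precision; this is applied only when a
#' value is rendered.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
reportRound <- function(x, digits = 1L) {
  p <- 10^digits
  # nudge by a relative epsilon so values that are decimal ties (e.g. 6.05,
  # stored as 6.049999...) round away from zero as intended
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps) * abs(x)) / p
}

#' Per-subject percent difference from baseline
#'
#' Signed percent change from the basal measurement to the
#' post-intervention measurement, \code{100 * (t1 - t0) / t0}. The basal
#' value is the denominator, so the sign tracks the direction of the
#' intervention effect. Vectorised over subjects.
#'
#' @param t0 basal measurement(s), must be positive.
#' @param t1 post-intervention measurement(s), must be non-negative.
#' @return Signed percent difference(s).
#' @examples
#' subjectDifference(100, 102)  # +2
#' subjectDifference(50, 45)    # -10
#' @export
subjectDifference <- function(t0, t1) {
  if (any(!is.finite(t0)) || any(t0 <= 0)) {
    stop("'t0' must be finite and > 0 (it is the percent-change denominator)",
         call. = FALSE)
  }
  if (any(!is.finite(t1)) || any(t1 < 0)) {
    stop("'t1' must be finite and >= 0", call. = FALSE)
  }
  100 * (t1 - t0) / t0
}

#' Mean percent difference across subjects
#'
#' Computes each subject's percent change from baseline first, then averages:
#' the mean of per-subject percent differences, not the percent difference of
#' means. Scale-free: rescaling both measurements by a common positive
#' constant leaves the result unchanged.
#'
#' @inheritParams subjectDifference
#' @return A list with elements \code{perSubjectMD} (signed percent
#'   differences), \code{meanMD} (their arithmetic mean) and \code{n}.
#' @examples
#' meanDifference(c(100, 200, 50), c(110, 180, 55))$meanMD  # 3.333...
#' @export
meanDifference <- function(t0, t1) {
  if (length(t0) == 0L) stop("no measurement pairs given", call. = FALSE)
  if (length(t0) != length(t1)) {
    stop("'t0' and 't1' must have equal length", call. = FALSE)
  }
  md <- subjectDifference(t0, t1)
  list(perSubjectMD = md, meanMD = mean(md), n = length(md))
}
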