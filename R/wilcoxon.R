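#' Exact null distribution of the signed-rank statistic
#'
#' Distribution of \eqn{W^+}, the sum of ranks carrying a positive sign, when
#' each rank independently receives its sign with probability 1/2 (the
#' signed-rank null). Computed by dynamic programming over the rank sums:
#' ranks are doubled to make mid-ranks integral and the count vector is built
#' by successive convolution, so the cost is \eqn{O(n \cdot \sum r)} rather
#' than the literal \eqn{2^n} enumeration.
#'
#' @param ranks positive rank values; mid-ranks (halves) are allowed.
#' @param maxN refuse enumeration beyond this many ranks (default 25).
#' @return A \code{data.frame} with columns \code{w} (achievable values of
#'   \eqn{W^+}) and \code{prob}; probabilities sum to 1 and the distribution
#'   is symmetric about half the total rank sum.
#' @examples
#' exactNullDistribution(c(1, 2, 3))  # probs {1,1,1,2,1,1,1}/8
#' @export
exactNullDistribution <- function(ranks, maxN = 25L) {
  if (length(ranks) == 0L) stop("'ranks' must be non-empty", call. = FALSE)
  if (any(!is.finite(ranks)) || any(ranks <= 0)) {
    stop("'ranks' must be positive", call. = FALSE)
  }
  if (length(ranks) > maxN) {
    stop("refusing exact enumeration for ", length(ranks),
         " ranks (cutoff ", maxN, ")", call. = FALSE)
  }
  r2 <- 2 * ranks
  if (any(abs(r2 - round(r2)) > 1e-8)) {
    stop("'ranks' must be integers or half-integers (mid-ranks)", call. = FALSE)
  }
  r2 <- as.integer(round(r2))
  total <- sum(r2)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  upper <- 0L
  for (r in r2) {
    idx <- seq_len(upper + 1L)
    counts[idx + r] <- counts[idx + r] + counts[idx]
    upper <- upper + r
  }
  keep <- counts > 0
  data.frame(w = (which(keep) - 1L) / 2,
             prob = counts[keep] / 2^length(ranks))
}

# Ranks of the nonzero differences. Under "drop" the zeros are removed before
# ranking; under "pratt" all |d| are ranked jointly and the zeros' ranks are
# then discarded from the statistic.
.signed_ranks <- function(d, zeroPolicy) {
  nz <- d != 0
  if (zeroPolicy == "drop") {
    r <- rank(abs(d[nz]))
    list(ranks = r, signs = sign(d[nz]), zeros = sum(!nz))
  } else {
    r_all <- rank(abs(d))
    list(ranks = r_all[nz], signs = sign(d[nz]), zeros = sum(!nz))
  }
}

#' Wilcoxon signed-rank test for paired measurements
#'
#' The paired nonparametric test used for small clinical panels: differences
#' \code{t1 - t0} are ranked by absolute value (mid-ranks under ties), and
#' \eqn{W^+}, the rank sum of the positive differences, is referred to its
#' null distribution. For effective sample sizes up to
#' \code{exactTestMaxN(config)} the null is enumerated exactly (all
#' equiprobable sign assignments to the observed rank vector, via
#' [exactNullDistribution()]); beyond that, a normal approximation with
#' tie-corrected variance and continuity correction is used. The two-sided
#' p-value is the doubled smaller tail, capped at 1.
#'
#' @param t0,t1 paired measurement vectors (basal and post-intervention).
#'   Alternatively pass the differences directly via \code{differences},
#'   leaving \code{t0}/\code{t1} missing.
#' @param differences optional vector of paired differences \code{t1 - t0}.
#' @param config an [AnalysisConfig-class]; only \code{exactTestMaxN} is used.
#' @param zeroPolicy how zero differences are handled: \code{"drop"}
#'   (classical Wilcoxon, default) removes them before ranking;
#'   \code{"pratt"} ranks them jointly with the rest and then discards their
#'   ranks from the statistic.
#' @return A [TestResult-class].
#' @examples
#' res <- wilcoxonSignedRank(differences = c(1, 2, 3, 4, 5, 6))
#' res@wPlus       # 21
#' res@pTwoSided   # 0.03125 = 2/64
#' @export
wilcoxonSignedRank <- function(t0, t1, differences = NULL,
                               config = analysisConfig(),
                               zeroPolicy = c("drop", "pratt")) {
  zeroPolicy <- match.arg(zeroPolicy)
  if (is.null(differences)) {
    if (length(t0) != length(t1)) {
      stop("'t0' and 't1' must have equal length", call. = FALSE)
    }
    differences <- t1 - t0
  }
  if (length(differences) == 0L) stop("no pairs given", call. = FALSE)
  if (anyNA(differences)) stop("differences must not be missing", call. = FALSE)
  if (all(differences == 0)) {
    stop("all differences zero: the signed-rank test carries no information",
         call. = FALSE)
  }
  sr <- .signed_ranks(differences, zeroPolicy)
  w_plus <- sum(sr$ranks[sr$signs > 0])
  n_eff <- length(sr$ranks)
  if (n_eff <= config@exactTestMaxN) {
    dist <- exactNullDistribution(sr$ranks, maxN = config@exactTestMaxN)
    lower <- sum(dist$prob[dist$w <= w_plus + 1e-9])
    upper <- sum(dist$prob[dist$w >= w_plus - 1e-9])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- sum(sr$ranks) / 2
    sigma <- sqrt(sum(sr$ranks^2) / 4)  # tie-corrected via mid-ranks
    cc <- if (w_plus == mu) 0 else 0.5 * sign(w_plus - mu)
    zstat <- (w_plus - mu - cc) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(zstat)))
    method <- "normal_approximation"
  }
  new("TestResult", wPlus = w_plus, nEffective = n_eff,
      pTwoSided = p, method = method, zerosDropped = sr$zeros)
}

#' @export
setMethod("show", "TestResult", function(object) {
  cat("Wilcoxon signed-rank test (", object@method, ")\n",
      sprintf("  W+ = %g on n = %d pairs (%d zero difference(s) removed)\n",
              object@wPlus, object@nEffective, object@zerosDropped),
      sprintf("  two-sided P = %.5g\n", object@pTwoSided), sep = "")
})
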