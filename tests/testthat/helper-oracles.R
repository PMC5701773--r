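# Independent brute-force oracle for the exact signed-rank p-value: literal
# enumeration of all 2^n sign assignments to the mid-ranks of |d| (zeros
# dropped), recomputing the tail mass from scratch. Deliberately shares no
# code with the package's dynamic-programming path.
bruteForceSignedRankP <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n <- length(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
}

# Random integer-valued difference vector exercising ties and zeros; never
# all-zero.
randomDifferences <- function(n) {
  repeat {
    d <- sample(-4:4, n, replace = TRUE)
    if (any(d != 0)) return(d)
  }
}

# Minimal assessment object with prescribed summary numbers, for report and
# interferogram geometry tests.
makeAssessment <- function(md, dsi, rcv, p = 0.01, id = "x",
                           name = "Analyte X", unit = "U/L") {
  cfg <- analysisConfig()
  methods::new("ChangeAssessment",
    analyteId = id, displayName = name, unit = unit, n = 20L,
    medianT0 = 10, q1T0 = 9, q3T0 = 11,
    medianT1 = 10.5, q1T1 = 9.5, q3T1 = 11.5,
    pTwoSided = p, meanMD = md, dsi = dsi, rcv = rcv,
    statisticallySignificant = p < cfg@alpha,
    exceedsDSI = abs(md) > dsi,
    clinicallySignificant = abs(md) > rcv)
}

# Registry with a single analyte, handy for focused simulations.
singleAnalyteRegistry <- function(id = "glc", cv_a = 1.4, cv_i = 4.5,
                                  cv_g = NA_real_) {
  AnalyteRegistry(id, toupper(id), "mmol/L", cv_a = cv_a, cv_i = cv_i,
                  cv_g = cv_g)
}
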