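test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- simulationConfig(seed = 77L)
  p1 <- simulatePanel(cfg)
  p2 <- simulatePanel(cfg)
  expect_identical(basalValues(p1), basalValues(p2))
  expect_identical(postValues(p1), postValues(p2))

  p3 <- simulatePanel(simulationConfig(seed = 78L))
  expect_false(identical(basalValues(p1), basalValues(p3)))

  # the caller's RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulatePanel(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("simulated panels have the study shape: complete, positive, named", {
  panel <- simulatePanel(simulationConfig(seed = 12L))
  expect_equal(dim(panel), c(16L, 20L))
  expect_true(all(basalValues(panel) > 0))
  expect_true(all(postValues(panel) > 0))
  expect_equal(rownames(panel), analyteIds(waterIntakeRegistry()))
  expect_equal(SummarizedExperiment::rowData(panel)$cv_i,
               unname(cvI(waterIntakeRegistry())))
})

test_that("with no induced effect the mean difference is centred at zero", {
  reg <- singleAnalyteRegistry("glc", cv_a = 1.4, cv_i = 4.5)
  cfg <- simulationConfig(nSubjects = 2000L, registry = reg,
                          setPoints = c(glc = 4.8), seed = 5L)
  panel <- simulatePanel(cfg)
  md <- meanDifference(basalValues(panel)["glc", ],
                       postValues(panel)["glc", ])$meanMD
  expect_lt(abs(md), 0.5)
})

test_that("paired-ratio spread matches the variance-addition prediction", {
  reg <- singleAnalyteRegistry("glc", cv_a = 1.4, cv_i = 4.5)
  cfg <- simulationConfig(nSubjects = 5000L, registry = reg,
                          setPoints = c(glc = 4.8), seed = 6L)
  panel <- simulatePanel(cfg)
  ratio <- postValues(panel)["glc", ] / basalValues(panel)["glc", ] - 1
  expected_cv <- sqrt(2) * sqrt(4.5^2 + 1.4^2) / 100
  expect_equal(sd(ratio), expected_cv, tolerance = 0.05)
})

test_that("lognormal noise keeps the same CV structure", {
  reg <- singleAnalyteRegistry("glc", cv_a = 1.4, cv_i = 4.5)
  cfg <- simulationConfig(nSubjects = 5000L, registry = reg,
                          setPoints = c(glc = 4.8), seed = 16L,
                          distribution = "lognormal")
  panel <- simulatePanel(cfg)
  ratio <- postValues(panel)["glc", ] / basalValues(panel)["glc", ] - 1
  # log-scale ratio CV approximates the same combined noise at small CVs
  expect_equal(sd(ratio), sqrt(2) * sqrt(4.5^2 + 1.4^2) / 100,
               tolerance = 0.08)
})

test_that("induced shifts are recovered with slope about one", {
  reg <- singleAnalyteRegistry("glc", cv_a = 1.4, cv_i = 4.5)
  deltas <- c(0, 5, 10, 20)
  est <- vapply(seq_along(deltas), function(i) {
    cfg <- simulationConfig(nSubjects = 1500L, registry = reg,
                            setPoints = c(glc = 4.8),
                            delta = deltas[i], seed = 30L + i)
    panel <- simulatePanel(cfg)
    meanDifference(basalValues(panel)["glc", ], postValues(panel)["glc", ])$meanMD
  }, numeric(1))
  fit <- stats::lm(est ~ deltas)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
  expect_lt(max(abs(est - deltas)), 0.75)
})

test_that("recovery experiment reports per-analyte flag rates", {
  reg <- singleAnalyteRegistry("glc", cv_a = 1.4, cv_i = 4.5)
  cfg <- simulationConfig(nSubjects = 20L, registry = reg,
                          setPoints = c(glc = 4.8), seed = 42L)
  out <- recoveryExperiment(cfg, nReps = 100L)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_reps, 100L)
  expect_true(all(out[c("reject_rate", "exceeds_dsi_rate", "clinical_rate")] >= 0))
  expect_true(all(out[c("reject_rate", "exceeds_dsi_rate", "clinical_rate")] <= 1))
  expect_lt(abs(out$mean_md), 1.5)  # null: MD centred near 0
  expect_error(recoveryExperiment(cfg, nReps = 10L), "nReps")
})

test_that("simulation config validates inputs", {
  reg <- singleAnalyteRegistry("xyz")  # analyte unknown to the bundled summary
  expect_error(simulationConfig(registry = reg), "set point")
  expect_error(simulationConfig(nSubjects = 1L), "nSubjects")
  expect_error(simulationConfig(delta = c(bogus = 5)), "not in registry")
  expect_error(simulationConfig(setPoints = c(bogus = 5)), "not in registry")
})
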