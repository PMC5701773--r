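test_that("median and quartiles follow the linear-interpolation convention", {
  expect_equal(summarizeMeasurements(c(1, 2, 3, 4, 5)),
               c(median = 3, q1 = 2, q3 = 4))
  expect_equal(summarizeMeasurements(7), c(median = 7, q1 = 7, q3 = 7))
  expect_equal(summarizeMeasurements(c(2, 2, 2, 2)),
               c(median = 2, q1 = 2, q3 = 2))
  expect_error(summarizeMeasurements(numeric()), "empty")
})

test_that("three-tier classification separates statistical, analytical, clinical", {
  # mirrors published cases: total proteins, glucose, triglycerides
  got <- classifyChange(mean_md = c(2.2, 1.5, -6.5),
                        dsi = c(1.4, 2.3, 10.0),
                        rcv = c(8.0, 13.0, 56.0),
                        p = c(0.001, 0.104, 0.002))
  expect_equal(got$statistically_significant, c(TRUE, FALSE, TRUE))
  expect_equal(got$exceeds_dsi, c(TRUE, FALSE, FALSE))  # |-6.5| < 10.0
  expect_equal(got$clinically_significant, c(FALSE, FALSE, FALSE))

  # signed comparison makes any decrease non-significant by construction
  signed <- classifyChange(-6.5, 1.0, 2.0, 0.001,
                           config = analysisConfig(mdComparison = "signed"))
  expect_false(signed$exceeds_dsi)
})

test_that("assessAnalyte composes summaries, test, MD and thresholds", {
  reg <- singleAnalyteRegistry("glc", cv_a = 1.4, cv_i = 4.5)
  t0 <- c(4.4, 4.6, 4.8, 5.0, 5.2, 5.4)
  a <- assessAnalyte(t0, t0 * 1.10, reg, analyteId = "glc")
  expect_s4_class(a, "ChangeAssessment")
  expect_equal(a@meanMD, 10, tolerance = 1e-9)
  expect_equal(a@dsi, 2.25)
  expect_equal(a@rcv, sqrt(2) * 1.96 * sqrt(1.4^2 + 4.5^2), tolerance = 1e-12)
  expect_equal(a@pTwoSided, 2 / 64)  # six concordant increases
  expect_equal(a@medianT0, median(t0))
  expect_true(a@statisticallySignificant)
  expect_true(a@exceedsDSI)
  expect_false(a@clinicallySignificant)

  # identical phases: no information, P reported as 1 with a warning
  expect_warning(z <- assessAnalyte(t0, t0, reg, analyteId = "glc"),
                 "all differences zero")
  expect_equal(z@pTwoSided, 1)
  expect_false(z@statisticallySignificant)

  expect_error(assessAnalyte(t0, t0 * 1.1, reg, analyteId = "nope"),
               "not in registry")
  expect_error(assessAnalyte(5, 5.5, reg, analyteId = "glc"), "at least 2")
})

test_that("assessPanel maps the registry over the panel in registry order", {
  reg <- waterIntakeRegistry()
  panel <- simulatePanel(simulationConfig(seed = 3L))
  res <- assessPanel(panel, reg)
  expect_equal(nrow(res), 16L)
  expect_equal(res$analyte_id, analyteIds(reg))
  expect_equal(res$n, rep(20L, 16L))
  # flags recomputable from the numeric columns
  expect_equal(res$statistically_significant, res$p < 0.05)
  expect_equal(res$exceeds_dsi, abs(res$mean_md) > res$dsi)
  expect_equal(res$clinically_significant, abs(res$mean_md) > res$rcv)
  expect_true(all(res$clinically_significant <= res$exceeds_dsi))

  # deterministic given inputs
  res2 <- assessPanel(simulatePanel(simulationConfig(seed = 3L)), reg)
  expect_identical(as.data.frame(res2), as.data.frame(res))

  orphan <- panel
  rownames(orphan)[1] <- "mystery"
  expect_error(assessPanel(orphan, reg), "mystery")
})

test_that("assessment flags match hand-computed classification on a crafted panel", {
  reg <- AnalyteRegistry(c("a1", "a2", "a3"), unit = "U/L",
                         cv_a = c(1, 2, 1), cv_i = c(4, 10, 4))
  t0 <- matrix(rep(c(100, 50, 80), 8), nrow = 3,
               dimnames = list(c("a1", "a2", "a3"), paste0("s", 1:8)))
  t0 <- t0 * (1 + 0.01 * matrix(seq_len(24), 3))  # distinct positive values
  shift <- c(a1 = 1.04, a2 = 1.005, a3 = 1.30)    # vs DSI 2; 5; 2 and RCV ~11.4; ~28; ~11.4
  t1 <- t0 * shift[rownames(t0)]
  res <- assessPanel(PairedPanel(t0 = t0, t1 = t1), reg)
  expect_equal(res$mean_md, c(4, 0.5, 30), tolerance = 1e-9)
  expect_equal(res$exceeds_dsi, c(TRUE, FALSE, TRUE))
  expect_equal(res$clinically_significant, c(FALSE, FALSE, TRUE))
  expect_true(all(res$statistically_significant))  # 8/8 concordant, p = 2/256
})

test_that("reports round-trip in tidy style and star DSI exceedance in wide style", {
  reg <- waterIntakeRegistry()
  res <- assessPanel(simulatePanel(simulationConfig(seed = 21L)), reg)

  tidy_path <- withr::local_tempfile(fileext = ".csv")
  writeReport(res, tidy_path, style = "tidy")
  back <- readReport(tidy_path)
  num <- c("median_t0", "q1_t0", "q3_t0", "median_t1", "q1_t1", "q3_t1",
           "p", "mean_md", "dsi", "rcv")
  for (col in num) {
    expect_equal(back[[col]], as.data.frame(res)[[col]], tolerance = 1e-9,
                 label = col)
  }

  wide_path <- withr::local_tempfile(fileext = ".txt")
  writeReport(res, wide_path, style = "wide")
  lines <- readLines(wide_path, encoding = "UTF-8")
  expect_equal(length(lines), 17L)  # header + 16 analytes
  tab <- read.delim(text = lines, check.names = FALSE)
  starred <- grepl("\\*$", tab$`Mean difference (%)`)
  expect_equal(starred, res$exceeds_dsi)
  # wide and tidy agree numerically up to display rounding
  expect_equal(as.numeric(tab$`RCV (%)`), reportRound(res$rcv))
  expect_equal(as.numeric(tab$`DSI (%)`), reportRound(res$dsi))
  expect_equal(as.numeric(sub("\\*$", "", tab$`Mean difference (%)`)),
               reportRound(res$mean_md))
  expect_equal(as.numeric(tab$P), as.numeric(formatPValue(res$p)))
})
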