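test_that("exact signed-rank test matches hand-enumerated examples", {
  r <- wilcoxonSignedRank(differences = c(1, 2, 3, 4, 5, 6))
  expect_equal(r@wPlus, 21)
  expect_equal(r@nEffective, 6L)
  expect_equal(r@pTwoSided, 2 / 64)  # P(W+ >= 21) = 1/64, doubled
  expect_equal(r@method, "exact")

  r2 <- wilcoxonSignedRank(differences = c(1, -1))  # tied |d|, mid-ranks
  expect_equal(r2@wPlus, 1.5)
  expect_equal(r2@pTwoSided, 1.0)

  expect_error(wilcoxonSignedRank(c(1, 2, 3), c(1, 2, 3)),
               "all differences zero")
  expect_error(wilcoxonSignedRank(differences = numeric()), "no pairs")
})

test_that("exact null distribution enumerates correctly and normalises", {
  d <- exactNullDistribution(c(1, 2, 3))
  expect_equal(d$w, 0:6)
  expect_equal(d$prob, c(1, 1, 1, 2, 1, 1, 1) / 8)

  d1 <- exactNullDistribution(1)
  expect_equal(d1$w, c(0, 1))
  expect_equal(d1$prob, c(0.5, 0.5))

  set.seed(5)
  for (rep in 1:10) {
    ranks <- rank(abs(randomDifferences(8)))
    dd <- exactNullDistribution(ranks)
    expect_equal(sum(dd$prob), 1, tolerance = 1e-12)
    # symmetric about half the rank sum
    expect_equal(dd$prob, rev(dd$prob), tolerance = 1e-12)
    expect_equal(sum(dd$w * dd$prob), sum(ranks) / 2, tolerance = 1e-9)
  }
  expect_error(exactNullDistribution(1:30), "cutoff")
  expect_error(exactNullDistribution(c(1, -2)), "positive")
})

test_that("exact p agrees with independent 2^n enumeration (random vectors)", {
  set.seed(101)
  for (n in 3:9) {
    for (rep in 1:25) {
      d <- randomDifferences(n)
      got <- wilcoxonSignedRank(differences = d)@pTwoSided
      expect_equal(got, bruteForceSignedRankP(d),
                   tolerance = 1e-12,
                   label = paste0("n=", n, " d=", paste(d, collapse = ",")))
    }
  }
})

test_that("exact p matches stats::wilcox.test when untied and zero-free", {
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(5:15, 1)
    d <- round(rnorm(n), 6)  # continuous: no ties, no zeros
    ours <- wilcoxonSignedRank(differences = d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours@pTwoSided, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(ours@wPlus, unname(ref$statistic))
  }
})

test_that("swapping the two phases preserves p and reflects the statistic", {
  set.seed(303)
  for (rep in 1:20) {
    t0 <- runif(12, 10, 20)
    t1 <- t0 + rnorm(12)
    a <- wilcoxonSignedRank(t0, t1)
    b <- wilcoxonSignedRank(t1, t0)
    ranksum <- a@nEffective * (a@nEffective + 1) / 2
    expect_equal(b@wPlus, ranksum - a@wPlus)
    expect_equal(b@pTwoSided, a@pTwoSided, tolerance = 1e-12)
  }
})

test_that("zero handling: drop removes pairs, pratt keeps their ranks", {
  d <- c(0, 0, 1, 2, -3)
  drop <- wilcoxonSignedRank(differences = d)
  expect_equal(drop@nEffective, 3L)
  expect_equal(drop@zerosDropped, 2L)
  expect_equal(drop@wPlus, 1 + 2)  # ranks of |1|,|2| among {1,2,3}

  pratt <- wilcoxonSignedRank(differences = d, zeroPolicy = "pratt")
  expect_equal(pratt@nEffective, 3L)
  # zeros rank 1.5, 1.5; nonzero ranks 3, 4, 5
  expect_equal(pratt@wPlus, 3 + 4)
})

test_that("normal approximation with continuity correction kicks in beyond the cutoff", {
  set.seed(404)
  d <- rnorm(40, mean = 0.3)
  cfg <- analysisConfig(exactTestMaxN = 25L)
  res <- wilcoxonSignedRank(differences = d, config = cfg)
  expect_equal(res@method, "normal_approximation")
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(res@pTwoSided, unname(ref$p.value), tolerance = 1e-10)

  # same data forced exact: approximation should be close to the exact p
  cfg2 <- analysisConfig(exactTestMaxN = 40L)
  exact <- wilcoxonSignedRank(differences = d, config = cfg2)
  expect_equal(exact@method, "exact")
  expect_lt(abs(exact@pTwoSided - res@pTwoSided), 0.01)
})

test_that("exact test keeps type-I error at or below nominal (small null sweep)", {
  set.seed(505)
  n_reps <- 600
  rejected <- 0L
  for (i in seq_len(n_reps)) {
    d <- rnorm(20)
    if (wilcoxonSignedRank(differences = d)@pTwoSided < 0.05) {
      rejected <- rejected + 1L
    }
  }
  mc_se <- sqrt(0.05 * 0.95 / n_reps)
  expect_lte(rejected / n_reps, 0.05 + 3 * mc_se)
})
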