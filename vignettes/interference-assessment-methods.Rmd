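---
title: "Assessing preanalytical interference with reference change values: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing preanalytical interference with reference change values: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RCVassess)
```

## The question the package answers

A paired preanalytical study measures each subject once in a controlled
basal state (T0) and once after the intervention under scrutiny (T1), for a
panel of clinical chemistry analytes. Three different questions hide behind
"did the intervention change the analyte?":

1. **Statistical**: is the paired shift distinguishable from zero?
   Answered by the exact Wilcoxon signed-rank test at level `alpha`.
2. **Analytical**: is the mean percent difference (MD) larger than the
   imprecision a well-performing assay is permitted — the desirable
   specification for imprecision, DSI = 0.5 · CV~I~?
3. **Clinical**: is the MD larger than the noise *any* two serial results
   of this analyte carry, combining analytical and within-subject
   biological variation — the reference change value,
   RCV = √2 · Z · √(CV~A~² + CV~I~²)?

Since 0.5 · CV~I~ < √2 · Z · CV~I~ ≤ RCV for any Z ≥ 1, DSI < RCV always,
so the three tiers are ordered: a clinically significant change necessarily
exceeds the analytical goal too. `ChangeAssessment` objects assert this at
construction.

The package's classification rule compares |MD| against the thresholds.
This is a genuine design choice: results tables in this field carry signed
MDs, and a signed comparison would declare any *decrease* non-significant
by construction, which cannot be the intended meaning of "change". The
signed alternative remains available through
`analysisConfig(mdComparison = "signed")` for sensitivity analyses.

Likewise the percent difference uses the basal value as denominator,
100·(T1 − T0)/T0, not the pair mean: the basal draw is the reference state
of the design, and the sign then tracks the direction of the intervention
effect. The panel MD is the mean of per-subject percent differences (each
volunteer's change is computed first, then averaged), not the percent
difference of group means; the two differ whenever baseline values vary.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `z` | 1.96 | — | normal quantile of the RCV; 95 % bidirectional confidence |
| `alpha` | 0.05 | — | level of the signed-rank test |
| `exactTestMaxN` | 25 | pairs | largest effective n for exact enumeration |
| `mdComparison` | `"absolute"` | — | magnitude vs signed threshold comparison |
| `cv_a`, `cv_i`, `cv_g` | registry | % | analytical / within-subject / between-subject CVs |

CVs are percentages and everything downstream (MD, DSI, RCV) is a
percentage as well, so analyte units (mmol/L, µmol/L, g/L, U/L …) are
opaque labels that are never converted.

## The exact signed-rank test

Differences d = T1 − T0 are ranked by |d| with mid-ranks under ties; W⁺ is
the rank sum of the positive differences. For effective sample sizes up to
`exactTestMaxN` the null distribution is exact: every one of the 2ⁿ sign
assignments to the observed rank vector is equiprobable. The package never
loops over the 2ⁿ assignments; `exactNullDistribution()` doubles the
(possibly half-integer) mid-ranks to integers and builds the count vector
by successive convolution, O(n · Σr) time, which at the cutoff of n = 25
is a vector of at most 651 counts. The two-sided p-value is
min(1, 2 · min(lower tail, upper tail)), the standard doubling convention.

Zero differences are dropped before ranking (the classical treatment);
a Pratt-style option (`zeroPolicy = "pratt"`) ranks them jointly and then
discards their ranks from the statistic. A panel where every pair is
identical carries no signed-rank information at all: `assessAnalyte()`
reports it as "no change detected" with P = 1.00 and a warning rather than
failing, so panel-level runs stay total. Beyond the cutoff a normal
approximation is used with continuity correction and the mid-rank variance
Σr²/4, which equals the textbook tie-corrected variance.

The choice `exactTestMaxN = 25` keeps the study-sized design (20 pairs)
squarely in exact territory while bounding the enumeration cost.

## Display conventions

Internal computation keeps full precision; only rendering rounds. Reports
round **half away from zero to one decimal** (so a DSI of 6.05 renders 6.1
and −6.05 renders −6.1), the convention of published results tables in this
field, not base R's round-half-even. P-values render at three decimals with
a display floor of 0.001. Quartiles use the linear-interpolation convention
(`stats::quantile` type 7, the default of mainstream statistics software);
published interquartile ranges are therefore only comparable up to the
software convention of the original analysis, and the package makes no
exact-match claim about them.

Two published cells of the bundled study summary deserve a note. First,
four printed RCVs differ by 0.1–0.2 points from the value recomputed from
the printed one-decimal CVs, consistent with the original computation using
unrounded CV inputs; the bundled tests assert exact agreement only for the
twelve reproducible cells and ±0.2 for all. Second, the printed cystatin C
DSI (2.5) is not half its printed CV~I~ (0.5 · 5.5 = 2.75); the package
treats this as an anomaly of the printed table and excludes that single
cell from exact-match assertions.

## What the simulator emulates — and what it does not

`simulatePanel()` generates, for subject *j* and analyte *k*:

* a homeostatic set point S~jk~ = M~k~ · g~jk~, where M~k~ is the
  population central value (default: the bundled study's basal medians) and
  g~jk~ is a mean-one factor with between-subject CV;
* per phase, an observed value S~jk~ · w · a with independent mean-one
  within-subject (CV~I~) and analytical (CV~A~) noise factors, drawn
  independently at T0 and T1;
* at T1, an additional factor (1 + δ~k~/100) injecting the intervention
  effect.

Noise factors are normal on the (1 + x) scale, redrawn while ≤ 0.01 so
measurements stay positive; at the CVs of this panel (≤ 42 %) the
truncation is essentially never active and means remain interpretable as
percent effects (δ is directly the expected MD). A log-normal option with
matched CV and unit mean is available; at these CVs the difference is
second order. The registry carries no between-subject CVs (the study
reported none), so the simulator substitutes 15 % — a mid-range value for
routine chemistry analytes. The choice is deliberately inconsequential for
the analysis itself: between-subject spread cancels in per-subject
differences and only shapes the cross-sectional spread of the panel.

The generator's defaults are the study conditions: 20 subjects, the
16-analyte registry, δ = 0. Reproducibility is by a single master seed;
`recoveryExperiment()` spawns replicate seeds by counter from it, so
replicates are independent and the whole experiment is reproducible.

What passing simulation-based tests shows is *self-consistency*: the
pipeline recovers injected effects, keeps its type-I error at or below
nominal, and almost never flags clinical significance under a true null.
What they cannot show is fidelity to the unpublished raw data of any real
study: real analytes have skewed, sometimes correlated distributions,
diurnal structure, and occasional preanalytical artifacts (haemolysis,
lipemia) that the generator deliberately does not model. Published
medians, IQRs and p-values are therefore *inputs* here (via
`waterIntakeSummary()`), not reproduction targets.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route:

* exact signed-rank p-values against literal 2ⁿ enumeration (200 random
  integer difference vectors — with ties and zeros — for every n ≤ 12) and
  against `stats::wilcox.test(exact = TRUE)` on tie-free data;
* type-I error by a 5,000-replicate null simulation at the study size
  (n = 20), bounded by 0.05 plus three Monte-Carlo standard errors (the
  exact test is conservative, so the rate sits below nominal);
* simulator moments by Monte-Carlo at n = 2,000–5,000 subjects (MD centred
  at zero within ±0.5 points; paired-ratio CV within 5 % of the
  √2·√(CV~I~² + CV~A~²) variance-addition prediction) and effect recovery
  over δ ∈ {0, 5, 10, 20} with regression slope 1 ± 0.05;
* the classification structure by injecting δ = 2·RCV into one analyte
  (flag rate above 0.9 across 100 replicates) and by a 150-replicate null
  panel (below 1 % of analyte-replicate cells flagged).

These sizes were chosen so each Monte-Carlo bound has comfortable margin
relative to its standard error while the whole suite stays quick to run.

## Known limitations

* RCV here is the symmetric, normal-theory form; log-normal/asymmetric RCV
  variants, desirable bias and total-error specifications, and the index of
  individuality are out of scope.
* CV~I~ values are user-supplied (e.g. from a biological-variation
  database); the package does not query any online source.
* The test addresses a single intervention condition; multi-visit
  longitudinal designs and dose–response are not modelled.
* IQRs and p-values of an external study are not exactly reproducible
  without its raw data; the package's claims about them are limited to the
  classification they imply.
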