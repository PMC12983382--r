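---
title: "A quantitative modified Brandwein-Gensler risk score: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quantitative modified Brandwein-Gensler risk score: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgrisk)
```

## The problem and the model

Outcome in oral squamous cell carcinoma (OSCC) is only partly explained by
TNM stage: same-stage tumors behave differently, and histological features
of the tumor--host interface carry independent prognostic information. The
classical Brandwein-Gensler risk model combines worst pattern of invasion
(WPOI), perineural invasion (PNI) and a qualitative three-tier grading of
the lymphocytic host response. Its main practical weaknesses are the
subcategorized scoring and the subjectivity of the immune-infiltrate tier.

This package implements a simplified, quantitative variant built from three
binary indicators:

* **WPOI-5** -- satellite tumor nodules at least 1 mm from the main front
  (present = 1, absent = 0);
* **PNI** -- tumor surrounding at least a third of a nerve, or inside the
  nerve sheath or perineural space (present = 1, absent = 0);
* **%stromal TILs** -- the percentage of the tumor's stromal area occupied
  by mononuclear inflammatory cells, dichotomized at the cohort median
  (low = 1, high = 0).

The modified score is the plain sum, 0--3; scores 0--1 form the low-risk
and 2--3 the high-risk category. Coding low TIL density as adverse follows
the original model's treatment of a weak host response as a risk feature;
because the direction is a convention rather than a measurement, it is an
explicit switch (`til_low_is_adverse`) so its consequences can be examined
-- flipping it changes each patient's score by exactly the TIL-point
complement and touches nothing upstream.

## TIL quantification

The measurand is defined per microscopic field as

$$\%\text{stromal TILs} \;=\; 100 \times
\frac{\mathrm{area}(\text{TIL} \cap \text{stroma} \setminus \text{excluded})}
     {\mathrm{area}(\text{stroma} \setminus \text{excluded})},$$

with granulocyte-rich, ulcerated, crushed and necrotic areas excluded from
both numerator and denominator, and the case value the arithmetic mean over
five representative fields. Implementation is exact pixel counting on
binary annotation masks (PNG or TIFF, nonzero = inside region). Three
numerical conventions matter:

* TIL pixels drawn outside the stromal annotation are ignored (masks are
  intersected) rather than rejected: manual annotations overlap
  imperfectly, and the definition is a fraction *of stroma*.
* Cases are split at the cohort median with ties going to **low**
  (`value <= cutoff`). With an even number of distinct values this gives
  the balanced split (29/29 in a 58-patient cohort) that a
  strictly-greater-than-median rule also implies.
* Percentages are carried at full floating precision; rounding to two
  decimals happens only in report tables.

The five-field requirement is a protocol default, overridable via
`min_fields` because field selection itself is manual and out of scope.
Pixel size and magnification cancel out of the ratio, so masks are treated
as dimensionless.

## Association statistics

Two chi-square statistics are computed for every cross-tabulation because
printed clinical tables routinely conflate them:

* **Pearson chi-square**, $\sum (O-E)^2/E$ on $(R-1)(C-1)$ df, no
  continuity correction anywhere (recomputation of the reference cohort's
  2x2 gender-by-risk cell, p = 0.092, matches only the uncorrected
  statistic). Expected counts below 5 trigger a warning, not an exact
  test.
* **Linear-by-linear association** for ordinal pairs,
  $M^2 = (N-1)\,r^2$ on 1 df, where $r$ is the correlation of integer
  rank scores over the $N$ cross-classified observations. Several of the
  reference cohort's printed ordinal p-values (pathological node by score,
  clinical node and clinical stage by risk) are reproduced only by this
  trend statistic, while others (grading by score) are reproduced only by
  Pearson's. The package therefore reports both, each labelled, instead
  of a single unlabelled column.

One-way ANOVA is available from raw data (through `lm`) and, crucially,
**from printed group summaries**: with groups $(n_i, m_i, s_i)$,
$\mathrm{SSB} = \sum n_i (m_i - \bar m)^2$ against
$\mathrm{SSW} = \sum (n_i - 1) s_i^2$. Printed SDs are treated as sample
SDs ($n-1$ denominator); this choice is validated by the exact
reconstruction of the reference TIL total row ($58$, $22.71 \pm 12.75$)
from its five age-group cells. Groups of size one contribute zero
within-group variance. The summary route is numerically identical (to
1e-10 in the test suite) to the raw route on any data whose summaries
match, which is what makes a printed table a sufficient input.

ROC analysis uses the rank (Mann--Whitney) AUC with mid-ranked ties and
the Hanley--McNeil standard error; the AUC is reported in the fixed
orientation "larger predictor predicts the positive class", with a flag
when the observed discrimination runs the other way. Missing depth of
invasion (3 of 58 reference cases) is handled by pairwise deletion, which
reproduces the 55-case DOI columns.

## Survival analysis

Kaplan--Meier estimation and the log-rank test are delegated to the
survival package; censored subjects tied with an event time remain at risk
at that time. "Mean survival" is implemented as the restricted mean --
the exact step-function area under the product-limit curve -- with the
group-specific default horizon at the largest observed time, the
convention behind the group means printed by standard statistical
software. Pairwise log-rank p-values are reported unadjusted.

A calibration caveat found while validating: with four unbalanced score
groups at a 58-patient cohort size (smallest group only a few subjects),
the log-rank chi-square approximation is anticonservative -- about 9%
rejection at nominal 5% under the null, an effect reproducible with plain
independent exponential draws fed straight to `survival::survdiff`. The
two-group comparison at the same cohort size is close to nominal (about
5--6%, the residual excess coming from the unbalanced risk split under
heavy censoring). Null-calibration checks in this package therefore use
the two-group configuration; small multi-group log-rank p-values near the
0.05 boundary should be read with this in mind.

## The synthetic cohort generator

No raw per-patient data accompany the reference cohort, so the generator
is the package's substrate for end-to-end testing. Its defaults *are* the
study conditions: 58 patients; covariate marginals matching the reference
cohort (48/10 male/female, half lateral-tongue primaries, nodal and stage
distributions as printed); WPOI-5 with probability 22/58 and PNI 15/58;
%stromal TILs from a log-normal moment-matched to mean 22.8 and SD 12.7
and truncated at 100 (the reported mean exceeding the median implies right
skew; the exact family is unstated, and a log-normal is the standard
minimal choice); event times exponential with hazard
$\lambda_0 \cdot \mathrm{HR}^{\text{score}}$, with $\lambda_0 = 1/37$
per month and $\mathrm{HR} = 1.3$ per score point -- the value implied by
a roughly geometric decline of group mean survival from 37 to 17 months
over scores 0 to 3 ($ (37/17)^{1/3} \approx 1.30$). Censoring is
administrative and uniform over a 36-month study window, under which the
censored fraction comes out near the reference cohort's 36 of 58; the
source reports no follow-up duration, so the survivor split is matched
only approximately.

What the generator deliberately does **not** emulate: correlations among
covariates (marginals are independent, except an explicit
`node_score_assoc` knob that rank-couples pathological node status to the
score for trend-test power checks); the empirical score distribution
19/20/11/8, which in the real cohort reflects correlated components; and
any cohort-level frailty. Passing tests on synthetic cohorts therefore
demonstrate correctness of the machinery under a known model, not
clinical validity on real data.

Synthetic annotation fields are disc composites: stroma as a main disc
plus satellites, TIL blobs clipped to the evaluable stroma, radii set by
binary search on exact pixel counts so the achieved TIL fraction matches
the request to within about one percentage point (disc-boundary
discretization is the only error source), with the exact achieved
fraction returned as ground truth. This makes the quantifier testable
against construction rather than against itself.

## Problem sizes and numerical choices

The reference-cohort statistics are desk-scale (58 patients, milliseconds
each). Simulation-based checks in the test suite use 500 replicate
58-patient cohorts for null calibration, 400-patient cohorts for
survival-gradient recovery, and up to 20,000 draws for distributional
moments -- sizes at which Monte-Carlo error is a few tenths of a percent
while the whole suite stays interactive. Degenerate inputs are handled
explicitly rather than left to floating point: identical groups give
F = 0, p = 1; perfectly separated groups give p = 0 with a warning; empty
contingency margins are dropped with df adjusted; an all-tied TIL cohort
labels every case low with a warning; zero-area evaluable stroma is an
error, not a NaN.

## Worked example

```{r example}
# reference-cohort statistics from the packaged summary tables
res <- analyze_reference_tables()
subset(res, variable == "grading" & block == "score")

# a synthetic cohort under the study conditions, scored and analyzed
report <- run_pipeline(pipeline_config(
  "synthetic",
  params = synthetic_params(seed = 1)
))
report
```

## Known limitations

* The score's clinical meaning rests on given WPOI-5 and PNI annotations;
  the package does not determine them from histology.
* The median TIL cutoff is cohort-relative; cutoffs from one cohort do
  not transfer to another, and the package intentionally provides no
  "established" absolute threshold.
* Multi-group log-rank p-values are anticonservative at small, unbalanced
  group sizes (above).
* No multiplicity correction is applied anywhere, matching the analysis
  style the package reproduces; interpret families of p-values
  accordingly.
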