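---
title: "Estimating meaningful change thresholds for the QLDS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating meaningful change thresholds for the QLDS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qldsmct)
library(dplyr)
```

## The problem

Patient-reported outcome (PRO) scores are only useful for decision making if
a change on the scale can be read as *meaningful to the patient*. The
smallest such within-patient change is the meaningful change threshold (MCT,
also called the minimal clinically important difference). `qldsmct`
implements the standard regulatory-grade procedure for deriving an MCT for
the **Quality of Life in Depression Scale (QLDS)** — a 34-item true/not-true
questionnaire scored 0 (good quality of life) to 34 (very poor) — from
two-visit (baseline / treatment endpoint) trial data in a population of
depressed adults with acute suicidal ideation.

Two complementary routes are combined:

* **Anchor-based.** An external criterion ("anchor") with an accepted
  interpretation of change defines groups of patients who changed by a
  clinically recognisable amount. The mean QLDS change among patients who
  improved *one* anchor category is an MCT candidate. Anchors here are the
  MADRS (clinician-rated depression severity, 0–60) banded into four
  severity levels, the CGI-SS-r and CGI-SR-I clinician global impressions
  (7-point, where a 1-point change is clinically observable), and the
  EQ-VAS self-rated health scale (0–100), which enters continuously through
  a regression projection at its own published individual-level threshold
  of 7 points.
* **Distribution-based.** One half of the standard deviation of the QLDS
  change score, a conventional supportive benchmark tied to the scale's own
  variability rather than to patient meaning.

Candidates from all routes are pooled ("triangulated"): the recommended MCT
is the pooled median's magnitude rounded half-away-from-zero to an integer.

## Anchors, qualification and sign conventions

An anchor must demonstrate a monotone association with the target change
before it may define responder groups. We use the Spearman rank correlation
between the QLDS raw change and the anchor's raw change (both endpoint
minus baseline, pairwise-complete per anchor) and qualify an anchor when
**|ρ| ≥ 0.40**. The magnitude rule matters: EQ-VAS is scored so that
improvement is an *increase*, so a strongly negative correlation with QLDS
change is exactly the expected behaviour of a good anchor. The p-value uses
the t approximation `t = ρ√((n−2)/(1−ρ²))` on `n − 2` df, which is standard
at trial sample sizes; an exact full-enumeration permutation p is available
for n ≤ 8 (enumeration beyond 8! permutations buys nothing at the sample
sizes where the approximation is in doubt).

Sign conventions are fixed throughout and worth stating once: raw changes
are endpoint − baseline (QLDS/MADRS improvement negative, EQ-VAS positive);
grouping keys are improvement-signed — MADRS category change is baseline
severity index minus endpoint index and CGI point change is baseline minus
endpoint, so "+1" always reads "improved one category/point".

For the qualification correlation of the MADRS anchor we correlate the
*total-score* change (not the category change) for all three banding
schemes, which is why the three MADRS rows of `qualify_anchors()` share one
ρ: the banding affects grouping, not the anchor's association evidence.

## MADRS severity criteria

There is no consensus banding of the MADRS, so three published schemes are
built in and every analysis runs under all of them:

```{r}
all_severity_criteria()
```

Bands are stored as closed integer intervals; a published "> 28–60" becomes
[29, 60] since the MADRS total is integer-valued, removing open-interval
ambiguity. The ordinal severity index 0–3 is fixed; only label text is
configurable. A validity check enforces that each scheme partitions the
integers 0–60 exactly.

## Group summaries and candidate thresholds

Within each anchor-change group we report n, mean and SD (n − 1
denominator), median (midpoint of the central pair for even n), the t-based
95% CI `mean ± t(0.975, n−1)·SD/√n`, the standardized response mean
(mean / SD of change; undefined and reported as `NA` when the SD is 0) and
the standardized effect size (mean / SD of the *baseline* scores of the
full analysis set — the full-set denominator is a deliberate choice, kept
configurable via the `baseline_sd` argument, since group-specific baseline
SDs are unstable in small groups). Groups with n < 25 are flagged: anchor
groups of ~20–26 patients have been observed to destabilise group means in
exactly this setting.

Improvement groups are **exact** ("improved exactly one category"), not
cumulative ("at least one"): per-group means reported alongside two- and
three-category groups only make sense for exact groups. Cumulative grouping
remains available behind `cumulative = TRUE` for sensitivity analyses.

The default candidate set pooled by `triangulate()` is: the one-category
(or one-point) improvement mean of every *qualified* categorical or ordinal
anchor, with each MADRS banding scheme contributing separately; the
regression projection `β₀ + β₁·7` for every qualified continuous anchor
(always computed from full-precision fitted coefficients); and the half-SD
value. Each element can be excluded with the `include` filter. We keep the
set explicit and configurable because pooling rules differ between
published analyses and are rarely reconstructible from reported summaries;
with this default, pooling the published candidate values of the two trials
this procedure was developed on reproduces their reported pooled median
(−8.09 → recommended 8-point improvement), which `scripts/acceptance.R`
recomputes.

Missing scores are permitted at the record level and handled by pairwise
(per anchor–target pair) complete-case deletion, never imputation; this
mirrors the differing per-anchor n's typical of trial reports. Partial QLDS
item sets are refused rather than prorated when totals are formed from the
34 item columns. All analyses use the double-blind endpoint visit only —
no follow-up pooling — and treatment arms are pooled, as MCT derivation
conventionally ignores arm.

## The synthetic cohort generator

Real patient-level data of this kind are access-restricted, so the package
ships a generator whose defaults emulate the published marginal structure
of a 4-week two-visit trial in this population (cohort of 224; QLDS
baseline 27.24 (6.40) with change −12.46 (11.26); MADRS 41.1 (6.07) with
change −23.2 (13.03); EQ-VAS 42.0 (24.44) with change +20.7 (25.15); CGI
baselines matching the published frequency tables). CGI *change* marginals
are not published; the defaults use mean −2.0 (SD 1.6), a plausible
moderate improvement consistent with the published baseline distributions
and correlation magnitudes, chosen once and documented here.

Mechanically: independent latent Gaussian baselines per instrument receive
a latent multivariate-normal change vector with the configured correlation
matrix (QLDS–anchor entries set to the published change-correlation
magnitudes 0.66 / 0.43 / 0.44 / −0.53; unpublished anchor–anchor entries
set to moderate values keeping the matrix positive definite). Both visits
are then rounded to integers and clipped to the instrument ranges, with the
CGI scales discretised through configurable cut points (default:
midpoints). The configuration is validated — in particular the correlation
matrix must be symmetric, unit-diagonal and positive semi-definite — before
any sampling.

What this emulates and what it does not: marginal locations and spreads,
ordinal structure, floor/ceiling effects and the rank-correlation pattern
are reproduced; real features such as treatment-arm effects, skewed or
bimodal change distributions, informative dropout and item-level response
patterns are not. Two consequences deserve emphasis:

* **Attenuation.** Correlations are specified on the *latent* changes.
  Rounding, and more importantly clipping at the scale floors (a large
  share of latent QLDS and MADRS endpoints fall below 0 under the
  published marginals), attenuate the observed rank correlations below the
  latent targets; the generator tests therefore check the observed
  Spearman against the configured target with a ±0.05 band at n = 5000,
  and verify tight agreement separately under mid-scale configurations
  where clipping is negligible.
* **Shrunken change SDs.** For the same reason the observed SD of QLDS
  change is below the latent 11.26, so half-SD candidates computed *from
  synthetic cohorts* are smaller in magnitude than the published half-SD
  value. Published-input computations are unaffected.

Passing tests on these cohorts demonstrate the estimators' correctness and
calibration under a known truth, not fidelity of any particular synthetic
cohort to real patients.

`inject_missingness()` blanks all endpoint scores of a random patient
subset (baseline rows untouched), emulating endpoint dropout as
missing-completely-at-random; informative missingness is out of scope.
Every stochastic operation takes an explicit seed, the packaged demo cohort
(`demo_cohort()`) uses the fixed documented seed 1234, and identical seeds
give bit-identical tables.

### The parameter-recovery rig

`generate_anchored_cohort()` exists to validate the anchor-group estimators
against a known truth: each patient receives a true MADRS category
improvement k ∈ {0, 1, 2, 3} (baseline always in the severe band, as in an
acutely ill population), MADRS visits drawn uniformly inside the
corresponding bands so the realised category change equals the assignment
exactly, and a QLDS change drawn from N(true group mean, SD 9) around a
baseline drawn from the trial marginal (27.24, 6.40). Rounding and clipping
to [0, 34] perturb the realised group mean slightly: with a true
one-category mean of −8, latent endpoints fall below the floor with
probability ≈ 0.04 (biasing the observed mean upward) and baselines above
the ceiling are pulled down (biasing it downward); the net bias is a few
tenths of a point. The recovery test therefore asserts ≥ 90% empirical
coverage of the nominal 95% CI over 50 replicates of n = 450 rather than
nominal coverage — the honest statement of what the integer-valued,
range-limited estimator achieves.

## The stratified CDF report

For every categorical anchor the pipeline produces empirical CDF curves of
QLDS change per anchor-change category (right-continuous step functions as
plain tables, so any plotting stack can reproduce them; `plot_cdf_curves()`
is optional sugar). Visual "separation" of the curves is conventionally
offered as support for the anchor categories; we quantify it by the
two-sample Kolmogorov–Smirnov distance between adjacent categories — the
maximum vertical gap between the step curves, 0 for identical groups, 1
for disjoint supports. The KS summary is this package's explicit
operationalisation of a claim usually made only visually, and should be
read as a descriptive diagnostic, not a test.

## Numerical choices, degenerate inputs, problem sizes

* Sample SDs use the n − 1 denominator throughout; CIs use Student t.
* n = 1 groups report `NA` CI and SRM; SD-0 groups report `NA` SRM and a
  zero-width CI. Empty groups, empty candidate sets, < 3 correlation
  pairs, zero-variance designs and non-PSD correlation matrices are hard
  errors with named causes; pipeline stage failures are re-raised with the
  stage name.
* The recommended integer rounds the pooled median half-away-from-zero on
  its magnitude (−8.09 → 8; −8.5 → 9), reported with the improvement sign.
* Ties in ranks use average ranks; the KS distance is evaluated over the
  pooled support, which is exact for step functions.
* Test and validation problem sizes were chosen as the smallest that make
  the Monte-Carlo bands sharp enough to be meaningful: n = 5000 cohorts
  for correlation/missingness calibration (±0.05 and ±0.02 bands), 50
  replicates of n = 450 for recovery coverage, 1000 random small instances
  per brute-force oracle comparison.

## Limitations

Only the half-SD distribution method is implemented (no SEM, reliable
change index, or ROC/Youden methods); anchors enter at the double-blind
endpoint only; the generator makes no attempt at arm-specific effects; and
an MCT derived this way is population-bound — thresholds derived from an
acutely suicidal MDD population should not be assumed to transfer to
general MDD without re-derivation.

## A complete run

```{r, warning = FALSE}
report <- run_pipeline(demo_cohort(), seed = 1234)
report
glance(report$triangulation)
report$qualification
```
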