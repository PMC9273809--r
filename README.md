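# qldsmct

Anchor-based and distribution-based estimation of the within-patient
**meaningful change threshold (MCT)** for the Quality of Life in Depression
Scale (QLDS), for biostatisticians and outcomes researchers working with
two-visit (baseline / endpoint) clinical-trial data in depression.

A PRO score is interpretable only once we know how much change matters to a
patient. `qldsmct` derives that threshold for the QLDS (34 true/not-true
items, total 0 = good quality of life to 34 = very poor) the way regulatory
guidance prefers: externally anchored responder groups first, the scale's
own variability as support.

## The method

For patients observed at baseline and the treatment endpoint, with QLDS
change ΔQ = Q_end − Q_base (improvement negative):

1. **Anchor qualification.** For each candidate anchor A (MADRS total
   banded into severity levels under three published cut-off schemes,
   CGI-SS-r, CGI-SR-I, EQ-VAS), compute Spearman's ρ between ΔQ and ΔA.
   An anchor qualifies when **|ρ| ≥ 0.40**.
2. **Anchor-based candidates.** Group patients by exact improvement in the
   anchor (one category / one point, improvement-signed). The group mean
   ΔQ among one-category improvers is an MCT candidate; each group is
   reported with mean, SD, median, 95% t-interval, standardized response
   mean (mean/SD of change) and standardized effect size (mean/baseline
   SD), with small groups (n < 25) flagged.
3. **Regression projection.** For the continuous EQ-VAS anchor, fit
   ΔQ = β₀ + β₁·ΔVAS by OLS and project the anchor's own published
   individual threshold: candidate = β₀ + β₁·7.
4. **Distribution-based candidate.** Half the SD of ΔQ.
5. **Triangulation.** Pool all candidates; report mean, median and range;
   recommend the integer MCT = |median| rounded half-away-from-zero,
   with the improvement sign.

Stratified empirical CDF curves of ΔQ per anchor-change category, with
adjacent-category Kolmogorov–Smirnov distances, quantify how well the
anchor categories separate the change distribution.

Because the original patient-level trial data are access-restricted, the
package also ships a synthetic two-visit cohort generator
(`generate_cohort()`, `generate_anchored_cohort()`) reproducing the
published marginal means/SDs and change-correlation structure on latent
Gaussians, rounded and clipped to each instrument's integer range — so the
whole pipeline is exercisable and testable offline.

## Worked example

```r
library(qldsmct)

report <- run_pipeline(demo_cohort(), seed = 1234)
report
#> Meaningful change threshold report
#>   224 patients analysed (448 input rows)
#>   anchors qualified: 4 of 6
#> Triangulation of 5 candidate threshold(s)
#>   mean -7.604, median -8.085, range [-9.024, -4.954]
#>   recommended integer MCT: 8-point improvement (decrease)

report$candidates
#> # A tibble: 5 × 5
#>   source                anchor                   criteria   value     n
#>   <chr>                 <chr>                    <chr>      <dbl> <int>
#> 1 anchor_mean           madrs_total (criteria_1) criteria_1 -7.58    36
#> 2 anchor_mean           madrs_total (criteria_2) criteria_2 -8.08    71
#> 3 anchor_mean           madrs_total (criteria_3) criteria_3 -8.38    72
#> 4 regression_projection eq_vas                   <NA>       -9.02   224
#> 5 half_sd               distribution             <NA>       -4.95   224
```

Reading this: on the demonstration cohort, four of six anchors pass the
|ρ| ≥ 0.40 bar (the two CGI global impressions fall just short after
discretisation). Patients who improved exactly one MADRS severity category
improved by about 7.6–8.4 QLDS points depending on the banding scheme; a
7-point EQ-VAS improvement projects to −9.0 QLDS points; half the SD of
QLDS change is 5.0. The pooled median, −8.09, rounds to a recommended
**8-point improvement** as the meaningful change threshold.

Individual stages are exported and pipe-friendly — `compute_changes()`,
`qualify_anchors()`, `group_by_anchor_change()`, `summarize_groups()`,
`fit_change_regression()` (with `tidy()`/`glance()`), `half_sd_mct()`,
`triangulate()`, `stratified_cdfs()` — plus `plot_group_means()`,
`plot_cdf_curves()` and `plot_candidates()` for the standard figures, and
`write_report()` for a CSV/JSON bundle. See
`vignette("qldsmct-methods")` for the full methodological account.

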