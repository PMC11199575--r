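# ivret

Responder/non-responder analysis of pre/post exercise-intervention
outcomes, for exercise scientists and biostatisticians studying
**inter-individual variability in response to training (IVRET)**: not just
whether an intervention works on average, but who benefits, by how much,
and whether benefiting in one outcome (body fat) predicts benefiting in
others (blood pressure, cardiorespiratory fitness).

## What it computes

**Classification.** With change scores Δᵢ = postᵢ − preᵢ, the typical
error of measurement is

    TE = SD_diff / √2

and a participant is a **responder (Rs)** when their beneficial change
(−Δ for outcomes that improve by decreasing, +Δ otherwise) strictly
exceeds **2·TE**; otherwise a **non-responder (NRs)**. Cutoffs are
estimated per stratum (per sex by default), or from a reference set of
change scores (e.g. a control group), or fixed by the user.

**Inference around the classification.**

* Cross-outcome concordance: 2×2 contingency tables, Pearson χ²
  independence test (df = 1, optional Yates correction), odds ratio with
  Haldane–Anscombe option and Wald CI, Cramér's V, and Sankey-ready flow
  tables.
* 2 (Rs/NRs) × 2 (pre/post) mixed between-within ANOVA with generalized
  eta squared (η²_G), Bonferroni post-hoc contrasts (m = 4), percent
  changes Δ% = |mean Δ| / mean_pre × 100, and the study-table effect-size
  conventions ESw = |mean Δ| / √((s²_pre + s²_post)/2) and
  ESb = |x̄₁ − x̄₂| / √((s₁² + s₂²)/2), with noncentral-t confidence
  intervals; baseline-adjusted ANCOVA of post values; Shapiro–Wilk /
  Levene diagnostics.
* Baseline moderation: per-group OLS of Δ on baseline body fat and the
  hierarchical two-line comparison (slope interaction in the full model,
  vertical shift in the parallel-slopes model).
* Repeated-measures correlation r_rm (subject-specific intercepts, one
  common slope, df = N − k − 1), implemented from scratch by
  within-subject centering.
* A synthetic cohort generator with known ground truth (true individual
  response SD, technical error, cross-outcome response correlations),
  calibrated to a 73-adolescent school-based HIIT cohort, so the entire
  pipeline is testable without real data.

Deterministic physiological helpers are included: Harvard step-test
fitness index FI = 100·L/(5.5·p), Tanaka HRmax = 208 − 0.7·age, intensity
bands, BMI.

## Worked example

```r
library(ivret)

cohort <- simulate_cohort(simulation_params(seed = 7))   # 73 subjects, 31 M / 42 F
labels <- classify_response(cohort, "BFP", strata = "sex")
labels
#> <responder_labels> outcome BFP (benefit = decrease): NRs = 65, Rs = 8
#>   stratum male     n =  31  TE = 2.256  cutoff = 4.511
#>   stratum female   n =  42  TE = 2.137  cutoff = 4.275
```

Eight adolescents reduced body fat by more than twice the typical error
estimated within their sex stratum (4.5 percentage points for males, 4.3
for females). Did they also gain more fitness?

```r
fit <- mixed_anova(cohort, labels, "FI")
fit
#> <prepost_result> outcome FI (2 x 2 mixed ANOVA, GG epsilon = 1)
#>      effect df1 df2 statistic   p_value     ges
#>       group   1  71     1.955 0.1663740 0.02364
#>        time   1  71    16.330 0.0001332 0.02700
#>  group:time   1  71     9.289 0.0032365 0.01554
#>
#> Change by group:
#>  group  n mean_delta sd_delta  ci_lo ci_hi pct_change
#>     Rs  8      5.294    3.494 2.3728 8.215     11.981
#>    NRs 65      1.236    3.560 0.3538 2.118      2.828
```

The group-by-time interaction (F(1,71) = 9.29, p = 0.003) says the
fitness-index gain differs by response category: +5.3 points (12.0%) in
body-fat responders versus +1.2 points (2.8%) in non-responders. The
Bonferroni post-hocs localize it:

```r
bonferroni_posthoc(fit)
#>            contrast estimate statistic df   p_raw  p_adj     d    d_lo  d_hi
#> 1   Rs: post vs pre    5.294     4.286  7 0.00363 0.0145 1.638  0.4887 2.740
#> 2  NRs: post vs pre    1.236     2.799 64 0.00676 0.0271 0.234  0.0644 0.402
#> 3  Rs vs NRs at pre    0.484     0.276 71 0.78362 1.0000 0.125 -0.7654 1.015
#> 4 Rs vs NRs at post    4.542     2.200 71 0.03105 0.1242 0.940  0.0853 1.788
```

Both groups improved, but the responders' within-group effect is large
(d = 1.64) against small in non-responders (d = 0.23), with no baseline
difference. The within-subject coupling of fat and fitness in responders:

```r
rmcorr_prepost(cohort, "BFP", "FI", labels = labels, category = "Rs")
#> <rmcorr_result> r_rm = -0.829, df = 7, p = 0.005739 (common slope -0.8307, 8 subjects)
```

Lower body fat goes with a higher fitness index within the same subject
(r_rm = −0.83): the generator's built-in negative true-response
correlation, recovered by the statistic.

The whole sequence — classify, flow tables, per-outcome ANOVA bundles,
moderation regression, rmcorr, with provenance-stamped CSV/JSON outputs —
runs as one call:

```r
run_pipeline(list(simulation = list(), seed = 7, output_dir = "run1"))
```

See `vignettes/responder-analysis.Rmd` for the model, conventions, and
design decisions.

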