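---
title: "Typical-error responder classification and the analysis of individual response to training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typical-error responder classification and the analysis of individual response to training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ivret)
```

## The problem

Exercise interventions are usually reported as mean pre/post changes, but
individuals vary widely around that mean. Part of the spread is technical
(measurement error at each occasion), part is genuine between-subject
variability in the true response, and part is within-subject variability
across outcomes. `ivret` implements the analysis chain used to study this
inter-individual variability in response to training (IVRET) in a pre/post
design with one intervention group:

1. classify each participant as a responder (Rs) or non-responder (NRs)
   per outcome using a typical-error cutoff on the change score;
2. ask whether response categories agree across outcomes (flow tables,
   chi-squared independence, odds ratio, Cramér's V);
3. quantify adaptation within and between categories (2×2 mixed
   between-within ANOVA, Bonferroni post-hocs, baseline-adjusted ANCOVA,
   standardized effect sizes, percent changes);
4. ask whether baseline body fat moderates the response (two-line
   regression comparison); and
5. estimate the common within-subject association between body fat and
   each physiological outcome (repeated-measures correlation).

The motivating setting is a ten-week school-based HIIT programme in
adolescents with four outcomes: body fat percentage (BFP, %, benefit =
decrease), systolic and diastolic resting blood pressure (SBP/DBP, mmHg,
decrease), and the Harvard step-test fitness index (FI, increase), with a
cohort of 73 adolescents (31 male, 42 female, age ≈ 16.1 ± 0.4 y).

## Responder classification by typical error

The typical error of measurement is estimated from the change scores as

$$\mathrm{TE} = \mathrm{SD}_{\mathrm{diff}} / \sqrt{2},$$

where $\mathrm{SD}_{\mathrm{diff}}$ is the sample SD (n − 1 denominator)
of post − pre. A change score carries the measurement error of both
occasions; under pure technical noise its SD is $\sqrt{2}$ times the
per-occasion error, which the division undoes. A subject is a responder
when their *beneficial* change (the change score oriented by the outcome's
benefit direction) strictly exceeds $2\,\mathrm{TE}$; a tie at the cutoff
is a non-responder. Cutoffs are computed per stratum (per sex by default),
mirroring the practice of sex-specific cutoffs estimated from the studied
sample; a control-group reference or a fixed cutoff can be substituted via
`te_source`, since control-group TE is the literature-preferred estimator
of pure technical noise when a control arm exists.

A consequence worth knowing: when there is *no* true response
heterogeneity and no mean effect, the observed change is pure noise with
SD $\sigma_t\sqrt{2}$, while TE estimates $\sigma_t$; the standardized
cutoff is therefore
$2\mathrm{TE}/(\sigma_t\sqrt{2}) = \sqrt{2}$, so the expected false-positive
responder rate is $P(Z > \sqrt{2}) \approx 0.079$ per tail, not the 2.3%
that a two-sigma rule might suggest. The test suite checks this analytic
rate by Monte Carlo.

```{r classify}
cohort <- simulate_cohort(simulation_params(seed = 1))
labels <- classify_response(cohort, "BFP", strata = "sex")
labels
```

## The synthetic cohort generator

No subject-level data are deposited for the motivating study, so the
package ships a generative model with known ground truth. Each subject
has a latent baseline per outcome, a true change drawn from a
multivariate normal with mean `mu_delta`, SD `sd_individual_response`
(SD~IR~) and a cross-outcome correlation matrix, and independent technical
error at each occasion:

$$y_{\mathrm{pre}} = b + \varepsilon_1, \qquad
  y_{\mathrm{post}} = b + \Delta + \varepsilon_2, \qquad
  \varepsilon_j \sim N(0, \sigma_t^2).$$

Ground-truth columns record each subject's latent $\Delta$ and whether its
beneficial component exceeds the *generative* cutoff $2\sigma_t$, so
classification can be validated exactly on noise-free draws.

Default parameters were fixed once from the published group-level tables
of the motivating study and are not tuned thereafter: cohort composition
31 M / 42 F, age 16.1 ± 0.4 y; sex-specific height/weight (176.74 ± 6.07
cm, 65.42 ± 12.51 kg for males; 164.38 ± 6.54 cm, 56.71 ± 10.23 kg for
females); baselines BFP 22.0 ± 8.1 %, SBP 119.5 ± 11.1 mmHg, DBP
72.9 ± 7.4 mmHg, FI 44.0 ± 4.3. Mean true changes (BFP −0.7 %, SBP −6.2,
DBP −2.5 mmHg, FI +2.0) and SD~IR~ values (3.0, 7.0, 7.5, 3.3) were chosen
so the observed change-score SDs, $\sqrt{\mathrm{SD_{IR}}^2 + 2\sigma_t^2}$,
match the printed Δ SDs; technical errors (0.5 %, 3 mmHg, 3 mmHg, 1.5)
reflect the instruments involved (high-reliability bioimpedance; automated
cuff averaged over three readings; a field step test). The true-response
correlation couples fat loss with fitness gain (BFP–FI −0.6) and weakly
with pressure reduction; −0.6 is the value at which the simulated
fitness-index interaction reproduces the strong signature the study
reports. With these defaults the sex-specific BFP cutoffs come out near
5.8 % (males) and 3.8 % (females), the same order as the published 6.298 %
and 3.245 %.

What the generator does *not* emulate: growth and maturation over the
intervention window, dropout or missingness (the package has a
complete-case contract), floor/ceiling effects, and any control arm.
Passing tests therefore demonstrate internal statistical correctness of
the procedures under a plausible data-generating process — not that any
particular field dataset satisfies the model's assumptions.

Two optional generator features support sensitivity analyses rather than
the default conditions: `baseline_response_correlation` couples a
subject's baseline with their true change (the default 0 makes "no
baseline moderation" true by construction, so the two-line comparison is
calibrated under its null), and `responder_fraction_override` forces a
chosen true-responder proportion by drawing the beneficial change on the
prescribed side of the generative cutoff (useful because the motivating
study never reports its Rs/NRs group sizes; the override deliberately
replaces the normal response model for that outcome).

## Pre/post inference

`mixed_anova()` fits the 2 (response category) × 2 (time) between-within
design via the standard error-stratum decomposition. With two
within-subject levels sphericity holds by construction, so the
Greenhouse–Geisser ε is reported as exactly 1 (the correction machinery
would be active only with ≥3 occasions, which this release does not
expose). Effect sizes use generalized eta squared,
$\hat\eta^2_G = SS_{\mathrm{effect}} / (SS_{\mathrm{effect}} +
SS_{\mathrm{error,between}} + SS_{\mathrm{error,within}})$, the
denominator appropriate to repeated-measures designs. A useful algebraic
identity — the interaction F equals the squared t of the unpaired
pooled-variance test on change scores — serves as an independent oracle in
the tests.

Post-hoc contrasts are the four comparisons of the 2×2 cell display:
pre vs post within each category (paired) and Rs vs NRs at each occasion
(unpaired), with Bonferroni family size m = 4 and
$p_{\mathrm{adj}} = \min(1, 4p)$.

Two effect-size conventions needed a decision because the within-group
convention of the motivating study is not stated:

* **ESw** (within group): $|\bar\Delta| / \sqrt{(s_{\mathrm{pre}}^2 +
  s_{\mathrm{post}}^2)/2}$. This pooled pre/post standardizer reproduces
  both published within-group values (0.28 and 0.18) from the published
  means and SDs, whereas the change-score convention ($\bar\Delta /
  s_\Delta$) would give 0.66 for the responders — clearly not what was
  printed. The change-score convention remains available by flag.
* **ESb** (between groups): $|\bar x_1 - \bar x_2|$ over the equal-weight
  pooled SD $\sqrt{(s_1^2 + s_2^2)/2}$, which reproduces the published
  post-intervention value (0.39); sample-size weighting is available but
  requires group sizes, which the motivating study never printed.

Confidence intervals for standardized effects invert the noncentral t
distribution of the corresponding test statistic; where the reported
effect size uses a different standardizer than the statistic (the pooled
pre/post ESw vs the paired t), the interval is rescaled around the
estimate, a documented approximation. A normal-approximation fallback is
available.

The change-score comparison between the two response categories is an
independent-samples t-test (Student by default, Welch by flag): the
categories are disjoint groups of different subjects, so a paired test is
not defined for this contrast.

`ancova_post()` compares post-intervention means adjusted for baseline
(`post ~ group + baseline`). A constant baseline carries no information;
rather than fail, the covariate is dropped with a warning and the
comparison reduces to the unadjusted t-test, which is the same limit the
adjusted analysis approaches as baseline variance vanishes.

Diagnostics follow the conventional battery: Shapiro–Wilk per design
cell (skipped with a recorded reason below n = 3), Levene's test across
groups at each occasion using absolute deviations from the group means,
and the trivial-sphericity note.

## Baseline moderation: comparing two regression lines

Per category, the change score is regressed on baseline BFP. The
categories are compared hierarchically in a pooled model with an NRs
reference indicator: the slope difference is the interaction coefficient
in the full model; the vertical (intercept) shift is the group coefficient
in the parallel-slopes model. The hierarchy matters: a vertical shift is
interpretable only when the lines are parallel, and the motivating
analysis reports exactly this combination (significant shift,
non-significant interaction) for the fitness index. A joint-model option
reports the group term with the interaction retained, off by default.

## Repeated-measures correlation

`rmcorr()` estimates the common within-subject association between two
variables measured at both occasions: a fit of y on x with one intercept
per subject and a single shared slope, computed by within-subject
centering. The estimate is
$r_{rm} = \mathrm{sign}(b)\sqrt{SS_x / (SS_x + SS_{\mathrm{res}})}$ with
$N - k - 1$ degrees of freedom (k subjects, N observations; k − 1 for two
occasions). With two occasions this is algebraically the through-origin
correlation of difference scores, $\sum \Delta x \Delta y /
\sqrt{\sum \Delta x^2 \sum \Delta y^2}$ — both identities are verified
numerically in the tests against an explicit subject-indicator
least-squares fit. Subject intercepts absorb any per-subject constant, so
the statistic is invariant to between-subject level differences; it
captures only the common intra-individual trend. This release supports
exactly two occasions per subject; the decomposition generalizes, and more
occasions are a documented extension rather than a redesign. The x/y
orientation (body fat as x) affects only the plotted per-subject lines,
not the magnitude of the statistic.

## Numerical and degenerate-input conventions

* Ties at the classification cutoff are non-responders (strict `>`), per
  the "greater than two-fold TE" rule.
* A stratum, group, or cell too small for a procedure is an error naming
  the stratum (classification, ANOVA) or a recorded skip (per-cell
  diagnostics) — never a silent NA.
* Heart-rate presentation values round half away from zero; internal
  values stay unrounded.
* The step-test formula's stated domain is L < 300 s, but a completed
  test lasts exactly 300 s; the package accepts L ≤ 300 since excluding
  completers would be nonsensical.
* Zero cells in the odds ratio are flagged (`degenerate = TRUE`) unless
  the Haldane–Anscombe 0.5 correction is requested; a zero table margin
  makes the chi-squared test an error, distinct from the small-cell
  warning.
* All simulation draws flow from one master seed; identical parameters
  and seed give byte-identical CSV output.

## Problem sizes used in the test suite

The suite validates the Monte-Carlo properties at sizes chosen to make
the checks sharp but quick: moment matching pools 200 cohorts of n = 73;
correlation recovery uses one cohort of n = 2000 (tolerance 0.05); the
technical-error false-positive rate uses n = 5000 (tolerance 0.01 against
the analytic 0.0786); the type-I calibration of the interaction test uses
500 null cohorts of n = 73 (three binomial SEs around 5%); the oracle
equivalences use 100 random small datasets each, and the chi-squared
brute-force identity is checked exhaustively over all 2×2 tables with
cells ≤ 20.

## Known limitations

* Two groups, two occasions only; no >2-level within factors, no
  multilevel random-slope models.
* The published subject-level statistics of the motivating study (exact
  cutoffs, F values, correlation coefficients) are not reproducible
  without its raw data; the package treats them as qualitative anchors
  for the calibrated simulator, not as assertions.
* Cohen's d confidence intervals for the pooled pre/post ESw convention
  are rescaled noncentral-t intervals, an approximation documented above.
* The complete-case contract is deliberate: missing-data handling belongs
  upstream of this analysis.
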