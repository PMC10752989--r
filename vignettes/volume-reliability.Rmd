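---
title: "Evaluating volumetric biomarkers: accuracy, test-retest reliability and longitudinal variance components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating volumetric biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volrely)
```

## The problem

Automated pipelines that measure the volume of a brain structure — the
hippocampus is the motivating example — must be judged on three axes
before they can support longitudinal studies where the expected effect is
a volume change of only one or two percent:

1. **Accuracy**: how close are automated volumes to a manual reference?
2. **Test–retest reliability**: how stable is the measurement when the
   same person is scanned twice under unchanged conditions?
3. **Longitudinal reliability**: does the measurement separate people
   from each other while staying reproducible within a person over
   repeated visits?

`volrely` implements one coherent statistical pipeline for all three,
together with a synthetic-data generator that reproduces the exact
distributional structure each analysis assumes, so every stage is
testable without any imaging data.

## Metrics

**Volume percentage error.** For a predicted volume $v_{pred}$ and a
ground-truth volume $v_{gt}$,
$\mathrm{VPE} = 100\,(v_{pred} - v_{gt})/v_{gt}$. The mean VPE over
subjects measures systematic bias (sign preserved: underestimation is
negative), the SD measures precision. Accuracy tables report median,
mean, 25th/75th percentiles (linear interpolation) and the sample SD.

**Pearson correlation** between automated and reference volumes
side-steps differences in boundary protocols: a method may be biased yet
rank subjects perfectly. Bands: $r > 0.9$ very strong, $0.7 < r \le
0.9$ strong, $0.4 < r \le 0.7$ moderate, otherwise weak/negligible.
Boundary values deliberately fall in the lower band, reading the cut
points as strict inequalities.

**Volume percentage difference.** For test/retest volumes,
$\mathrm{VPD} = 100 \cdot 2\,|v_{test}-v_{retest}|/(v_{test}+v_{retest})$,
symmetric in its arguments and invariant to a common rescaling. Reports
include the share of subjects with VPD below 2%, a threshold chosen
because it brackets both exercise-intervention effects (~1.2%) and
annual age-related atrophy (0.8–1.7%).

**Intraclass correlation.** `icc_consistency()` implements the
single-rater, consistency, two-way mixed-effects ICC: with $MS_R$ the
between-subject and $MS_E$ the residual mean square after removing a
session effect,
$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)\,MS_E}.$$
Removing the session effect makes the estimate insensitive to a constant
offset between sessions — scanner drift that affects everyone equally is
not charged against reliability. The 95% CI is the standard F-based
interval ($F = MS_R/MS_E$ on $(n-1, (n-1)(k-1))$ degrees of freedom,
each bound mapped through $(F/F_{crit}-1)/(F/F_{crit}+k-1)$); the CI
construction is not stated in the literature this layout follows, so the
F-based companion of this ICC form is used and documented here rather
than a bootstrap. Bands: $<0.75$ poor, 0.75–0.95 good, $>0.95$
excellent. Missing sessions are rejected, not imputed: the analyses are
defined on complete pairs.

## The hypothesis-testing battery

Comparisons between two methods use, at a study-wide $\alpha = 0.01$:

* a **normality-gated paired location test** on the per-subject metric
  (absolute VPE for accuracy, VPD for test–retest): each sample is first
  screened with a one-sample Kolmogorov–Smirnov test against a normal
  with estimated mean and SD at $\alpha = 0.05$; if either sample
  rejects, a Wilcoxon matched-pairs signed-rank test is used, otherwise
  a paired t-test. Estimating the KS parameters from the sample makes
  the gate conservative (true rejection rate under normality is below
  5%); this is retained as the stated procedure rather than replaced by
  a Lilliefors correction, and simulations in the test suite confirm the
  gated test still holds its level. The Wilcoxon branch drops zero
  differences, uses the exact sign-flip null distribution (computed by
  convolution, midranks included) up to 25 non-zero differences, and the
  continuity- and tie-corrected normal approximation above; two-sided
  p-values double the smaller tail, capped at 1. All differences zero
  returns p = 1: no evidence, not an error.
* an **F-test on VPE variances** (precision), two-sided by doubling the
  smaller tail.
* a **Fisher z-test on the two correlations** (accuracy), treating them
  as independent. When both methods are correlated against the same
  manual volumes the independence assumption is only approximate; the
  test is computed in the standard independent-samples form on purpose,
  and this caveat is the reason a dependent-correlation test (Steiger or
  Williams) is listed as an extension rather than silently substituted.

Interval estimates (ICC, and the posterior summaries below) are compared
by an **overlap rule**: two estimates differ significantly when neither
point estimate lies inside the other interval. The rule could be read
one-directionally; the symmetric reading is the default because it is
the conservative one, and the asymmetric variant is available behind the
`rule` argument of `ci_overlap_significant()`.

## The longitudinal hierarchical model

For volumes $V_{ij}$ of subject $i$ at visit $j$, with $t$ the time in
months from that subject's own baseline:

$$V_{ij} \sim N(\alpha_i + \beta_i t_{ij},\ \sigma^2), \qquad
\alpha_i \sim N(\alpha_0, \tau^2), \qquad \beta_i \sim N(\beta_0, \rho^2)$$
$$\alpha_0, \beta_0 \sim N(0, 10^2), \qquad
\sigma, \tau, \rho \sim \mathrm{Cauchy}^+(0, 5)$$

$\tau$ is the between-subject variability, $\sigma$ the within-subject
variability, and the **variance ratio** $r = \tau/\sigma$ is the
headline statistic: a good longitudinal biomarker discriminates between
subjects (large $\tau$) while repeated measurements of one subject stay
tight around that subject's trend (small $\sigma$).

Two prior-scale readings were open: the second arguments of
$N(0, 10)$ and $\mathrm{Cauchy}^+(0, 5)$ could be SDs or variances, and
the volume scale of the fit is unstated. They are read as SD/scale, and
volumes are standardized by their grand mean and SD before fitting
(default `standardize = TRUE`): on raw volumes of thousands of mm³ these
priors would be absurdly informative, so the standardized-scale reading
is the only one under which they are weakly informative. $r$ is
invariant to this choice, and all location/scale summaries are reported
on both the fitting and the raw scale (`summaries` / `summaries_raw`).

### Sampler

The model is linear-Gaussian given its variance components, and the
sampler exploits that three ways:

* $(\alpha_i, \beta_i)$ are drawn jointly per subject from their exact
  bivariate Gaussian full conditionals; $\alpha_0, \beta_0$ from their
  Gaussian conditionals.
* $(\tau, \sigma, \rho)$ get a **collapsed** update: a joint lognormal
  random walk (step adapted during warmup only) whose target is the
  marginal posterior with all subject effects integrated out
  analytically (a 2×2 Woodbury computation on per-subject sufficient
  statistics). Because the effects are re-drawn jointly right after,
  this is a valid partially collapsed move — and it is immune to the
  funnel-shaped coupling between a small variance component and its
  subject effects that stalls purely centered samplers.
* each scale also gets independence-Metropolis refreshes against its
  exact conditional shape (inverse-gamma in the centered
  parameterization, truncated-normal in an interweaved non-centered
  one), leaving only the slowly varying half-Cauchy prior ratio in the
  acceptance probability.

Four chains (default) start from dispersed data-informed values; chain
$c$ is seeded with `seed + c`, making fits bit-reproducible. After
sampling, split-Rhat is computed for **every** sampled parameter and the
fit fails loudly — listing the offending parameters — if any exceeds
1.01. The threshold is deliberately strict; `rhat_max` is exposed for
exploratory work but the default is the contract. Default budgets are
1500 warmup plus 3000 retained draws per chain, chosen so that the
strict diagnostic passes with margin on cohorts of tens of subjects and
a handful of visits (a few seconds of CPU per fit at 40 subjects ×
5 visits). $r$ is summarized as the posterior mean of the per-draw
ratio $\tau/\sigma$ (not the ratio of means), with a central 95%
credible interval.

Designs in which every subject has a single visit leave $\rho$
unidentified; such fits are refused unless $\rho$ is pinned with
`blme_spec(fix_rho = )`. The sampler is validated in the test suite
three ways: the exact joint log posterior matches a hand-computed
closed-form case; a conjugate reduction matches its Rao–Blackwellized
closed form; and a full fit matches an independent JAGS implementation
of the same model to within Monte-Carlo error.

## The synthetic-data generator

`simulate_longitudinal()` draws from exactly the hierarchical model
above — subject effects first (in subject order, so extending the visit
grid does not change who the subjects are), then residuals. No
positivity truncation is applied there, because the model itself is
Gaussian and standardized-scale configurations legitimately produce
non-positive values. `simulate_testretest()` (true volume per subject
plus independent session noise) and `simulate_accuracy()` (multiplicative
bias-plus-noise on a truncated-Gaussian ground truth) emulate physical
volumes, so non-positive draws are rejected and redrawn, with the count
logged and parameter regimes implying more than 1% rejection flagged —
heavy truncation would distort the generative law the analytic checks
rely on. The accuracy generator's multiplicative percent-error form is
an artifact choice (no generative model for error dispersion is given in
the literature this mirrors); its consequence — VPE mean ≈ bias, VPE SD
≈ noise — is what the tests verify.

Default study conditions used throughout the tests mirror the designs
the pipeline emulates: 45-subject two-session panels with between/within
SDs of 300/30 mm³ around 3000 mm³ (generative ICC 0.990); accuracy
panels with 1.5% bias and 5.2% dispersion; and 40-subject cohorts at
months 0/3/6/9/12 with $\tau = 1$, $\sigma = 0.2$, $\rho = 0.02$ on the
standardized scale (true $r = 5$).

What the generator does **not** emulate: scanner- or field-strength
effects beyond variance components, segmentation failures producing
outliers or zero volumes, heteroscedastic errors, non-linear
trajectories, and informative dropout. Passing tests therefore show the
statistical machinery is correct under its own assumptions, not that any
particular imaging pipeline is reliable on real data.

## Numerical choices and degenerate inputs

* Percentiles use linear interpolation between order statistics
  (quantile type 7), the common default; the SD uses $n-1$.
* Band boundaries fall into the lower band everywhere (strict readings
  of the published cut points).
* Zero residual variance makes the ICC CI degenerate at the estimate;
  zero total variance is an error.
* `vpe`/`vpd` reject non-positive volumes; `blme_log_posterior` returns
  $-\infty$ (rejected region, not an exception) for non-positive scales.
* Split-Rhat is reported as `NA` for parameters with zero variance
  (e.g. a fixed $\rho$) and such parameters are exempt from the
  convergence gate.
* Monte-Carlo test tolerances scale as $1/\sqrt{n}$; moment checks use
  $n \ge 2000$. Recovery checks for the hierarchical fit average point
  estimates over five replicate cohorts, because at 40 subjects the
  cohort-to-cohort spread of the posterior mean (driven by the partial
  confounding of $\sigma$ with $\rho\,t$ noise at five visits) is
  comparable to the recovery tolerance itself; interval calibration is
  checked as frequentist coverage over 50 cohorts.

## Limitations

* The Fisher z comparison ignores the dependence induced by the shared
  reference volumes (see above); with strongly correlated methods it is
  anticonservative.
* The CI-overlap rule is a heuristic, not a calibrated test; its type-I
  behaviour depends on the interval widths.
* No multiple-testing correction is applied anywhere, matching the
  procedure the pipeline reproduces.
* The longitudinal model is linear in time with Gaussian components and
  time as the only covariate; diagnosis, age or scanner covariates are
  out of scope.
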