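# volrely

Statistical evaluation of volumetric biomarkers — accuracy, test–retest
reliability, and longitudinal variance components — for comparing volume
measurement methods such as automated hippocampal segmentation pipelines.

Volume changes that matter in longitudinal neuroimaging are small: annual
age-related hippocampal atrophy is 0.8–1.7%, exercise-intervention effects
about 1.2%. Whether a measurement pipeline can see such changes is a
statistical question about its bias, precision and variance components.
`volrely` implements the full evaluation battery on one common input — a
long-format table of per-subject, per-session volumes — and ships a
synthetic-data generator with the exact distributional structure each
analysis assumes, so the whole pipeline runs and is tested without any
MRI data.

## What it computes

**Accuracy** (`run_accuracy`): volume percentage error
VPE = 100·(v_pred − v_gt)/v_gt per subject, summarized as median / mean /
quartiles / SD; Pearson correlation with the reference volumes, with
interpretation bands (r > 0.9 very strong, …).

**Test–retest** (`run_testretest`): volume percentage difference
VPD = 100·2·|v_test − v_retest|/(v_test + v_retest); the single-rater,
consistency, two-way mixed-effects intraclass correlation
ICC = (MS_R − MS_E)/(MS_R + (k−1)·MS_E) with an F-based 95% CI and
reliability bands (< 0.75 poor, 0.75–0.95 good, > 0.95 excellent).

**Longitudinal** (`run_longitudinal`): a Bayesian hierarchical linear
mixed-effects model fitted by MCMC,

    V_ij ~ N(alpha_i + beta_i * t_ij, sigma^2)
    alpha_i ~ N(alpha0, tau^2),  beta_i ~ N(beta0, rho^2)
    alpha0, beta0 ~ N(0, 10^2),  sigma, tau, rho ~ Cauchy+(0, 5)

with t in months from each subject's baseline. tau is the
between-subject and sigma the within-subject variability; the **variance
ratio r = tau/sigma** (posterior mean and 95% credible interval) is the
headline longitudinal-reliability statistic — higher means the
measurement separates subjects while staying reproducible within
subject.

**Method comparisons**: normality-gated paired t / exact Wilcoxon
signed-rank tests (α = 0.01), an F-test on error variances, a Fisher
z-test on correlations, and a confidence-interval overlap rule for ICCs
and posterior summaries (significant iff neither estimate lies inside
the other's interval).

## Worked example

```r
library(volrely)

# a 45-subject two-session panel: true volume ~ N(3000, 300^2) mm^3,
# session noise SD 30 mm^3  =>  generative ICC = 300^2/(300^2+30^2) = 0.990
tab <- simulate_testretest(45, mu = 3000, between_sd = 300, within_sd = 30,
                           seed = 7)
rep <- run_testretest(tab)
rep$icc[["simulated/hippocampus_L"]]
#> ICC (two-way mixed, consistency, single rater): 0.9926, 95% CI [0.9865, 0.9959] (excellent reliability)
#>   n = 45 subjects, k = 2 sessions

# a longitudinal cohort: 40 subjects, visits at 0/3/6/9/12 months,
# tau = 1, sigma = 0.2 (standardized scale)  =>  true variance ratio 5
cfg <- sim_config(40, c(0, 3, 6, 9, 12), alpha0 = 0, beta0 = -0.02,
                  tau = 1, rho = 0.02, sigma = 0.2, seed = 11)
fit <- fit_blme(simulate_longitudinal(cfg), blme_spec(seed = 3))
variance_ratio(fit)
#> $mean
#> [1] 4.047147
#>
#> $ci
#> [1] 3.127479 5.269445
```

The ICC estimate sits on its analytic target and the posterior of
r = tau/sigma brackets the generative value 5; `fit$summaries_raw` gives
tau/sigma on the original volume scale, and every fit carries split-Rhat
diagnostics (fits failing the 1.01 threshold error out rather than
return silently).

A thin command-line wrapper over these functions is installed at
`inst/cli/volrely.R` (modes `simulate` / `accuracy` / `testretest` /
`longitudinal`, YAML or JSON config; exit codes 0/2/3 for
success/validation error/non-convergence).

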