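---
title: "Mediation in two-timepoint randomized trials: models, gate, bootstrap"
author: "rmmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mediation in two-timepoint randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmmediate)
```

## The problem

Small behavioural trials — for instance a 12-week physical-activity
intervention in breast cancer survivors, with 43 exercise and 44 control
participants measured at baseline and week 12 — often ask not only *does
the intervention work* but *through what*.  Did the intervention improve
self-reported cognition because it reduced anxiety?  Because it improved
physical functioning?  Through an inflammatory or neurotrophic biomarker?
`rmmediate` packages that question as a reusable pipeline: repeated-measures
mixed models for every causal-steps path, a significance screen for which
mediators are worth testing, and a subject-resampling bootstrap for the
indirect effect's confidence interval.

## The model

Every path model is a linear mixed model with a subject-level random
intercept.  For a variable $V_{it}$ (mediator or outcome) on subject $i$,
arm $g_i \in \{0,1\}$ (0 = control, 1 = exercise), timepoint
$t \in \{0,1\}$ (0 = baseline, 1 = week 12):

$$V_{it} = \beta_0 + \beta_g g_i + \beta_t t + \beta_{gt}\, g_i t
  + u_i + \varepsilon_{it}, \qquad u_i \sim N(0,\tau^2),\;
  \varepsilon_{it} \sim N(0,\sigma^2).$$

The coefficient $\beta_{gt}$ is the **difference of change**: the
between-arm difference in baseline-to-week-12 change, the natural
treatment-effect contrast for a two-timepoint trial.  With only two
timepoints, a fully unstructured marginal covariance on top of a random
intercept is not identifiable; the implied compound-symmetric structure
(equal variances $\tau^2+\sigma^2$, covariance $\tau^2$) is the default,
and `covariance_mode = "heteroscedastic_time"` frees the residual
variance to differ by timepoint for users who want the richer structure.

Fitting is by REML through `lme4` (the heteroscedastic mode through
`nlme` with timepoint-stratified residual variances); full ML is
available, and AIC model comparisons are exposed only under ML because
REML likelihoods of models with different fixed effects are not
comparable.  Inference on fixed effects is Wald-normal ($z$); we chose
this over a degrees-of-freedom approximation because the analyses the
package automates (path screening and a bootstrap CI) do not rest on the
per-coefficient small-sample P values, and the choice keeps every mode
of the engine consistent.  Satterthwaite-type corrections are out of
scope.  Rows with a missing response are dropped (available-case
analysis), which is unbiased when week-12 records are missing at random;
all randomized subjects contribute their baseline data (intent to
treat).  Biomarkers are log transformed (natural log) before modelling
to correct right-skew; the log is the only transform the data model
applies.

### Numerical choices

The optimizer runs with a relative likelihood tolerance of $10^{-8}$ and
an evaluation budget of 200; a fit that stops without satisfying the
optimizer is flagged `converged = FALSE` and refused by the contrast
extractor — never silently retried on altered data.  Two boundary cases
are deliberately treated as converged: a random-intercept variance
estimated at zero (a singular but valid REML solution), and a residual
variance at numerical zero (a perfect within-subject fit, where the
profiled objective decreases without a finite optimum while the fixed
effects are exact).  On balanced complete data the group-by-time
estimate equals the difference-in-differences of the four cell means for
*any* variance-component values; the test suite holds the engine to that
oracle at $10^{-8}$.

## The causal-steps mediation

For a mediator $M$ and outcome $Y$:

* **path a** — group-by-time coefficient of the model for $M$;
* **path c** — group-by-time coefficient of the model for $Y$;
* **path c′** and **path b** — group-by-time and mediator coefficients
  of the model for $Y$ that adds the mediator's concurrent value as a
  time-varying covariate.

Two ambiguities in the usual statement of the causal steps are resolved
as package defaults.  First, "the mediator is associated with the
outcome" does not say whether path b is adjusted for treatment; we read
b from
the multivariable (c′) model — the standard causal-steps practice — and
provide `b_adjusted = FALSE` for the unadjusted variant.  Second, the
mediator enters the c′ model as its concurrent value at each timepoint
(the repeated-measures analogue of controlling for the mediator), with a
baseline-adjusted change-score formulation intentionally left out of the
default path.

A mediation test proceeds only when paths a, b and c are all significant
at the gate level, default $\alpha = 0.10$ — a liberal screen
appropriate to small pilot samples.  The inequality is strict:
$P = 0.10$ exactly fails.  The **indirect effect** is the
difference of coefficients $c - c'$; in the linear Gaussian model with
no exposure-mediator interaction it coincides with the product $a\,b$,
and the test suite checks the two estimators against each other on
simulated trials.  No multiple-testing adjustment is applied across
mediator-outcome pairs (deliberately, matching the screening character
of the analysis); the report instead states the number of pairs tested.

## The bootstrap

The CI for $c - c'$ comes from a cluster bootstrap: each replicate
resamples *whole subjects* with replacement — a subject carries all its
repeated measures, and a subject drawn twice enters as two distinct
clusters — stratified by arm so every replicate preserves the trial's
per-arm counts.  Subject-level resampling is the only unit that respects
the random-intercept dependence; stratification preserves the 43/44
design.  The c and c′ models are refit on each replicate, and the
percentile interval is taken from the empirical quantiles of the
replicate $c - c'$ values, with linear interpolation between order
statistics.  Mediation is declared when the interval strictly excludes
zero.  BCa and parametric/residual bootstraps are out of scope.

Replicates whose refit fails to converge are redrawn up to 5 times and
then dropped and counted; the count is reported, never hidden, and more
than 10% failures raises a warning.  The default of 200 replicates
matches small-sample practice in the kind of trial the package emulates;
for production inference we recommend 1999 or more.  Seeding is
hierarchical: the pipeline derives each mediator-outcome pair's
resampling seed deterministically from the master seed and the pair's
names, so adding or removing a pair never perturbs the others — a
property the test suite asserts byte-for-byte on rendered reports.

## The synthetic trial generator

Because the motivating trial deposited no participant-level data, the
generator is the package's test bed.  It draws
$M_{it} = \mu_M + \gamma_M t + a\,g_i t + u_i + \varepsilon_{it}$ and
$Y_{it} = \mu_Y + \gamma_Y t + d\,g_i t + b\,M_{it} + v_i + \eta_{it}$,
so the implied total effect is $c = d + ab$ and the indirect effect is
$ab$ by construction.  Defaults emulate the motivating design: 43
exercise / 44 control, one dropout per arm (all week-12 records of a
uniformly chosen subject removed — missing at random by construction,
98% retention), mediator baseline mean 55.2 and outcome mean 45.4 on the
T-score scale, and total SD 8 split as $\tau^2 = 58$, $\sigma^2 = 6$.
The split is an assumption, not an estimate — the true between/within
decomposition of the emulated trial is unpublished — and was fixed so
that the difference-of-change SE at $n=87$ lands near the published 0.7;
patient-reported T-scores over 12 weeks are strongly subject-stable, so
a high intraclass correlation is the realistic regime.  Because the
outcome equation adds $b\,M_{it}$, the realized outcome baseline mean is
$\mu_Y + b\,\mu_M$; the means are cosmetic and play no inferential role.

`biomarker_mode` exponentiates the mediator so the linear model holds on
the log scale (emulating right-skewed positive biomarkers such as CRP or
an insulin-resistance index, which the pipeline log-transforms back);
`heavy_tailed` swaps Gaussian errors for scaled $t_4$ for robustness
exercises.  By default there is no exposure-mediator interaction and
errors are Gaussian — the minimal regime in which $c - c' = ab$, which
is what makes the product-vs-difference consistency checks meaningful.
What the generator does **not** emulate: item-level patient-reported
scoring, adherence dynamics, baseline covariate imbalance, informative
dropout, or floor/ceiling effects in T-scores.  Passing tests therefore
show the pipeline's statistical machinery is correct under the stated
model, not that any real trial satisfies that model.

## Calibration results the package itself computes

The test suite runs (sizes chosen to give stable Monte-Carlo answers):

* the DiD oracle on 4-subject toys, at tolerance $10^{-8}$;
* estimator consistency on 100 trials of 500 subjects/arm with $a = 2$,
  $b = 0.5$, $d = 0$: mean $c - c'$ within 2 Monte-Carlo SEs of 1.0 and
  per-replicate agreement of $c-c'$ with $ab$;
* CI coverage on 100 trials at the 43/44 design with one dropout per
  arm, true indirect $-0.6$, 199 replicates each: coverage required in
  [88%, 99%];
* the null ($a = b = 0$): at most 12 of 100 trials may pass the gate
  with a CI excluding zero;
* gate decisions reproduced from published screening P values, pooled
  baseline arithmetic, and byte-identical report reproducibility.

`scripts/acceptance.R` recomputes the same kinds of quantities from a
fresh seed at smaller Monte-Carlo sizes (20 trials for the bootstrap
summary, 50 for the null rate) and writes them as JSON.

## Known limitations

Only bivariate mediation (one mediator at a time) is implemented, as in
the screening analyses the package automates; multiple simultaneous
mediators, exposure-mediator interaction decompositions, and sensitivity
analysis for sequential ignorability are out of scope.  Two timepoints
only; no random slopes (unidentifiable here) or GEE alternative.  The
causal-steps gate is a screening device, not a causal identification
strategy: with ~87 subjects the power to detect modest mediation is
limited, and a passed gate plus a CI excluding zero is evidence worth
following up, not proof of mechanism.  A cautionary note on clinical
interpretation: the meaningful-change classifier applies its stated
threshold (3 T-score points, inclusive, direction-blind) exactly; it
will not reproduce judgement calls that describe sub-threshold changes
as "suggestive" of meaningful improvement.
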