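---
title: "MIMIC models for brain-behavior analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MIMIC models for brain-behavior analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Behavioral performance in cognitive-neuroscience tasks is usually condensed
into a single score per participant — a sum of correct responses or an IRT
ability estimate — and that score is then regressed on a brain measure. This
two-stage route discards the measurement model at exactly the point where it
matters: measurement error in the summary attenuates the estimated
brain-behavior coefficient, and item-level artifacts (items whose behavior
depends directly on the brain covariate, i.e. differential item functioning,
DIF) contaminate the summary itself.

`mimicirt` implements the joint alternative: the multiple-indicator
multiple-cause (MIMIC) model. Binary items measure a unidimensional latent
trait $\theta$ through a two-parameter response model, and $\theta$ is
simultaneously regressed on observed causes $x$ (here, ERP features):

$$y^*_i = \lambda_i \theta + \epsilon_i, \qquad y_i = 1 \iff y^*_i > \tau_i,
\qquad \theta = \gamma' x + \zeta .$$

Under the probit (normal-ogive) link the item residual is
$\epsilon_i \sim N(0, 1 - \lambda_i^2)$, so the latent response has unit
variance when $Var(\theta) = 1$; the familiar 2PL display parameters are
$a_i = \lambda_i / \sqrt{1 - \lambda_i^2}$ and $b_i = \tau_i / \lambda_i$.
Under the logit link the loading slot holds the discrimination $a_i$
directly and $\epsilon_i$ is standard logistic, giving
$P(y_i = 1 \mid \theta) = \text{logit}^{-1}\{a_i(\theta - b_i)\}$.

**Identification.** The population is standardized: with z-scored causes,
$Var(\zeta) = 1 - \sum_k \gamma_k^2$ so $Var(\theta) = 1$, and estimation
imposes the same constraint. Simulated and estimated $\gamma$ are therefore
on the same (standardized) scale, and `latent_structure()` rejects
$\sum \gamma_k^2 \ge 1$.

**DIF.** Uniform DIF adds a direct covariate path into one item's intercept
($\beta_{dif}' x$: a difficulty shift; in mediation terms, the cause's
effect on the item is not fully mediated by the trait). Nonuniform DIF adds
a covariate moderation of the loading ($(\beta_{dis}' x)\,\theta$: a
discrimination shift). `fit_mimic_with_dif()` frees these terms for one item
at a time, which is the brute-force scan `scan_uniform()` /
`scan_nonuniform()` runs over an itemset.

## Estimation

The marginal likelihood integrates $\theta$ out of each respondent's
response pattern against the $N(\gamma' x_j,\ 1 - \sum\gamma_k^2)$ prior.
The integral is evaluated on a fixed Gauss-Hermite rule with base measure
$N(0,1)$ (61 nodes by default); the respondent-specific prior is handled by
reweighting the fixed rule with the density ratio
$\phi(\theta;\gamma'x_j,\sigma)/\phi(\theta;0,1)$, normalized per
respondent. Keeping one grid means all non-DIF item probabilities are
computed once per iteration on an items-by-nodes table and each likelihood
and score evaluation reduces to two matrix products — this is what makes the
Monte-Carlo study below (about two thousand model fits) run in minutes. The
refinement test in the suite verifies that 61 and 201 nodes agree to
$10^{-6}$ per observation and that $\hat\gamma$ moves by less than
$10^{-4}$ when the node count doubles.

The log-likelihood is maximized by L-BFGS-B on transformed parameters
(probit loadings via $\tanh$, $\gamma$ through a unit-ball map that encodes
$\sum\gamma_k^2 < 1$), with analytic score vectors; convergence is declared
on relative likelihood change ($10^{-8}$) and checked against the score
norm, and a failed or non-converged optimization is flagged in the result,
never raised as an error. Starting values come from item-total correlations
(loadings), inverse-link item means (thresholds) and an OLS of the z-scored
proportion correct on $x$ ($\gamma$). Degenerate items (all observed
responses identical) are dropped with a warning; all-0/all-1 respondents
are retained — the marginal likelihood handles them — and a respondent with
no observed responses is scored at the prior (EAP $= \gamma'x_j$, posterior
SD $= \sqrt{Var(\zeta)}$).

The observed information is a central-difference Jacobian of the analytic
score at the optimum. With repeated measures, `cluster_sandwich_cov()`
computes $A^{-1} B A^{-1}$ with $B$ the sum of outer products of
within-cluster score sums; duplicating every row of a dataset inside its
cluster leaves both the estimates and the sandwich standard errors
unchanged, which the suite asserts.

## The synthetic-data generator

Two generators define the study conditions.

**Population grid.** `build_condition_grid()` crosses sample size (200,
500), even- and odd-item indicator strength (0.4, 0.8), causal magnitude
(0.2, 0.4, 0.6) and the difficulty range ($[-1,1]$ or $[0,2]$): 48
population cells, 144 analysis cells once crossed with the three summary
methods. Each dataset has 20 items and one standard-normal cause. The
indicator-strength values are treated as 2PL *discriminations* and the grid
is simulated and fitted under the logit link: discriminations of 0.4/0.8
with a standardized trait reproduce the qualitative regime the study design
targets (weak items attenuate two-stage estimates by roughly a third at
strong causal magnitude), whereas reading the same numbers as standardized
probit loadings gives far milder attenuation. Difficulties are drawn
uniformly on the cell's range and never from harder ranges, where response
vectors collapse to all-zeros and fits fail.

**Emotional-identification fixture.** `simulate_empirical_fixture()`
emulates the repeated-measures EEG task shape: 61 subjects by default, 4
cycles, 4 emotions with 24 items each (23,424 potential trials), P200
amplitude and latency per subject and emotion from a bivariate normal
(correlation 0.3, z-scored; the modelling covariates are amplitude, latency
and their product, formed after z-scoring), a per-subject-per-emotion latent
trait shared across cycles (which is what makes subjects genuine clusters),
planted uniform/nonuniform DIF on configurable items, and planted data-quality
problems: missing trials (6% by default, matching roughly 22.5 of 24
responses observed), sub-150-ms responses (1%), and occasional multiple
keypresses. The default causal structure plants an amplitude effect on
neutral identification (0.25) and a negative amplitude-by-latency
interaction on discomfort (-0.25) — the two relationships the workflow is
designed to detect — with null effects elsewhere. What the fixture does
*not* emulate: real ERP waveform dynamics (the P200 extractor is exercised
on synthetic waveforms), item-content effects, learning across cycles, and
any demographic structure. Passing tests therefore certify the statistical
machinery, not the neuroscience.

## The Monte-Carlo bias study

`run_full_study()` simulates each population cell, summarizes every dataset
three ways — z-scored sum scores regressed on the cause, z-scored 2PL EAP
scores regressed on the cause, and the joint MIMIC estimate — and records
parameter bias, defined as true minus estimated (positive bias =
underestimation). Per-replication seeds are spawned from one root seed and
depend on the cell and replication but not on the method or the worker
count, so the three methods are compared on identical data and parallel runs
are bit-reproducible. `bias_anova()` fits the balanced five-factor ANOVA
(method, causal magnitude, indicator strength as the single four-level
even-by-odd factor, difficulty range, sample size) with all two- to
four-way interactions — 30 effect terms — and reports classical eta-squared
($SS_{term}/SS_{total}$, residual included in the total) with Cohen's
$f = \sqrt{\eta^2/(1-\eta^2)}$; in this balanced design Type I/II/III sums
of squares coincide, which the suite checks by permuting the factor order.
Causal magnitude is treated as categorical. Replications with failed fits
are dropped listwise with a reported count.

Problem sizes: the packaged acceptance script runs 50 replications per cell
(7,200 datasets, ~14,400 likelihood fits) and the test suite 30; both are
chosen so the full study completes in minutes on one core while leaving the
eta-squared estimates stable to within about $\pm 0.01$ across seeds. A
full 100-replication run is one `run_full_study(reps = 100)` (or the
`inst/scripts/run-bias-study.R` wrapper, which adds checkpointing).

## The empirical-style workflow

`run_empirical_pipeline()` chains preprocessing (keep the last response per
trial, recode sub-150-ms responses as missing — 150 ms exactly is retained,
exclude subjects missing more than half their potential responses), the
per-emotion brute-force DIF scans, purification (remove the union of
flagged items, single pass, no re-scan), and the three-method
brain-behavior comparison with BH-FDR across the four emotions within each
covariate. DIF flagging uses the raw per-item $p$ of the
amplitude-by-latency interaction term at $\alpha = 0.05$ (configurable to
any-covariate flagging); FDR correction is applied only at the
brain-behavior stage. The two-stage regressions deliberately use naive OLS
standard errors while the MIMIC fit uses subject-clustered sandwich errors —
preserving the contrast the workflow is meant to illustrate. The sign
convention for nonuniform DIF is that $\beta_{dis} > 0$ means
discrimination increases with the covariate.

## Numerical choices and limitations

* Quadrature: 61 fixed nodes by default; 21 suffice for the bias study's
  20-item logit models (verified against 61) and 31 are used inside the
  pipeline's smaller fits. Adaptive quadrature is out of scope.
* The P200 extractor takes the windowed argmax (180-250 ms), earliest
  sample on ties; it is a toy for fixture plumbing, not signal processing.
* One item per DIF fit: the scan frees DIF terms for a single item at a
  time. With few items and strong DIF, the unmodelled DIF leaks into the
  trait and can smear significance onto clean items; the purification step
  removes the union of flags, which is conservative in that regime.
* Weighted-least-squares (WLSMV-style) estimation, multidimensional traits
  and Bayesian estimation are not implemented; full-information ML is the
  package's single estimation route.
* Under a correctly specified joint model the MIMIC estimator is
  consistent, so at weak causal magnitude all three methods are nearly
  unbiased while at strong magnitude the two-stage methods fall behind —
  the method-by-cause interaction the bias ANOVA quantifies. How dominant
  the method main effect is depends on details of the generating
  parameterization (link, identification scale, summary standardization);
  the package fixes these choices as documented above and reports whatever
  the ANOVA then yields.
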