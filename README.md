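# mimicirt

Joint brain-behavior modelling for binary task data: the
multiple-indicator multiple-cause (MIMIC) model, differential item
functioning (DIF) scans against neurophysiological covariates, and a
Monte-Carlo study of the parameter bias that two-stage behavioral
summaries introduce.

## The problem

Cognitive-neuroscience studies usually summarize task behavior first — sum
scores or IRT ability estimates — and then regress the summary on a brain
measure (an ERP amplitude, a volume, ...). Both stages lose information:
measurement error in the summary attenuates the brain-behavior coefficient,
and items whose response process depends *directly* on the brain covariate
(DIF) contaminate the summary. The MIMIC model estimates the measurement
and structural parts as one system,

y\*ᵢ = λᵢ θ + εᵢ,  yᵢ = 1 ⇔ y\*ᵢ > τᵢ,  θ = γ′x + ζ,

with a standardized latent trait (Var(θ) = 1, Var(ζ) = 1 − Σγ²), probit or
logit items, full-information marginal maximum likelihood (fixed
Gauss-Hermite quadrature, analytic scores), and cluster-robust (sandwich)
standard errors for repeated-measures designs. Uniform DIF (a direct
covariate path into an item's intercept) and nonuniform DIF (a covariate
moderation of an item's loading) are tested item by item with Wald
statistics, and flagged items are removed before the brain-behavior
comparison.

For whom: anyone relating itemized binary task performance to continuous
subject-level covariates who wants the measurement model inside the
regression rather than in front of it.

## A worked example

```r
library(mimicirt)
set.seed(1)
bank <- item_bank(loading = rep(c(0.4, 0.8), 10), difficulty = runif(20, -1, 1))
pop  <- latent_structure(gamma = 0.5)          # Var(zeta) = 1 - 0.25
dat  <- simulate_mimic_dataset(bank, pop, n = 500)

fit <- fit_mimic(dat$y, dat$x, cluster = seq_len(500))
summary(fit)$gamma
#>     term  estimate   se_model se_sandwich        t            p
#> 1 gamma1 0.4429949 0.03708873  0.03566288 12.42174 1.991908e-35

z <- summarize_sumscore(dat$y)                 # the two-stage alternative
two_stage_estimate(z, dat$x[, 1])
#> [1] 0.4245817
```

The joint estimate (0.443 ± 0.036) sits closer to the generating γ = 0.5
than the z-scored sum-score regression (0.425), whose shortfall is the
attenuation the package's bias study quantifies. `fit_2pl()` fits the
no-cause 2PL with EAP scoring, `fit_mimic_with_dif()` frees one item's DIF
terms, `scan_uniform()` / `scan_nonuniform()` / `purify_itemset()` run the
itemset scans, and `run_empirical_pipeline()` chains preprocessing, DIF
scanning, purification and the three-method brain-behavior comparison on an
emotional-identification-shaped study (see `simulate_empirical_fixture()`).

The Monte-Carlo experiment crosses 48 population cells (sample size,
even/odd indicator strength, causal magnitude, difficulty range) with the
three summary methods and analyzes bias = γ − γ̂ with a balanced
five-factor ANOVA (all interactions to fourth order), reporting η² and
Cohen's f per term:

```r
tab <- run_full_study(reps = 50, root_seed = 1)   # ~3 min on one core
bias_anova(tab)
```

A vignette (`vignettes/mimic-models.Rmd`) documents the model, the
estimation details, the generator's defaults and the design decisions.

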