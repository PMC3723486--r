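---
title: "Modelling and power for GRS-by-activity interactions on BMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and power for GRS-by-activity interactions on BMI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxepower)
```

## The model

`gxepower` is built around one generating and fitting model. For
participant $i$ with genetic risk score $G_i$ (a count of BMI-raising
alleles over 12 loci, 0–24) and binary physical activity $E_i$
(1 = active),

$$\mathrm{BMI}_i = \beta_0 + \beta_G G_i + \beta_E E_i +
  \beta_{GE} G_i E_i + \gamma' z_i + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \sigma^2),$$

where $z_i$ collects the adjustment covariates (age, age$^2$, sex, study
center for multicenter cohorts). The target of inference is the
interaction coefficient $\beta_{GE}$, in kg/m$^2$ per allele per activity
unit: how much one unit of activity changes the per-allele genetic effect.
Assumptions worth keeping in view:

* additive allele effects — the score enters linearly, so each extra risk
  allele shifts BMI by the same amount;
* a single multiplicative interaction — activity rescales the genetic
  slope but does not otherwise reshape the BMI distribution;
* homoscedastic Gaussian residuals with SD $\sigma$ *given* the
  predictors. We treat $\sigma$ as the residual SD throughout. At these
  effect sizes the marginal and residual SDs of BMI differ by well under
  1%, so the distinction barely matters numerically, but the residual
  reading is the one under which the power calculations are exact.

The obesity variant of the model is a logistic regression of obese
(BMI $\ge$ 30) versus normal weight (18.5 $\le$ BMI $<$ 25) on the same
predictors; overweight and underweight participants are excluded from that
contrast so the odds ratio compares the two reference categories cleanly.

## Default parameters

The defaults of `cohort_spec()` and `power_scenario()` describe the
reference study conditions used across the package:

| parameter | default | units | origin |
|---|---|---|---|
| GRS mean | 11.2 | alleles | mean of the 12-locus score at the default allele frequencies, $\sum_j 2f_j$ |
| GRS variance | 5.06 | alleles$^2$ | binomial variance of the same score, $\sum_j 2f_j(1-f_j)$ |
| $p_{\text{inactive}}$ | 0.30 | — | typical prevalence of the "inactive" class in adult European-ancestry cohorts |
| $\beta_G$ | 0.154 | kg/m$^2$ per allele | reference marginal genetic effect |
| $\beta_E$ | −0.313 | kg/m$^2$, active vs inactive | reference marginal activity effect |
| $\beta_{GE}$ | −0.07 | kg/m$^2$ per allele per unit | reference interaction magnitude |
| $\sigma$ | 3.5 | kg/m$^2$ | residual BMI SD |
| $\alpha$ | 0.05 | — | two-sided Wald level |
| iterations | 1000 | — | Monte-Carlo replicates per power estimate |

A note on the GRS variance: a score summing 12 independent
Binomial(2, $f_j$) dosages has variance $\sum_j 2f_j(1-f_j)$, which equals
5.05 at the default frequencies — an SD of about 2.25, not the 2.2 that a
casually rounded SD would suggest. The variance scale is what the power of
the interaction test actually responds to (the noncentrality below is
linear in it), so the default is stated as a variance, 5.06, and the
direct-normal GRS simulator takes mean and variance rather than mean and
SD. The default intercept (25.5 kg/m$^2$) puts mean BMI near 26.5, typical
of middle-aged European-ancestry cohorts; it affects nothing but the BMI
location.

## The synthetic-data generator

`simulate_cohort()` draws, in order: the GRS (either $N(11.2, 5.06)$
directly, or — when allele frequencies are supplied — as a sum of
Hardy-Weinberg genotype dosages); the activity indicator; BMI from the
linear model; and demographic covariates (age, sex, height) that are
independent of everything else. Independent covariates are deliberate:
they let covariate-adjusted fits be validated against the unadjusted truth
without confounding entering the generator by accident.

**Correlated activity.** When a GRS–activity correlation $\rho$ is
requested, activity is thresholded from a latent Gaussian: with
$c = \Phi^{-1}(p_{\text{inactive}})$ and standardized GRS $z$, the
indicator is $E = \mathbf{1}\{a z + \sqrt{1-a^2}\,\eta > c\}$. For a
normal GRS, $\mathrm{cor}(G, E) = a\,\phi(c)/\sqrt{p(1-p)}$, so the latent
coefficient is set to $a = \rho \sqrt{p(1-p)}/\phi(c)$ and the realized
point-biserial correlation matches the request (the unit tests verify
±0.02 at $n = 2\times10^5$). The marginal inactive proportion is
$p_{\text{inactive}}$ exactly, in expectation, for any $\rho$.

**Multi-cohort runs.** `simulate_multi_cohort()` draws each cohort's
$\beta_{GE}$ from $N(\beta_{GE}, \tau^2)$ and generates cohort $i$ with
seed `master_seed + i` — a deterministic rule, so any single cohort can be
regenerated without rerunning the others.

**What the generator does not emulate.** Linkage disequilibrium between
the 12 loci (they are treated as independent score components);
questionnaire measurement error and the full occupational × leisure joint
distribution (the CPAI levels attached to simulated cohorts are a
consistent decoration, not a behavioural model); confounding between
activity and the covariates; population stratification. Passing tests
therefore show that the *procedures* are correct under the stated
statistical structure — they do not certify robustness to the biases real
cohort data carry.

## GRS construction rules

Dosages are oriented so that every column counts the BMI-raising allele;
columns reported on the other allele are flipped $d \mapsto 2 - d$, and
strand-ambiguous (A/T, C/G) loci are assumed reported on the map strand,
with a warning, since no strand check is possible for them. QC computes
per-locus call rate (threshold 0.95) and a 1-df chi-square Hardy-Weinberg
test on genotype counts, without continuity correction — at panel scale
the exact test buys nothing, and a plain chi-square against expected
proportions $((1-p)^2, 2p(1-p), p^2)$ is transparent. Failing loci are
flagged, never dropped silently: in a 12-SNP panel, removing a variant is
a sensitivity analysis, not a default.

Missing genotypes are imputed by expected dosage: a participant missing
locus $j$ receives $2\hat f_j$, the mean dosage among participants called
there. This keeps the score on the allele metric and preserves the cohort
mean under missingness completely at random (verified by simulation). The
alternative — rescaling the observed sum by $12/\text{observed}$ — was
rejected because it inflates the variance contribution of participants
with missing data. Participants missing more than four loci are excluded
rather than imputed; beyond a third of the panel, an expected-dosage score
is mostly imputation.

## The activity index

The Cambridge Physical Activity Index cross-tabulates a four-category
occupational rating with a four-category leisure-exercise frequency into
four total-activity levels. The exact published cell mapping is not
available, so the default crosswalk is
$\text{level} = \min(4, \text{occupational} + \text{leisure} - 1)$, which
satisfies every constraint the published index states — sedentary work
plus occasional exercise is "inactive", physically straining work is
"active" regardless of leisure, and the index is non-decreasing in both
inputs — and the crosswalk is an argument, so an exact institutional
mapping can be substituted. Missing leisure is assigned the lowest
category before lookup (a conservative rule: it can never raise the
index); missing occupational activity cannot be defaulted the same way,
so those records are flagged for analysis with the binary variable only.

The binary fallback classifies the bottom 20% of the activity
distribution as inactive. Ties at the 20th percentile all go to inactive,
keeping "bottom 20%" a lower bound; the realized fraction is recorded,
since with a four-level index heavy ties routinely push it above nominal.

## Power: analytic oracle and simulation

For independent predictors, the OLS estimator of $\beta_{GE}$ has
asymptotic variance $\sigma^2 / (n v)$ with
$v = \mathrm{Var}(G_{\text{eff}}) \, p(1-p)$, where $G_{\text{eff}}$ is
the continuous GRS (variance 5.06) or its mean-split indicator (variance
$0.5 \times 0.5 = 0.25$). The Wald noncentrality is
$\lambda = n \beta_{GE}^2 v / \sigma^2$ and

$$\text{power} = \Phi(\sqrt\lambda - z_{1-\alpha/2}) +
  \Phi(-\sqrt\lambda - z_{1-\alpha/2}).$$

`simulate_power()` is the Monte-Carlo counterpart: each iteration draws a
cohort, fits the four-term OLS model by a closed-form Cholesky solve, and
rejects when the interaction's two-sided Wald $z$ p-value falls below
$\alpha$. The Wald $z$ (rather than $t$) is used throughout; at the sample
sizes of interest ($n \ge 10^3$) the difference is far below Monte-Carlo
resolution. Singular draws (possible at tiny $n$, e.g. an all-active
sample) are redrawn and counted rather than scored as non-rejections.
The two routes agree within Monte-Carlo error across the unit-test grid,
and the simulated rejection rate under $\beta_{GE} = 0$ sits at $\alpha$.

`required_sample_size()` inverts the analytic curve by bisection
(`uniroot` to a quarter-participant, far below reporting resolution) when
$\rho = 0$, optionally confirming by simulation at the returned $n$; for
$\rho \ne 0$ it bisects on the simulated power curve to a 2% bracket.
Reported sizes are rounded to the nearest 1,000 — the convention for
sample-size statements at this magnitude — with the exact root retained.

Two consequences of the formula are worth spelling out. Dichotomizing the
GRS at its mean collapses its variance from 5.06 to 0.25, so the required
sample size grows by the factor $5.06/0.25 \approx 20.2$ — from roughly
18,500 to roughly 374,000 for $\beta_{GE} = -0.07$ at 80% power — which
is why the continuous score should never be split for interaction
testing. And because $v \propto p(1-p)$, the required size is minimized
at a balanced activity split and is symmetric in
$p \leftrightarrow 1 - p$.

**Correlated predictors.** Under the latent-Gaussian construction,
correlating activity with the GRS *cannot* raise the power of the
interaction test: thresholding on a latent correlated with $G$ shrinks
the within-group GRS variance, which inflates the interaction SE, leaving
power essentially flat for $|\rho| \le 0.2$ and visibly lower by
$\rho = 0.6$. Claims that predictor correlation helps interaction
detection depend on how the correlation is induced (e.g. group mean
shifts with conditional variance held fixed behave differently from a
copula with the marginal variance held fixed); since the closed form is
only valid at $\rho = 0$, `analytic_power()` refuses correlated scenarios
and directs the caller to the simulation, and the package documents the
copula behaviour rather than asserting a direction that its own
construction contradicts.

## Meta-analysis conventions

The primary pooling weights are cohort sizes: $w_i = n_i$, pooled
$\bar\beta = \sum w_i \beta_i / \sum w_i$ with SE
$\sqrt{\sum w_i^2 s_i^2} / \sum w_i$ — the exact variance of the weighted
sum under independence, used because size-weighted pooling has no
canonical SE formula the way inverse-variance pooling does.
Inverse-variance fixed-effect and DerSimonian-Laird random-effects
pooling are provided as sensitivity methods (cross-checked against
`metafor` in the tests). Cochran's $Q$ is always computed with
inverse-variance weights, even when the point estimate is size-weighted,
matching conventional heterogeneity reporting;
$I^2 = \max(0, (Q - \mathrm{df})/Q) \times 100$, truncated at zero so
homogeneous sets report 0% rather than negative percentages.

## Problem sizes in the test suite

The validation suite chooses sizes where the assertions have clean error
control: moment checks at $n = 10^5$–$2\times10^5$ with 3-standard-error
bands; parameter recovery at $n = 2\times10^5$; coverage of the pooled CI
over 2,000 simulated meta-analyses; type-I error of the interaction test
over 2,000 iterations; the reference power point at $n = 20{,}000$ with
1,000 iterations; and each required-$n$ result confirmed by 500-iteration
simulation at the returned size. Everything runs in a few minutes on one
core.

## Known limitations

* The score is unweighted; interaction-weighted refits (weighting alleles
  by their individual interaction estimates) need validation samples the
  framework does not model.
* Power is for the linear BMI outcome only; logistic (binary-outcome)
  interaction power and case-only designs are out of scope.
* The copula correlation mapping is exact for a normal GRS; for a
  genotype-built score it is accurate to the normal approximation of a
  12-locus binomial sum.
* Proxy-SNP lookup, LD-based imputation, and reference-panel genotype
  imputation are out of scope; proxies are taken as given in the risk
  allele map.
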