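# gxepower

Gene-by-physical-activity interaction analysis and power simulation for BMI.

## The problem

Large meta-analyses of obesity cohorts test whether physical activity
attenuates the aggregate effect of common obesity susceptibility variants on
body mass index. The standard design sums the BMI-raising alleles at 12
established loci (FTO, SH2B1, SEC16B, MTCH2, MC4R, NEGR1, TMEM18, GNPDA2,
BDNF, KCTD15, ETV5, FAIM2) into an unweighted genetic risk score
(GRS, 0–24 alleles), classifies participants as active or inactive from
questionnaire data, and fits, in each cohort,

```
BMI = b0 + bG·GRS + bE·activity + bGE·GRS·activity
      + age + age² + sex (+ center) + e
```

The per-cohort interaction coefficients `bGE` (kg/m² per allele per activity
unit) are then pooled across cohorts by sample-size-weighted meta-analysis.
Because interaction coefficients are small (on the order of −0.05 to −0.10
kg/m² per allele), the central design question is statistical power: how many
participants are needed to detect `bGE`, and how badly do dichotomized
predictors, unbalanced exposure groups, correlated predictors, or noisy BMI
measurement hurt?

`gxepower` implements that whole pipeline for methodologists and analysts
planning or replicating gene–environment interaction studies:

* **Synthetic cohorts** (`cohort_spec()`, `simulate_cohort()`,
  `simulate_multi_cohort()`): genotypes under Hardy-Weinberg proportions, a
  normal GRS, a binary activity exposure (optionally correlated with the GRS
  through a Gaussian copula), and BMI from the linear interaction model —
  so every stage is testable without individual-level cohort data.
* **GRS construction** (`align_risk_alleles()`, `qc_variants()`,
  `compute_grs()`, `dichotomize_grs()`): risk-allele orientation, call-rate
  and Hardy-Weinberg QC, expected-dosage imputation for participants missing
  up to four genotypes, exclusion beyond that.
* **Activity index** (`build_cpai()`, `dichotomize_activity()`): the
  Cambridge Physical Activity Index from occupational × leisure
  questionnaire categories, and the 80/20 binary fallback.
* **Interaction regression** (`fit_bmi_interaction()`,
  `fit_obesity_logistic()`, `stratified_effects()`, `lsmeans_by_group()`,
  `beta_to_weight()`): the linear BMI model, the obese-vs-normal-weight
  logistic model, per-stratum genetic effects, adjusted group means, and the
  gram-equivalent conversion `g = beta × height² × 1000`.
* **Meta-analysis** (`pool_estimates()`, `heterogeneity()`,
  `forest_export()`): sample-size weighting (primary), inverse-variance
  fixed and DerSimonian-Laird random effects, Cochran's Q, I², forest
  tables and plots.
* **Power engine** (`power_scenario()`, `analytic_power()`,
  `simulate_power()`, `required_sample_size()`, `scenario_sweep()`):
  Monte-Carlo power for the interaction Wald test plus a closed-form oracle
  via the noncentrality `lambda = n·bGE²·Var(G)·p(1−p)/sigma²`, and
  sample-size search with simulation confirmation.

## Worked example

Six cohorts generated under a shared interaction of −0.07 kg/m² per allele
(between-cohort SD 0.01), each fitted and pooled:

```r
library(gxepower)

specs <- lapply(c(4000, 9000, 2500, 6000, 12000, 3500),
                function(n) cohort_spec(n, beta_ge = -0.07))
cohorts <- simulate_multi_cohort(specs, between_sd = 0.01, master_seed = 42)
est <- do.call(rbind, Map(
  function(co, nm) cohort_estimate(fit_bmi_interaction(co), nm),
  cohorts, names(cohorts)))
pool_estimates(est)
#> Meta-analysis of 6 cohort estimates (sample-size-weighted)
#>   pooled beta = -0.06328 (SE 0.01766), 95% CI [-0.09791, -0.02866], p = 0.0003402
#>   heterogeneity: Q = 2.596 (df = 5), I2 = 0.0%, p = 0.762
```

The pooled interaction (−0.063 kg/m²) recovers the generating value within
one standard error, and the heterogeneity statistics behave as expected for
near-homogeneous cohorts (Q below its 5 degrees of freedom, so I² truncates
to 0).

Power at the reference design — N = 20,000, `bGE` = −0.07, GRS variance
5.06, 30% inactive, residual SD 3.5 kg/m²:

```r
analytic_power(power_scenario(n = 20000))
#> [1] 0.8303758
```

and the cost of dichotomizing the GRS at its mean (variance 5.06 → 0.25):

```r
required_sample_size(power_scenario(grs_binary = TRUE))
#> Required n for 80% power: 374,000 (exact 373755)
```

an ~20-fold sample-size penalty relative to the ~18,500 needed with the
continuous score, exactly the variance ratio 5.06/0.25.

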