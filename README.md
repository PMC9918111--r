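# phewasmr

Phenome-wide Mendelian randomization (MR) for a common binary exposure,
end to end: from a simulated biobank-style cohort, through a split-sample
GWAS, polygenic risk score (PRS) and phenome-wide association scan
(PheWAS), to one-sample and two-sample MR with the full sensitivity
battery.

The package is written for epidemiologists and statistical geneticists
who want to study — or teach, or stress-test — the PheWAS→MR design used
to screen a disease exposure (the motivating case is irritable bowel
syndrome, IBS, ~11.5% prevalence) against hundreds of ICD-derived disease
outcomes. Individual-level biobank data behind such studies are not
redistributable, so `phewasmr` includes a first-class synthetic-cohort
generator with the statistical structure the analysis assumes:
liability-threshold exposure with a polygenic component, shared
unobserved confounding, LD blocks, palindromic variants, questionnaire
ascertainment flags, and dated ICD-9/ICD-10 diagnosis records.

## The statistics inside

* **Phenotypes** — ICD-9→ICD-10 mapping, 3-character phecodes restricted
  to ICD-10 chapters I–XV and XVII with a strict >250-case filter;
  exposure ascertained by the union of four criteria with dated
  exclusions.
* **Genetics** — covariate-adjusted logistic GWAS; greedy LD clumping
  (instrument preset r² < 0.001 / 10,000 kb / p < 1e-5; PRS preset
  r² < 0.1 / 250 kb / p < 0.05); standardized PRS and tertile risk
  groups.
* **PheWAS** — logistic scan of every phecode on the scaled PRS, with
  Bonferroni control at α/K (0.05/665 = 7.52e-5 at the reference
  phenome size) and a PRS–confounder independence check.
* **MR** — Wald ratios; IVW (fixed and multiplicative random effects):
  β̂ = Σwⱼβ̂ⱼ/Σwⱼ, wⱼ = 1/se(β̂ⱼ)²; MR-Egger regression with intercept
  test; weighted median and weighted mode with bootstrap SEs; Cochran's
  Q; MR-PRESSO global/outlier/distortion; Steiger directionality;
  leave-one-out; pleiotropy pruning at p < 7.52e-5; harmonization with
  exclusion of palindromic variants at intermediate allele frequency
  (0.42–0.58); per-doubling odds ratios OR = exp(0.693·β); analytic MR
  power for binary outcomes.
* **Orchestration** — `run_pipeline()` executes the whole design with
  one master seed and a reproducible manifest; `run_stratified()`
  reruns it per stratum (e.g. sex); `run_reverse_mr()` swaps exposure
  and outcome roles.

## Worked example

Simulate a 20,000-participant cohort in which gastro-esophageal reflux
disease (ICD-10 K21) is causally downstream of the exposure
(log-OR 0.5 per unit exposure log-odds) and two other diagnoses are
null, then run the full pipeline:

```r
library(phewasmr)

cfg <- sim_config(
  n_participants = 20000, n_snps = 300, ld_block_size = 10, ld_rho = 0.6,
  n_causal_snps = 30, h2_liability = 0.2,
  outcome_specs = list(
    outcome_spec("gerd",        "K219", 0.10, causal_beta = 0.5),
    outcome_spec("asthma_null", "J459", 0.08),
    outcome_spec("htn_null",    "I109", 0.12)),
  seed = 42)

cohort <- simulate_cohort(cfg)
report <- run_pipeline(cohort, seed = 7)
report
#> PheWAS-MR report
#>   base/target: 9981/9981 (cases 1176/1100), 38 excluded
#>   instruments: 11; PRS variants: 43; phecodes tested: 3
#>   significant phecodes: K21
```

The planted outcome — and only it — survives the Bonferroni-controlled
PheWAS. Its MR work-up:

```r
mr <- report$mr[["K21"]]
mr$suite[, c("method", "n_snp", "beta", "se", "or_per_doubling",
             "or_ci_low", "or_ci_high", "p")]
#>            method n_snp  beta     se or_per_doubling or_ci_low or_ci_high        p
#> 1          ivw_fe    10 0.380 0.0325            1.30      1.25       1.36 1.25e-31
#> 2         ivw_mre    10 0.380 0.0528            1.30      1.21       1.40 5.60e-13
#> 3           egger    10 0.449 0.1710            1.36      1.08       1.72 3.04e-02
#> 4 weighted_median    10 0.399 0.0586            1.32      1.22       1.43 9.63e-12
#> 5   weighted_mode    10 0.381 0.0859            1.30      1.16       1.46 9.44e-06

mr$one_sample
#> two_stage: beta = 0.3491 (SE 0.0421), p = 1.18e-16
#>   OR per doubling of exposure odds: 1.274 (95% CI 1.203-1.349)

mr$sensitivity$steiger$direction_correct
#> [1] TRUE
```

Reading the numbers: doubling the odds of the exposure raises the odds
of the planted outcome by ~30% (per-doubling OR 1.30, IVW), with the
one-sample two-stage estimate (1.27) and every robust estimator telling
the same story, and Steiger confirming the assumed causal direction.
Estimates sit somewhat below the planted conditional effect
(per-doubling OR ≈ 1.41) because odds ratios are non-collapsible and
in-sample instrument selection adds winner's-curse attenuation — see the
methods vignette (`vignettes/phewas-mr-methods.Rmd`), which discusses
the marginal estimand the truth record carries as `beta_marginal`.

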