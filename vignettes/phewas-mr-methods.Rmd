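---
title: "Methods: phenome-wide Mendelian randomization with phewasmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenome-wide Mendelian randomization with phewasmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phewasmr)
```

## The design

`phewasmr` implements a hypothesis-free scan for downstream consequences of
a common binary exposure (the motivating application is irritable bowel
syndrome, IBS, with ~11.5% prevalence in a mid-life cohort), followed by
causal triangulation with Mendelian randomization (MR):

1. **Split-sample GWAS.** The cohort is randomly halved. An exposure GWAS
   is run in the *base* half only, so that polygenic-score weights and the
   sample they are applied to never overlap (overlap inflates type-1
   error of PRS associations).
2. **PRS.** Base-half summary statistics are LD-clumped and summed into a
   polygenic risk score in the *target* half, standardized to unit SD.
3. **PheWAS.** Every 3-character ICD-10 phecode with more than 250 cases
   (chapters I–XV and XVII only) is regressed on the scaled PRS with
   adjustment for age, sex, assessment center and 10 genetic principal
   components, under Bonferroni control at 0.05/K.
4. **MR.** Each phenome-wide significant phecode is taken to one-sample
   (two-stage) MR on individual-level data and to the two-sample
   summary-statistics suite: IVW, MR-Egger, weighted median/mode,
   Cochran's Q, MR-PRESSO, Steiger directionality, leave-one-out, and
   manual pruning of instruments associated with secondary traits.

Everything runs on synthetic cohorts produced by the package's own
generator, so the whole design is testable without access to restricted
individual-level biobank data.

## The generative model

The exposure follows a liability-threshold model. Participant $i$ has
liability

$$L_i = \sum_k b_k g_{ik} + c\,U_i + \varepsilon_i,$$

with dosages $g_{ik} \in \{0,1,2\}$, polygenic effects $b_k$ scaled so the
genetic component has variance $h^2$ (default 0.2), a standard-normal
unobserved confounder $U$, and $\varepsilon$ normal with variance
$1-h^2-c^2$, so $\mathrm{Var}(L)=1$. Exposure is $L_i > \tau$ with
$\tau = \Phi^{-1}(1-K)$ for target prevalence $K$ (default 0.115). LD
blocks are generated by a copy mechanism on haplotypes: each block member
copies the block's lead allele with probability $\rho$, giving pairwise
haplotype correlations of $\rho$ (lead–member) and $\rho^2$
(member–member) without requiring a real LD map. Palindromic A/T and C/G
variants are planted, a configurable fraction of them with allele
frequency drawn from the 0.42–0.58 band, to exercise the harmonization
filter.

Outcomes are Bernoulli with

$$\mathrm{logit}\,P(Y_i = 1) = a + \beta\,\Lambda_i + d\,U_i +
  \textstyle\sum_j \alpha_j (g_{ij} - 2p_j),$$

where $\Lambda_i = 1.702\,(L_i - \tau)$ is the liability re-expressed on
an (approximate) exposure log-odds scale via the probit-to-logit constant
1.702. This makes $\beta$ directly interpretable as a log-OR per unit
increase in the log odds of exposure, so the conventional per-doubling
rescaling $\mathrm{OR} = e^{0.693\beta}$ applies to the planted value.
The intercept $a$ is solved numerically so the outcome hits its target
prevalence; unsolvable (saturating) configurations are reported as errors
naming the outcome. The $\alpha_j$ terms are direct (horizontally
pleiotropic) variant effects used to plant balanced, directional, or
single-outlier pleiotropy.

### What the planted effect does and does not pin down

Odds ratios are non-collapsible: the *marginal* variant–outcome log-OR
that a logistic GWAS estimates is attenuated relative to the conditional
$\beta$ by the unmodeled variance on the logit scale, and in-sample
instrument selection adds winner's-curse attenuation of Wald ratios. MR
on these cohorts therefore targets a marginal estimand somewhat smaller
than the conditional $\beta$. The generator records this estimand in the
truth record as `beta_marginal`, computed at generation time by a
collapsed quasibinomial fit of the true outcome probabilities on
$\Lambda$. Tests assert (i) exact null behaviour when $\beta = 0$ —
non-collapsibility vanishes under the null — and (ii) recovery near
`beta_marginal`, or confidence intervals excluding 1, for planted
effects; they do not assert recovery of the conditional $\beta$, which no
odds-ratio-based method identifies. The same caveat applies to published
biobank analyses of this design; it is a property of the estimand, not a
bug in the estimator.

### What the generator does not emulate

Realistic human LD maps and allele-frequency spectra, relatedness and
population stratification (the PCs supplied are pure noise covariates),
imputation uncertainty, X-chromosome dosages, and diagnosis-code
misclassification. Passing tests therefore demonstrate the statistical
machinery is correct under the stated model, not that any particular
biological conclusion transfers to real data.

## Phenotype construction

Diagnosis records are normalized (dots stripped, upper-cased), ICD-9
records converted through a user-supplied two-column general-equivalence
mapping (a small synthetic mapping ships with the package; unmapped codes
are counted and dropped), truncated to their first three characters, and
restricted to ICD-10 chapters I–XV and XVII (letters A–O and Q), which
removes perinatal conditions, unclassified symptoms/signs, injuries and
poisoning. The `> 250` case filter is strict, per its source's wording.
Exposure cases are the union of four criteria (symptom questionnaire,
digestive-health questionnaire, self-report, clinical ICD-10 code);
carriers of confounding conditions (e.g. inflammatory bowel disease)
dated on or before the earliest exposure diagnosis are excluded, and
carriers without any dated exposure diagnosis are excluded conservatively
— the source design states "before diagnosis" without a tie rule, so ties
exclude.

## Estimators and numerical choices

* **GWAS** is covariate-adjusted logistic regression via IRLS (epsilon
  1e-8, max 100 iterations) with a warm start from the covariate-only
  null fit; Wald tests. Monomorphic and non-converged (separated)
  variants are flagged records, not errors. A mixed model is unnecessary
  because simulated cohorts are unrelated by construction.
* **Clumping** is greedy by ascending p (ties: smaller SE, then id) using
  in-sample dosage correlations; the instrument preset is r² < 0.001
  within 10,000 kb at p < 1e-5, the PRS preset r² < 0.1 within 250 kb at
  p < 0.05. The two presets are separate because the motivating study
  specifies only the instrument-selection parameters; PRS
  clumping-and-thresholding settings are conventional defaults and fully
  configurable.
* **Harmonization** aligns outcome effects to the exposure effect allele
  (swap ⇒ sign flip + EAF complement; strand flips recognized by
  complement). Palindromic variants with exposure EAF in [0.42, 0.58]
  (inclusive) are excluded; outside the band they are aligned by
  frequency. A `strict_eaf_exclusion` switch applies the band to all
  variants, implementing the literal reading of the source text; the
  default restricts it to palindromic variants, the conventional
  behaviour.
* **IVW** meta-analyzes Wald ratios with first-order weights; the
  multiplicative random-effects SE inflates by max(1, √(Q/(m−1))).
  `mode = "auto"` switches to random effects when Q's p < 0.05; reports
  include both.
* **MR-Egger** re-orients instruments so all exposure effects are
  positive (the estimate is not orientation-invariant), then weighted
  least squares with a free intercept; t-tests with m−2 df.
* **Weighted median** interpolates the 50% point of the cumulative
  inverse-variance weights; **weighted mode** maximizes a weighted
  normal-kernel density whose bandwidth is a weighted Silverman analogue
  times a user factor (the bandwidth → ∞ limit recovers the weighted
  mean; a degenerate zero-spread ratio set returns the common value).
  Both use seeded parametric bootstrap SEs (default 1000 draws).
* **MR-PRESSO** follows the residual-sum-of-squares construction with
  leave-one-out predictions, a parametric simulated null (+1-corrected
  empirical p), per-instrument two-sided outlier tests Bonferroni-scaled
  by m, and a distortion test against random same-size subset removals.
  Note the smallest attainable adjusted outlier p is m/(n_sim+1), so
  n_sim must exceed roughly 20·m for detection at the 0.05 level;
  defaults satisfy this.
* **Steiger** uses the binary-trait approximation r² = Z²/(Z²+n) per
  instrument and a Fisher-z test on the implied correlations; the
  variance-explained approximation for binary–binary trait pairs is a
  documented choice.
* **One-sample MR** is two-stage predictor substitution on the log-odds
  scale: logistic stage 1 (exposure ~ PRS + covariates), stage-2 logistic
  of the outcome on the stage-1 linear predictor. The stage-2 coefficient
  is a log-OR per unit genetically predicted exposure log-odds, so the
  ×0.693 per-doubling scaling applies. Wald SEs by default (no
  generated-regressor correction, matching common practice); a seeded
  nonparametric bootstrap is available.
* **Per-doubling scaling** uses the literal constant 0.693 by default so
  reported ORs match published practice to the printed digits;
  `exact_ln2 = TRUE` switches to full-precision ln 2.
* **Power** uses the standard non-centrality approximation for binary
  outcomes, `power = Φ(μ − z) + Φ(−μ − z)` with
  `μ = |log OR|·√(n·r²·f(1−f))`; it returns exactly α at OR = 1 and is
  validated against a Monte-Carlo rejection-rate oracle in the tests.

## Problem sizes

Default analyses in the examples, tests and acceptance script use cohorts
of 3,000–20,000 participants with 100–400 variants, 500 replicates for
estimator calibration, 200 for robustness comparisons, 100 for outlier
detection and directionality rates, and 10 end-to-end pipeline
replicates at n = 20,000 with one planted causal outcome among 20 null
phecodes. These sizes give binomial Monte-Carlo error comfortably inside
the asserted bands while keeping a full run on a single CPU to a few
minutes; all replicate streams are seeded from one master seed via
deterministic child seeds.

## Known limitations

Correlated-instrument (LD-aware) MR, multivariable MR and colocalization
are out of scope. The one-sample SEs ignore the generated-regressor term
unless bootstrapped. Cohort-level estimator tests are anchored to the
marginal estimand (see above), not the conditional liability-scale
effect. The synthetic ICD-9 mapping is a toy table, not a real
general-equivalence mapping.
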