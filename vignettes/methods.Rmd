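---
title: "Models and methods behind irongc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind irongc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models, their assumptions, the tunable parameters with their defaults
and units, the numerical choices, and what the synthetic-data tests do and
do not establish.

## 1. The analysis chain

Seven iron-status biomarkers (hepcidin, ferritin, hepcidin/ferritin,
hepcidin/TS, serum iron, TIBC, transferrin saturation) measured on the full
genotyped sample and four non-invasive measurements of atherosclerosis
(plaque presence, IMT, ABI at rest, ABI after exercise) measured on a
subset are related through three arms: single- and multi-SNP Mendelian
randomization, cross-trait association of outcome SNPs with biomarkers, and
genomic correlation (bivariate GREML and a Bayesian multi-trait model), all
downstream of a shared preprocessing chain.

### Preprocessing (`prepare_trait`, `qc_filter_snps`, `ld_prune`)

* Genotype QC keeps SNPs with folded MAF ≥ 1% and a Hardy–Weinberg
  equilibrium p-value above 1e-6. The HWE test is the 1-df goodness-of-fit
  chi-square on hard calls (soft dosages rounded for the test only); we use
  the chi-square rather than the exact test because only a p-value
  threshold is specified and chip-QC practice uses the chi-square at these
  sample sizes.
* LD pruning slides a window of 100 SNPs advanced by 5 and removes the
  later member of any pair with r² > 0.98, repeating passes until stable.
  Keeping the *first* SNP of a violating pair makes the output
  deterministic where an upstream tool relies on an internal default.
* Trait preparation: natural-log transform for hepcidin, ferritin and the
  two hepcidin ratios (the base is irrelevant after standardization);
  within each sex stratum, OLS residuals on age, age², and — for the
  biomarkers only — two time-of-sampling dummies against the
  before-noon reference; then either outlier *exclusion* (|z| > 4, used by
  the SNP-association arm) or *winsorization* (clamp at mean ± 4 SD, used
  by the genomic-correlation arm); finally standardization to zero mean,
  unit variance within stratum. Whether outcome-trait residualization
  should also include time of sampling is exposed as a flag
  (`use_time`) rather than guessed; the default follows the biomarker/
  outcome split above. Missing covariates drop a sample from that trait's
  residualization only.
* Binary plaque enters all variance-component analyses as its standardized
  0/1 residual (observed scale); no liability-scale transformation is
  applied anywhere downstream.

### Mendelian randomization (`run_mr_suite`)

Dosages are probability-weighted allele counts
(`0·P_AA + 1·P_AB + 2·P_BB`, allele B counted). Five of the twelve
instrument SNPs are flipped (`2 − dosage`) so that every counted allele is
hypothesized risk-increasing; the eight SNPs with a known hypothesized
direction form the multi-SNP score (range 0–16), and quartiles of the score
are compared Q2/Q3/Q4 against Q1. Quartile boundaries use the
linear-interpolation (type-7) 25/50/75 percentiles with ties assigned to
the lower quartile — deterministic where the source is silent. Whether the
boundaries are computed on the full genotyped sample or the outcome subset
is an exposed option (`quartiles_on`, default full sample).

Models are OLS (IMT, ABI, biomarker residuals) and maximum-likelihood
logistic regression (plaque; IRLS, log-likelihood tolerance 1e-8, max 100
iterations, separation flagged when a |log-OR| exceeds 15 rather than
reported as a finite estimate). Effects carry Wald 95% CIs (±1.96 SE).
Linear-model p-values use the exact t reference with residual degrees of
freedom — the finite-sample-correct choice, and what keeps the type-I
error calibration test exact; logistic p-values are normal Wald. No
multiple-testing correction is applied: the design is explicitly
explorative and p < 0.05 is labelled nominal. Direction consistency is
scored on point-estimate signs with strict inequalities (a beta of exactly
0 is inconsistent); significance plays no role, and unknown-direction SNPs
are reported but never scored.

### GRM and relatedness (`compute_grm`, `filter_relatedness`)

The GRM is the standardized cross-product
`A_jk = (1/m) Σ_i (x_ij − 2p_i)(x_ik − 2p_i) / (2p_i(1−p_i))` with sample
allele frequencies; missing dosages are mean-imputed per SNP (zero
contribution after centering). Cryptic relatedness is removed by
iteratively dropping the individual with the most pairwise relationships
≥ 0.025 (ties: lowest index) until no pair remains — the acceptance
property ("no retained pair ≥ cutoff") is order-independent even though
the greedy order is fixed for determinism. Note the 0.025 default presumes
a genome-wide SNP panel: the null GRM entry noise is ~1/√m, so desk-scale
simulations (m in the hundreds) must either raise the cutoff or be read as
filtering noise; the tests use explicit sib pairs and a cutoff matched to
m.

### Bivariate GREML (`fit_bivariate_greml`)

The model is `y = Xb + g + e`, `cov(g) = G0 ⊗ A`, `cov(e) = R0 ⊗ I` on
overlapping samples, with per-trait intercepts as the only fixed effects
(traits are pre-residualized). With complete overlap the restricted
likelihood decouples in the GRM eigenbasis into independent 2×2 problems
per eigen-coordinate (variance `d_k·G0 + R0`), giving an O(n) likelihood,
gradient and average-information matrix; with partial overlap (the
outcome-subset design) a dense stacked-covariance path is used, treating
the off-overlap residual covariance as structurally zero. The two paths
agree to 1e-6 on shared fixtures, which is tested.

Optimization is AI-REML with safeguards: AI proposals are ridge-stabilized,
norm-capped, and step-halved; when no AI step improves the likelihood an
EM-style fallback is taken, `θ_i ← θ_i + 2 s_i ∂ℓ/∂θ_i / n`, with the EM
scale `s_i = θ_i²` for variances and `θ_i θ_j + θ_ij²` for covariances (the
covariance scale is what allows a zero-initialized covariance to move — a
necessity discovered on the degenerate identical-trait fixture, where the
optimum sits exactly on the rG = 1 boundary). Convergence requires a
log-likelihood change below 1e-6 and a relative parameter change below
1e-4, within 200 iterations. Variances are clamped at 1e-8; the genetic
covariance is projected so G0 stays PSD, hence rG is always reported in
[−1, 1] and lands exactly on ±1 at the boundary, with `status = boundary`.
Standard errors come from the inverse AI matrix and the rG SE by the delta
method; at a boundary these are reported as-is but should be read as
unreliable (the small-sample report summarizes the boundary-pile-up
behaviour expected at a few hundred samples). Initialization: variances at
half the phenotypic variance, covariances at 0.

### Bayesian multi-trait model (`run_gibbs`, `run_model_suite`)

Traits are regressed on `Z = U·diag(√d)` (so `ZZ' = A`); the genetic side
carries `L_g` latent factors plus trait-specific effects, giving
`G0 = Λ_g diag(σ²_f) Λ_g' + diag(ψ_g)` — PSD by construction, so every
per-sweep rG is in [−1, 1]. The residual side mirrors this with its own
`L_e` factors (an unstructured residual covariance was the alternative; the
latent-factor form matches the genetic side, scales to 8 traits, and its
factor count can be scanned with the same DIC machinery). Because the
sampler works in the GRM eigenbasis, every full conditional is diagonal and
a sweep costs O(n(T + L)).

Priors: uniform(0, 10) on all variances (vacuous for standardized traits;
sampled exactly by inverse-CDF from the truncated conjugate conditional),
N(0, 1) on free loadings, lower-triangular loadings with non-negative
diagonals (half-normal conditional draws) for identifiability. The residual
scale/loading split retains a benign scale non-identifiability; rG and all
reported covariances are identified functions. Chain defaults are 30,000
sweeps, 10,000 burn-in, thinning 20; tests run far shorter chains and check
effective sample sizes instead. A seed is required and matched seeds give
bit-identical chains.

Missing trait values (the outcome-subset design) are imputed by data
augmentation each sweep from their residual conditional. DIC uses the
*marginal* deviance given (G0, R0) when traits are complete — evaluated in
O(nT²) by simultaneous diagonalization — because the conditional-on-latents
deviance lets a superfluous factor absorb noise through the full-rank
eigenvector regression and systematically prefers larger L; with missing
data the conditional deviance is used and DIC comparisons should be made
within a common missingness pattern. `p_D = D̄ − D(θ̄)` is reported
alongside.

The four-model suite guards the roster invariant (a ratio trait never
co-occurs with both of its components) and merges posteriors into the
7-biomarker × 4-outcome rG report, sourcing hepcidin/ferritin/iron/TIBC
rows from the 8-trait model and the ratio and TS rows from the dedicated
smaller models.

## 2. The synthetic cohort

`simulation_config()` states the world once: 1,819 samples (ages uniform
42–76, even sex split, sampling-time split 21/64/15%), an outcome subset of
549 (plaque prevalence 42% via thresholding the standardized liability at
the 58th percentile), SNPs with MAF uniform on a configured range under
HWE, optional sibling pairs built from explicit parental gametes (so the
expected sib relationship of 0.5 is a consequence, not an input), per-SNP
effects drawn jointly across traits from N(0, genetic_cov / n_causal) on
the standardized-genotype scale (so target h² and rG hold in expectation
regardless of the MAF spectrum, matching the GRM standardization), Gaussian
residuals with the configured residual covariance, and additive fixed
allelic effects on the dosage scale.

Defaults that the source left open, chosen once: heritability 0.3 per trait
(mid-range for serum iron markers), zero genetic correlation between the
biomarker and outcome blocks in `nbs_like_config()` (the null the study
largely found), covariate effects age 0.02 SD/year, sex 0.5 SD, sampling
time (0.15, 0.3) SD — nonzero so residualization is consequential in tests
— and a lipid panel (TC/LDL/HDL/TGC, mmol/L) with mild age/sex structure
and no genetic component, sufficient for exercising lipid adjustment.
Simulated traits are generated directly on their analysis (post-log) scale;
tests exercising the log-transform exponentiate first.

What the generator does *not* emulate: linkage disequilibrium beyond
duplicated-column blocks (enough to test pruning, not a coalescent),
population stratification, assay error structure, or the real cohort's
missingness patterns. A green recovery test therefore establishes that the
estimators are correct under their own assumptions at the stated sizes — it
cannot certify the source study's numerical estimates, whose underlying
data are not deposited; that is also why the acceptance surface is
property-based (oracle equivalence, calibration, recovery of known truth,
boundary behaviour, estimator agreement) rather than value reproduction.

## 3. Numerical choices and degenerate inputs

* Dosage triples must sum to 1 within 1e-6; negative components are errors.
* `assign_quartiles` refuses constant scores and fewer than 8 values.
* GRM computation refuses monomorphic SNPs (QC removes them first).
* Eigenvalues in [−1e-8, 0) are clipped to zero with a count; anything more
  negative on a supposedly-PSD matrix errors.
* An identity-like GRM (no eigenvalue spread) makes the variance components
  unidentifiable; the univariate fitter detects this and reports `failed`.
* The GCTA binary GRM writer stores float32; round trips are exact to 1e-6.
* All stochastic functions take an explicit integer seed; there is no
  hidden global-RNG dependence across calls (genotypes and phenotypes use
  seed and seed + 1 so the two draws are independent streams).
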