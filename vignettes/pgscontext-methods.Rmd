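---
title: "Context-dependent polygenic score performance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent polygenic score performance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A polygenic score (PGS) summarizes the genetic liability of a trait as a
weighted sum of allele counts, with weights estimated in a genome-wide
association study (GWAS). For adiposity-like traits, both the
*performance* of the score (the share of phenotypic variance it explains,
incremental R^2^) and its *effect size* vary systematically with personal
and environmental context: age, sex, blood lipids, physical activity,
alcohol intake. `pgscontext` implements the full analysis cycle for
studying such context dependence — a seed-controlled synthetic cohort
generator, per-SNP association scans, pruning-and-thresholding (P+T)
score construction including age-aware scores, covariate-stratified
performance with bootstrap uncertainty, interaction models with a
shared-heritability correction, quantile-regression effect profiles, and
a cross-validated comparison of penalized linear models against small
neural networks.

All analyses run on synthetic cohorts produced by the package's own
generator (real biobank data are access-restricted), or on user-supplied
TSV genotype/phenotype tables and PLINK-style score files.

# The synthetic cohort generator

`sim_config()` + `simulate_genotypes()` / `simulate_effects()` /
`simulate_cohort()` produce a biobank-style cohort on a **unit phenotype
variance budget**. The generative phenotype (log-scale, log(BMI)-like,
intercept 3.3) is

$$y_i = \mu + g_i\,(1 + \gamma\, \tilde g_i) + \Big(\sum_n \beta^{GxAge}_n
k_{in}\Big)(\mathrm{age}_i - \overline{\mathrm{age}}) + \beta_s\,
\mathrm{sex}_i + \sum_c \big(\alpha_c C_{ic} + \eta_c C_{ic}\tilde g_i\big)
+ \varepsilon_i\,(1 + \theta \tilde g_i),$$

where $g_i = \sum_n \beta_n k_{in}$ is the true genetic score over allele
counts $k \in \{0,1,2\}$, $\tilde g$ its z-score, and $\varepsilon$
normal noise sized so the total variance hits 1.

Parameters that matter, with units and defaults:

* `h2_main` (variance fraction, default 0.3) — main effects are drawn iid
  normal and rescaled so $\sum_n 2f_n(1-f_n)\beta_n^2 =$ `h2_main`.
* `maf_range` (allele frequencies, default 0.05–0.5) — per-SNP
  frequencies are uniform on this range; genotypes are two Bernoulli
  draws (Hardy–Weinberg, linkage equilibrium by default; an
  equicorrelated-block mode exists solely to exercise clumping).
* `gxage_fraction`, `gxage_scale` — a random fraction of SNPs receives an
  age-interaction effect. `gxage_scale` is *scale-free*: the per-year
  effect SD is `gxage_scale * sd(beta) / sd(age)`, i.e. the knob states
  the interaction magnitude relative to the main effect per SD of age.
  (Stated per raw year, a value like 0.5 would swamp the variance budget;
  the per-age-SD convention keeps the budget arithmetic meaningful at
  every scale.) Age enters the generative model centered so `h2_main` is
  age-invariant; the deployed scoring formula uses raw age and the age
  coding is recorded in score metadata.
* `covariate_specs` — each covariate mixes the trait's standardized
  genetic score (fraction `genetic_overlap` of its variance) with
  environmental noise; binary covariates threshold the latent at the
  prevalence quantile. `main_effect` is phenotype units per covariate SD;
  `pgs_interaction` (units per SD x SD) multiplies the covariate with the
  standardized genetic score.
* `genetic_scale` ($\gamma$, default 0) — convexity of the genetic
  effect: the marginal effect of the score grows with the score itself.
  This emulates the well-replicated feature of adiposity traits that
  genetic effects are larger at higher trait values; it is also exactly
  the mechanism by which interaction tests against genetically
  overlapping covariates inflate (see below). Order 0.01 is a mild,
  realistic gradient.
* `noise_gradient` ($\theta$, default 0) — multiplicative noise: the
  residual SD scales with the genetic value, giving the conditional
  quantile slope the closed form $\beta(\tau) = b + z_\tau \sigma_e
  \theta$, used as an oracle in the tests.

What the generator does **not** emulate: realistic LD from a reference
panel, population-structure confounding of the PCs, relatedness, and
assortment. Passing tests therefore demonstrate the statistical machinery
under clean sampling assumptions, not robustness to real-cohort
confounding.

# Association scans and score construction

`run_gwas()` fits one OLS per SNP with Age, Sex and five PCs as
covariates, optionally rank-normalizing the phenotype first (Blom offset
3/8 — the common biobank convention; the package exposes the offset).
Computation residualizes the phenotype and the SNP columns on the shared
covariates (Frisch–Waugh), which is exact OLS with correct degrees of
freedom and vectorizes across SNPs. The `gxage` design adds a
SNP-by-age product column and solves the per-SNP 2x2 normal equations in
closed form; monomorphic SNPs and SNP-age columns collinear with the SNP
(all ages equal) are flagged, never dropped. `run_stratified_gwas()`
splits on age quartiles (half-open boundaries, ties to the lower
stratum) and rank-normalizes within stratum.

`clump()` is greedy P+T pruning: SNPs in ascending main-effect p order,
discarding candidates whose squared genotype correlation with a kept SNP
exceeds `r2_cutoff` (default 0.1; no positional window — synthetic SNPs
carry no coordinates). `build_score()` applies a p threshold from the
ten-value ladder `pt_thresholds()`; `score_individuals()` computes
$\sum_n \beta_n k_n$ or, for age-aware models, $\sum_n (\beta_n k_n +
\beta^{GxAge}_n k_n \mathrm{Age}_i)$. Missing model SNPs are a hard
error — synthetic data are complete and scoring stays exact. For the
age-aware design, SNP selection and clumping use the *main-design*
p-values while both weight sets come from the interaction scan; selecting
on interaction p-values is available behind a flag but off by default.
`tune_threshold()` picks the candidate with the best training incremental
R^2^, breaking ties toward the more inclusive threshold. Raw P+T sums are
evaluated inside incremental-R^2^ regressions, which absorb scale; no
weight recalibration on the training split is performed.

# Stratified performance

`incremental_r2()` is the difference in R^2^ between
`phenotype ~ PGS + Age + Sex + PCs` and the covariate-only model on the
same rows. `bootstrap_r2()` resamples individuals within stratum
(both models see the same resample) and reports the bootstrap SD;
strata below 30 individuals are reported without p-values.
`r2_diff_pvalue()` compares two strata as a two-sided normal z-test on
the difference using the bootstrap SDs; the literal overlapping
coefficient of the two normal densities is available as `mode = "ovl"`
since a descriptive overlap is sometimes preferred — the z-test is
primary because it yields a calibrated p-value. The driver computes the
full pairwise matrix, leaving the choice of contrasts to the caller, and
applies Bonferroni at 0.05 divided by the number of covariates tested.
`weighted_r2_trend()` regresses stratum R^2^ on stratum mean covariate
value, weighted by stratum size, and exposes prediction at arbitrary
covariate values. `slope_r2_demo()` tabulates the identity
$R^2 = b^2\sigma^2_x / (b^2\sigma^2_x + \sigma^2_e)$ against simulation:
R^2^ grows with the slope magnitude at a fixed mean squared residual,
which is why strata with larger PGS effects show larger R^2^ *and*
possibly larger error — R^2^ alone is an incomplete performance metric.

# Interaction models and the shared-heritability correction

`fit_interaction()` fits

```
phenotype ~ PGS*Covariate + PGS + Covariate + PGS_cov + PGS*PGS_cov
            + Age + Sex + PCs
```

where `PGS_cov` is a polygenic score for the covariate itself, built by
the same GWAS + P+T machinery from the simulated covariate genetics.
Continuous covariates and scores are standardized first
(`standardize()`, population-SD convention, full-analysis-sample moments
— per-stratum moments would make units incomparable across covariates;
binary covariates pass through). Reported: the interaction beta with its
p-value, the percent change in PGS effect per covariate unit
(`100 * beta_int / beta_PGS`, using the interaction model's own main
effect — the natural within-model contrast), and the R^2^ gain over the
same model without the product term (equal to the squared semi-partial
correlation of that column).

Why a correction is needed at all: when the trait's genetic effect is
convex (`genetic_scale > 0`), the product of the trait PGS with any
covariate that shares genetics with the trait partially proxies
$\tilde g^2$, so the uncorrected interaction test rejects a true null.
Under a purely linear Gaussian generative model no such inflation exists
(third cross-moments vanish), which is why the calibration analyses in
the test suite switch the convexity on. The two `PGS_cov` terms absorb
the genetically driven curvature and pull the type-I rate back to
nominal.

`fit_main_effect()` fits fresh main-effect-only models (main effects
inside interaction models depend on centering), and
`weighted_pearson()` / `effect_correlation_summary()` compute
sample-size-weighted correlations among main effects, interaction
effects, and the max-minus-min stratum R^2^ per covariate (continuous
covariates only), with significance via the effective sample size
$(\sum w)^2 / \sum w^2$.

# Quantile-regression profiles

No quantile-regression backend ships in the package's dependency set, so
the estimator is authored here: `fit_quantile()` minimizes the check
loss $\sum_i \rho_\tau(y_i - x_i^\top b)$ through a smoothed surrogate
$\rho_{\tau,\gamma}(u) = \tau u + \gamma \log(1+e^{-u/\gamma})$ with an
asymmetric-reweighting (IRLS) warm start, a data-driven first bandwidth
($((p + \log n)/n)^{0.4}$ times the response SD, the
convolution-smoothing rate), and a small-bandwidth BFGS polish. The
tests verify the fit against a brute-force enumeration oracle at tiny n
(the optimum passes through p data points), against closed-form
conditional quantiles, and against the OLS objective bound. Confidence
intervals are bootstrap percentile (default 500 replicates, method
stamped in the output) — chosen over asymptotic sandwich forms for
small-stratum robustness. `decile_profile()` fits taus 0.1–0.9 with Age,
Sex and PC covariates; integer-coded phenotypes with fewer than 10
distinct values are refused because binned traits make decile effects
uninterpretable. `effect_ratio()` reports the max/min effect ratio and
whether the extreme deciles' CIs overlap.

# Machine-learning comparison

Three model classes are compared by mean 10-fold cross-validated R^2^ on
identical fold assignments (paired comparison): L1-penalized linear
regression over the 18-value lambda ladder, the same with PGS-covariate
product terms appended, and a feed-forward neural network without
product terms. Features are min-max scaled to [0,1] with bounds learned
per training fold (no leakage; test rows may fall outside [0,1] and are
flagged, not clipped). The LASSO path uses `glmnet` with
`standardize = FALSE` so the [0,1] scaling is the operative one.

The network is a ReLU regressor trained by plain momentum SGD on MSE
loss (authored in C++ within the package), with hyperparameters sampled
uniformly from: hidden width [10, 200], 1–2 hidden layers, learning rate
[1e-4, 0.01], schedule constant or inverse-scaling with power-t
[0.4, 0.6], momentum [0.80, 1.0], batch size [32, 256]. Every sampled
configuration receives the **same training compute**: the epoch budget
(default 40 for a one-layer, width-100 reference) shrinks in proportion
to a configuration's per-epoch cost, the usual fairness convention of
flat-budget random search; training also stops early on an MSE plateau
(relative improvement < 5e-5 over 6 epochs). Diverging configurations
are discarded with a per-configuration log; the default search is 50
iterations (the full-scale protocol of 1,000 is a parameter away).

# The GxAge experiment

`run_gxage_experiment()` orchestrates the three GWAS designs — main
effects, SNP-by-age interaction, and age-quartile-stratified — on a 60%
random split, builds each design's ten-threshold candidate ladder, tunes
on a 20% training split by incremental R^2^, and evaluates the winners on
the held-out 20%. The SNP-by-age scan supports raw-year (default,
matching the conventional scoring formula) and centered age codings; the
deployed model records its coding and scoring applies it, and the two
deployed scores are *identical* — the per-SNP fit is invariant to the
affine reparameterization, only the reported per-coefficient SEs differ.
Evaluation: the evaluation regression (rank-normalized phenotype
on score + Age + Sex + PCs) is fit on the training split and its
predictions are correlated with the test phenotype, minus the
covariate-only analogue; a variant adds a post-hoc PGS-by-age product.
For the stratified design, quartile boundaries come from the GWAS split,
per-quartile models are tuned separately, and per-quartile test
predictions are pooled before the single R^2^ computation. Each stratum
has its own GWAS, so clumping is per-quartile. `bootstrap_test_r2()`
resamples the *training* individuals and refits only the evaluation
regression (re-running thousands of GWAS would be computationally
indefensible, and the evaluation regression is the train-side randomness
that survives to test R^2^), reporting the 2.5/97.5 percentile interval.
Relative improvements are reported as $(R^2_a - R^2_b)/R^2_b$.

# Numerical choices and degenerate inputs

* OLS everywhere is QR-based; rank-deficient designs raise errors naming
  the collinear columns.
* Quantile ties in stratum construction go to the lower bin; heavily
  tied covariates may merge bins deterministically.
* Empty score models are allowed but warned about; an all-empty
  candidate ladder is an error.
* Seeds: every stochastic entry point takes a `seed` argument, runs
  under a locally restored RNG state, and derives per-stage child seeds
  below 2^31.

# Problem sizes in the test suite

The packaged tests exercise the pipeline at sizes chosen to give stable
Monte-Carlo margins on a single CPU: calibration analyses use 10,000
analysis individuals with a 4,000-individual GWAS split over 80 SNPs
(500 replicates), recovery and stratification analyses 20,000
individuals over 40–60 SNPs, the GxAge experiment 50,000 individuals
over 200 SNPs (10 seeds per condition), and the model comparison 10,000
individuals with a 50-configuration search over 10 seeds. Bootstrap
loops inside calibration replicates use a few hundred resamples — enough
for a stable SD inside a replicated calibration check — while the
single-analysis default remains 5,000. The per-SNP architecture of the
GxAge experiment (200 SNPs at h^2^ = 0.05, all causal SNPs carrying an
age interaction at half the main-effect magnitude per age SD) is
deliberately weak: its held-out incremental R^2^ lands near 0.05, the
scale reported for real biobank BMI scores, and quartile-stratified GWAS
lose real power — the regime in which age-stratified scores are known to
underperform.

# Known limitations

* The covariates' generative relationship to the trait is a deliberately
  simple mixture surrogate; real covariate architectures (measurement
  error, time dependence, discrete scales) are out of scope.
* P+T is the only weighting scheme; posterior shrinkage weighting is out
  of scope.
* The neural-network stage is a small SGD regressor suitable for tabular
  features at desk scale, not a deep-learning framework.
* Incremental R^2^ on the test split can be slightly negative under a
  null score; values are reported as computed, not clipped.
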