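---
title: "Models and methods behind episcope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind episcope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

episcope implements an end-to-end blood DNA-methylation analysis of a
quantitative trait: kinship-aware phenotype residualization, a marginal
epigenome-wide association study (EWAS) with cell-composition and smoking
covariates, empirical-Bayes correction of test-statistic bias and inflation,
a joint Bayesian EWAS over all CpGs, elastic-net methylation scores
(EpiScores) projected into an external cohort, and latent growth modelling of
longitudinal cognition. Because the cohorts this kind of analysis is run on
are access-restricted, the package ships a synthetic-cohort generator whose
statistical structure mirrors them; every stage is tested against that
generator's ground truth. This vignette explains the models, the defaults,
and the design decisions, in that order of importance.

## The synthetic cohort generator

`simulate_cohort()` draws beta values through a logistic squash of Gaussian
latent variables on the log2-odds (M-value) scale, so `beta_to_m()` is the
exact inverse of the generative transform. CpGs fall into contiguous blocks
sharing a latent factor; the within-block correlation of M-values equals
`within_block_corr` (default 0.6, block size 20 at the default 20,000 CpGs /
1,000 blocks), a coarse stand-in for the local correlation structure of
methylation arrays.

The phenotype is assembled from components with *exact* empirical variance
shares: the causal-CpG signal first (left untouched), then age, age squared,
sex, a shared per-family effect, the first cell-type fraction, the smoking
exposure, a batch effect and Gaussian noise, each orthogonalized against the
preceding components before scaling. This makes the variance bookkeeping
sharp: regressing the trait on the causal M-values returns
`target_variance_explained` (default 0.40) up to overfitting bias of roughly
`n_causal / n_samples`, which is what the generator's recovery tests assert.

Causal effect magnitudes are drawn as `sign * (0.5 + effect_sd * |N(0,1)|)`.
Bounding them away from zero is deliberate: with plain Gaussian draws about a
fifth of "causal" sites carry effects no method could detect at any
reasonable sample size, and recovery rates would then measure the effect
distribution, not the estimator. `effect_sd = 0` gives equal-magnitude loci.

Confounding is built in rather than bolted on. Cell-type fractions are drawn
from a Dirichlet and drive both a 200-CpG reference panel (through a
synthetic cell-type reference, `make_cell_reference()`) and the phenotype; a
continuous smoking exposure shifts a 100-CpG panel and the phenotype; batch
labels shift all non-causal CpG M-values and contribute phenotype variance.
The per-component phenotype shares (age 2%, age-squared 0.5%, sex 1%, family
3%, cells 5%, smoking 4%, batch 2% by default) emulate a mostly-noise,
weakly-confounded adult cohort; `sim_config_confounded()` raises the batch
share to 10% and the batch shifts to SD 0.5 to act as a strong *unmeasured*
confounder.

Family structure is sibling clusters only: `sibs_per_family` members share
one family effect, so the kinship matrix has diagonal 0.5 and within-family
off-diagonal 0.5, and the mixed model's `2K` covariance gives siblings the
full shared variance. That is the simplest structure that makes the kinship
model non-trivial; it does not emulate extended pedigrees.

What the generator does *not* emulate: probe-type chemistry, genotype-driven
methylation (meQTL structure), non-Gaussian trait tails, or realistic
missingness mechanisms (missing values are injected uniformly at random,
default 2%, in test cohorts only). Tests passing on this generator therefore
certify the statistical machinery, not performance on any real array.

## Preprocessing

M-values are `log2(beta/(1-beta))` with betas clipped to
`[1e-6, 1 - 1e-6]` to avoid infinities. `quantile_normalize()` replaces each
sample's order statistics by their across-sample means (ties averaged),
delegating to `limma::normalizeQuantiles`. `remove_outliers()` is a single
(non-iterated) +/- k SD rule, default k = 4, warning when more than 1% of
values are removed; the outlier rule of the real cohorts is not published,
so this conservative convention is a package decision.

`precorrect_m_values()` residualizes each CpG on intercept + age + sex
(+ batch dummies when a batch column is present); single-sample batches are
merged into the reference level with a warning. Missing entries are ignored
per CpG and remain missing. The operation is idempotent, which the tests
assert.

`fit_kinship_lmm()` fits y = Xb + g + e with g ~ N(0, sigma2_g * 2K). After
an eigendecomposition of 2K the restricted likelihood is profiled to one
dimension and minimized by Brent's method over log(lambda) in [-10, 10]
(tolerance 1e-6), lambda = sigma2_g / sigma2_e. When 2K is numerically the
identity the ratio is unidentifiable — any split of the variance gives the
same likelihood — so the fit short-circuits to OLS with sigma2_g = 0, which
also pins down the documented OLS-equivalence contract. Residuals default to
*conditional* (subtracting the BLUP of g), matching the usual mixed-model
residual; `residual_type = "marginal"` keeps the family effect in. Age is
mean-centred before squaring so the linear and quadratic terms are not
strongly collinear; the source analyses do not state their centring
convention, and this is flagged as a package decision.

## Covariates

The smoking score is a fixed weighted sum of beta values over a CpG panel
(the 187-site weighted-score design), with cohort-mean imputation of missing
entries; on synthetic cohorts it recovers the true exposure at r > 0.95.
Cell-type proportions solve min ||beta_i - R w||^2 subject to w >= 0 and
sum(w) = 1 per sample. With at most a dozen cell types the exact solution is
found by enumerating all supports and solving the equality-constrained
least-squares problem on each: the global constrained optimum is the
feasible support solution with minimal residual, so no iterative NNLS
approximation is needed. Methylome PCs come from an exact eigendecomposition
of the smaller-dimension cross-product of the column-standardized
corrected-M matrix (constant CpGs dropped with a warning; component signs
fixed so the largest-magnitude loading is positive). PCs are computed on
*pre-corrected* M-values so they capture residual unmeasured structure
rather than re-capturing known batch.

## Marginal EWAS

`run_marginal_ewas()` regresses the residualized trait on each standardized
CpG plus covariates. With complete data the covariates are projected out
once by QR and every CpG is tested in closed form (Frisch–Waugh); CpGs with
missing samples fall back to per-CpG least squares on complete cases, with
`n_used` recorded. Effects are per SD of corrected M-value; p-values are
two-sided Student-t with the exact residual degrees of freedom; an
independent `lm()` oracle agreement of 1e-8 or better over 100 random CpGs
is part of the acceptance suite. Inflation is summarized by
lambda_GC = median observed chi-squared(1) / 0.4549, reported for both the
base and PC-adjusted models since the literature is ambiguous about which is
quoted. Zero-variance probes are excluded and logged rather than returning
NaN statistics. Epigenome-wide significance defaults to p < 3.6e-8, the
simulation-derived array-wide threshold.

## Bias/inflation correction (bacon-style)

`fit_bacon()` fits z-scores with a three-component Gaussian mixture by Gibbs
sampling: a central null component whose mean is the *bias* and SD the
*inflation*, plus sign-constrained tail components that absorb true signal.
Defaults: 5,000 iterations, 2,000 burn-in, two chains whose disagreement on
the bias (split R-hat > 1.1) warns and flags the fit. The priors matter.
With a flat Dirichlet weight prior a tail component absorbs one flank of a
*pure-null* z sample, overstating the bias and understating the inflation,
so the package uses a null-favouring Dirichlet(900, 5, 5) with
N(0,1)/N(-3,1)/N(3,1) means and wide-tail inverse-gamma variance priors
(IG(2,1) centre, IG(6,20) tails). These were fixed against three calibration
cases — N(0,1), N(0.5, 1.5^2), and a 95/5 null/signal mixture — before the
test suite was frozen; the test suite re-runs all three.
`apply_bacon()` rescales z' = (z - mu)/sigma, multiplies SEs by sigma,
shifts effects by mu * SE, and recomputes p on the normal reference.

## Joint Bayesian EWAS

`run_bayes_ewas()` is a Gibbs sampler for y = W alpha + X beta + e with all
standardized CpGs in X and a spike-and-slab mixture prior on beta: a point
mass at zero plus three Gaussian slabs with variances {1e-4, 1e-3, 1e-2}
times a sampled effect-variance scale — the standard small/medium/large
grid. Each iteration sweeps the CpGs in a freshly permuted order (reducing
order artifacts), samples each CpG's component from its conditional marginal
likelihood given the current residual, then its effect; the residual vector
is updated incrementally and checked against full recomputation to 1e-8 in
the tests. Covariates are unpenalized and resampled each iteration; mixture
weights are Dirichlet(counts + 1); the effect-variance scale and residual
variance have inverse-gamma conditionals. The per-CpG posterior inclusion
probability (PIP) is the post-burn-in inclusion frequency, and the
methylome-wide variance explained is var(X beta)/var(y) per thinned
iteration (well-defined under correlated X, unlike a ratio of variance
parameters). High-confidence sites are PIP >= 0.95, inclusive.

The effect-variance scale's prior is the one non-obvious numerical choice:
IG(shape 6, mean 10 * var(y)). If the scale is allowed to collapse, the
smallest slab's variance tends to zero, its Bayes factor against the spike
tends to one, and null CpGs random-walk into the slab, inflating the mean
PIP on pure-null data by an order of magnitude. Keeping the scale of order
var(y) pins the smallest detectable effect near 0.1% of trait variance and
restores the expected null behaviour (small mean PIP, no PIP >= 0.95 calls —
asserted by the tests) without hurting power: the test suite checks that a
single CpG carrying 20% of trait variance is recovered with high PIP and an
effect within a quarter of truth, and that 50 causal CpGs jointly explaining
40% return a posterior variance-explained within 0.08 of the target. Defaults are 10,000
iterations with 5,000 burn-in and thinning 5; the bundled analyses and
tests use shorter chains (300–1,500 iterations), which the recovery checks
show are sufficient at these problem sizes. Divergence (collapse of the
residual variance) aborts with the iteration number in the error.

Diagnostic limits are exposed as configuration switches rather than separate
code paths: `spike_only` forces all mass to the spike (all effects exactly
zero; residual variance returns to var(y)), and `force_inclusion` with a
single fixed-variance slab is a Bayesian ridge whose posterior means match
the closed-form ridge solution at the matched penalty sigma2_e / v.

## EpiScores

Training restricts to the probe intersection with the test array *before*
fitting, then runs a 20-fold cross-validated elastic net (alpha 0.5) over a
100-point log-spaced lambda path (min/max ratio 1e-3) at the minimum-MSE
lambda, via glmnet with columns standardized by the package so that the
stored weights, training means and SDs fully determine projection. The
package also carries its own fixed-penalty coordinate-descent solver
(`elnet_fit()`), used for the closed-form single-predictor identity
S(b, lambda*alpha)/(1 + lambda*(1-alpha)) and as an independent cross-check
against glmnet (agreement < 1e-4 at matched penalties). Fold assignment is
seeded but not family-aware — a known limitation with relatives in training
data. The pure-null sparsity property (CV selects an empty or near-empty
model) is checked at n = 1,000, where the minimum-MSE rule is stable; at a
few hundred samples 20-fold CV noise occasionally selects interior lambdas
on null data, which is a property of min-MSE selection rather than of the
implementation.

`project_score()` computes intercept + sum of weights times test values on
the training scale; weight CpGs absent from the test matrix, or missing per
sample, impute to the training mean (zero on the standardized scale), with
the imputed fraction recorded and a flag raised past 50% absent.
`bayes_score()` projects posterior-mean effects under the same contract.
Models are trained on the *residualized* phenotype but evaluated against the
*raw* trait with age and sex covariates — the asymmetry is intentional and
mirrors how such scores are deployed. `incremental_r2()` reports
R2(full) - R2(base) overall (with subgroup dummies when pooling subgroups)
and per subgroup (without them), flagging subgroups under 30 samples.

## Cognition

The latent growth model is a two-stage estimator. Stage 1 extracts a single
common factor: loadings are the first eigenvector of the pooled
across-waves test covariance (fixed across waves, sign-normalized, weights
scaled to sum to one so that with unit loadings the factor score is the
plain test mean); samples missing tests at a wave use renormalized weights.
Stage 2 fits a random-intercept, random-slope linear mixed model of factor
scores on years since baseline (lme4) and returns empirical-Bayes per-person
intercepts and slopes; when the per-person linear fits are exact (zero
noise) the mixed model is degenerate and the estimator returns the
per-person least-squares solutions, which are then the maximum-likelihood
estimates. A simultaneous factor-plus-growth structural equation model would
target the same two estimands; the two-stage version was chosen because it
is transparent, fast, and directly testable against simulation truth
(noiseless identifiability to 1e-6; intercept recovery r > 0.9 at realistic
noise). Factor scores default to baseline standardization, so intercept and
slope are in baseline-SD units (slope per year).

`test_associations()` regresses the standardized intercept (and slope) on
each standardized predictor plus covariates, one predictor at a time, with
Benjamini–Hochberg FDR within each outcome across the predictor family.
The direction — cognition as outcome, trait/EpiScore as predictor — follows
the reported standardized betas of this literature; the alternative reading
(scores regressed *on* the latent variables inside the SEM) is noted but not
implemented. `variance_decomposition()` reports incremental R2 over age+sex
for measured trait, EpiScore, and both.

## Pipeline and problem sizes

`run_pipeline()` chains the stages from a nested configuration (YAML or
list), derives per-stage seeds by hashing the global seed with the stage
name (so stage reordering cannot silently change a stage's stream), writes
summary TSV/JSON outputs with fixed numeric formatting, and records a
manifest with per-stage seeds, wall times and MD5 hashes of outputs.
Re-running an identical configuration reproduces byte-identical summary
files; the manifest itself carries wall times and is excluded from that
guarantee.

The bundled analyses run at deliberately desk-scale sizes — 2,000 samples by
20,000 CpGs for the cohort analyses, 5,000 CpGs for the sampler recovery
studies, a 500 x 2,000 default pipeline preset — chosen so the full suite of
analyses, tests and recovery checks completes on a laptop-class single core
while keeping every estimator in the regime where its asymptotic behaviour
is visible (for example, epigenome-wide power at p < 3.6e-8 at n = 2,000
requires per-CpG effects of about 1.5% of trait variance, which the
confounded preset's 20 equal loci at 2% deliberately exceed, while their
block-mates at correlation 0.75 sit just past the threshold — reproducing
the marginal-vs-joint count collapse at desk scale).

## Known limitations

* The generator's block-exchangeable correlation is much simpler than array
  reality; PIP dilution among near-duplicate probes is therefore milder here
  than it can be in real data.
* No probe-type normalization, detection-p QC or IDAT handling: the pipeline
  starts from post-QC betas by design.
* CV folds ignore family structure; with many relatives the CV estimate of
  score performance is mildly optimistic.
* The bacon-style correction assumes the null is a single Gaussian; heavy
  multi-component nulls would be absorbed into the tails.
* Cognitive dropout is simulated as monotone and ignorable, and the growth
  model does not model practice effects or mortality-informed dropout.
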