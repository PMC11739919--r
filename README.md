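# episcope

Blood DNA methylation carries reproducible signatures of metabolic health:
body-mass index, body fat, waist-hip ratio, glucose and cholesterol all leave
correlated marks across thousands of CpG sites. Analysing those signatures
well requires more than a per-CpG regression — family structure inflates
naive tests, cell composition, smoking and batch confound them, the
methylome's correlation structure multiplies "significant" sites far beyond
the number of independent signals, and a weighted sum of CpGs (an
**EpiScore**) trained in one cohort must survive projection onto a different
array in a different population.

episcope implements that full analysis as a tested R package:

* **Kinship-aware residualization** — phenotypes regressed on age, age²,
  sex and family structure via a REML linear mixed model,
  y = Xb + g + e with g ~ N(0, σ²_g·2K), profiled to a one-dimensional
  search after eigendecomposition of the kinship matrix 2K.
* **Marginal EWAS** — per-CpG OLS of the residualized trait on standardized
  M-values with smoking-score and cell-proportion covariates (optionally the
  first 20 methylome PCs), exact-df t tests, and the genomic inflation
  factor λ_GC = median(χ²)/0.4549.
* **bacon-style correction** — a three-component Gaussian-mixture Gibbs
  sampler on z-scores estimating bias μ and inflation σ of the null
  component; corrected statistics z′ = (z − μ)/σ.
* **Joint Bayesian EWAS** — a BayesR-style spike-and-slab Gibbs sampler over
  all CpGs simultaneously (slab variances {1e-4, 1e-3, 1e-2} × a sampled
  scale), yielding per-CpG posterior inclusion probabilities (PIP), the
  high-confidence set at PIP ≥ 0.95, and the trait variance explained by
  genome-wide methylation, var(Xβ)/var(y).
* **Independent-signal counting** — the number of principal components
  explaining ≥ 80% of the variance among significant CpGs.
* **EpiScores** — 20-fold cross-validated elastic net (α = 0.5) on the probe
  intersection between cohorts, projection with training-mean imputation,
  and incremental R² over age + sex, overall and by subgroup.
* **Cognition** — a latent growth model (common factor across tests, random
  intercept/slope over waves) and standardized associations of traits and
  EpiScores with cognitive level and change under Benjamini–Hochberg FDR.
* **Synthetic cohorts** — a generator with block-correlated CpGs, sparse
  causal effects with exact variance bookkeeping, cell/smoking/batch
  confounding, sibling kinship, reduced-probe test cohorts with subgroup
  heterogeneity, and longitudinal cognitive scores; every stage is tested
  against its ground truth, since the real cohorts this design targets are
  access-restricted.

## Worked example

```r
library(episcope)

# a 500 x 2,000 cohort: 20 causal CpGs explaining 40% of the trait
cfg <- sim_config(n_samples = 500, n_cpgs = 2000, n_blocks = 200,
                  n_causal = 20, target_variance_explained = 0.4,
                  family_spec = list(n_families = 60, sibs_per_family = 2),
                  seed = 1)
b  <- simulate_cohort(cfg)
mc <- precorrect_m_values(beta_to_m(b$methylation), b$phenotypes)
ph <- residualize_phenotype(b)

cells <- deconvolve_cells(b$methylation, b$truth$cell_reference)
smoke <- smoking_score(b$methylation,
                       weight_table(b$truth$smoking_cpg_ids,
                                    b$truth$smoking_weights))
covs  <- data.frame(smoking = as.numeric(smoke), cells[, -1])

ewas <- run_marginal_ewas(ph, mc, covs)
ewas
#> <ewas_result> trait=trait model=base CpGs=2000 lambda_GC=1.232
length(call_significant(ewas))          # epigenome-wide hits at p < 3.6e-8
#> [1] 3

post <- run_bayes_ewas(ph, mc, covs,
                       bayes_config(n_iterations = 800, burn_in = 300, seed = 7))
post
#> <bayes_posterior> trait=trait CpGs=2000 PIP>=0.95: 5 varexp=0.522 [0.420, 0.638]
```

Only three CpGs pass the stringent epigenome-wide threshold in the marginal
scan at this small size (λ_GC 1.23 reflects correlation-driven inflation),
while the joint model calls five high-confidence sites — all of them true
causal loci. The methylome-wide variance explained is estimated at 0.52
against a simulated truth of 0.40: at 500 samples and 2,000 CpGs the joint
model absorbs some noise into small effects, an upward bias that shrinks at
the package's reference scale (n = 2,000, where the recovery tests require
0.40 ± 0.08). `run_pipeline(default_run_config(seed = 1))`
chains all stages (simulation → preprocessing → covariates → marginal EWAS
with bacon → joint EWAS → EpiScore → cognition) and writes summary tables
plus a seed/hash manifest; re-running the same configuration reproduces the
summaries byte for byte.

The numbered scripts under `analysis/` run the same stages at the package's
reference scale (2,000 × 20,000) as a narrative analysis, writing tables
under `results/`: cohort simulation, preprocessing, covariates, marginal
EWAS, joint EWAS with the per-trait count table, EpiScore training and
cross-cohort evaluation, cognition, and the batch-confounded comparison in
which the significant-CpG count collapses from hundreds (marginal) to tens
(PC-adjusted) to ~20 (joint, PIP ≥ 0.95, nearly all inside the PC-adjusted
set).

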