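#' Methylation matrix container
#'
#' Thin container for a samples-by-CpGs methylation matrix with an explicit
#' scale tag. Beta values are methylation proportions in (0,1); M-values are
#' log2(beta/(1-beta)); corrected-M are M-values residualized on technical
#' covariates. Missingness is carried as `NA` in `values`.
#'
#' @param values numeric matrix, samples in rows (rownames = sample IDs),
#'   CpGs in columns (colnames = CpG IDs).
#' @param scale one of "beta", "M", "corrected-M".
#' @return object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(values, scale = c("beta", "M", "corrected-M")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  assert_that(!anyDuplicated(rownames(values)), "duplicate sample IDs")
  assert_that(!anyDuplicated(colnames(values)), "duplicate CpG IDs")
  if (scale == "beta") {
    rng <- range(values, na.rm = TRUE)
    assert_that(rng[1] > 0 && rng[2] < 1, "beta values must lie strictly in (0,1)")
  }
  structure(list(values = values, scale = scale), class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("<methylation_matrix> %d samples x %d CpGs, scale = %s, %.2f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.methylation_matrix <- function(x) dim(x$values)

sample_ids <- function(mat) rownames(mat$values)
cpg_ids <- function(mat) colnames(mat$values)

#' Simulation configuration
#'
#' Parameters of the synthetic-cohort generator. Defaults define the
#' package's reference study conditions: a family-structured training cohort
#' of 2,000 samples and 20,000 block-correlated CpGs with 50 causal sites
#' jointly explaining 40% of phenotype variance, confounded by blood cell
#' composition, a smoking exposure and additive batch shifts.
#'
#' @param n_samples,n_cpgs cohort dimensions.
#' @param n_blocks number of CpG correlation blocks (contiguous).
#' @param within_block_corr latent within-block correlation in \[0,1).
#' @param n_causal number of causal CpGs (0 gives a pure-null phenotype).
#' @param effect_sd heterogeneity of causal effect magnitudes: raw effects
#'   are sign * (0.5 + effect_sd * |N(0,1)|), then the joint signal is
#'   rescaled to `target_variance_explained` (so only relative magnitudes
#'   matter; 0 gives equal-magnitude loci).
#' @param confounder_spec list with `cell_types`, `smoking_effect`
#'   (M-value shift per SD of exposure), `batch_count`, `batch_effect_sd`.
#' @param family_spec list with `n_families`, `sibs_per_family`; remaining
#'   samples are unrelated singletons.
#' @param target_variance_explained fraction of phenotype variance explained
#'   by the causal CpG M-values jointly.
#' @param seed integer RNG seed; identical configs give bit-identical cohorts.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 2000, n_cpgs = 20000, n_blocks = 1000,
                       within_block_corr = 0.6, n_causal = 50, effect_sd = 1,
                       confounder_spec = list(cell_types = 6, smoking_effect = 1,
                                              batch_count = 10, batch_effect_sd = 0.1),
                       family_spec = list(n_families = 250, sibs_per_family = 2),
                       target_variance_explained = 0.4, seed = 1) {
  cfg <- list(n_samples = n_samples, n_cpgs = n_cpgs, n_blocks = n_blocks,
              within_block_corr = within_block_corr, n_causal = n_causal,
              effect_sd = effect_sd, confounder_spec = confounder_spec,
              family_spec = family_spec,
              target_variance_explained = target_variance_explained, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_samples >= 1 && cfg$n_cpgs >= 1 && cfg$n_blocks >= 1,
              "all counts must be >= 1")
  assert_that(cfg$n_causal <= cfg$n_cpgs,
              sprintf("infeasible config: n_causal (%d) > n_cpgs (%d)",
                      cfg$n_causal, cfg$n_cpgs))
  assert_that(cfg$n_blocks <= cfg$n_cpgs, "n_blocks must not exceed n_cpgs")
  assert_that(cfg$within_block_corr >= 0 && cfg$within_block_corr < 1,
              "within_block_corr must lie in [0,1)")
  assert_that(cfg$target_variance_explained >= 0 && cfg$target_variance_explained <= 0.8,
              "target_variance_explained must lie in [0, 0.8] to leave room for noise")
  assert_that(cfg$effect_sd >= 0, "effect_sd must be >= 0")
  assert_that(cfg$family_spec$n_families * cfg$family_spec$sibs_per_family <= cfg$n_samples,
              "family_spec implies more samples than n_samples")
  invisible(cfg)
}

#' Batch-confounded study conditions
#'
#' Preset configuration for the confounded-EWAS comparison: batch acts as a
#' strong unmeasured confounder (10% of trait variance, strong shifts on all
#' non-causal CpGs), 20 equal-magnitude causal loci jointly explaining 40%
#' of trait variance inside correlation blocks (within-block r = 0.75).
#' Under these conditions the causal sites reach about |t| = 7.6 in a
#' marginal EWAS at n = 2,000 and their block-mates about |t| = 5.7 — just
#' past the epigenome-wide threshold — so the marginal EWAS calls whole
#' blocks while the joint model concentrates on the causal sites.
#'
#' @param seed RNG seed.
#' @param n_samples,n_cpgs cohort dimensions.
#' @return a [sim_config()].
#' @export
sim_config_confounded <- function(seed = 33, n_samples = 2000, n_cpgs = 20000) {
  sim_config(n_samples = n_samples, n_cpgs = n_cpgs,
             n_blocks = max(1, n_cpgs %/% 20),
             n_causal = 20, effect_sd = 0, within_block_corr = 0.75,
             target_variance_explained = 0.4,
             confounder_spec = list(cell_types = 6, smoking_effect = 1,
                                    batch_count = 10, batch_effect_sd = 0.5,
                                    batch_pheno_share = 0.10),
             family_spec = list(n_families = max(1, n_samples %/% 8),
                                sibs_per_family = 2),
             seed = seed)
}

#' Synthetic whole-blood cell-type reference panel
#'
#' Per-cell-type mean beta values on a CpG panel, for reference-based
#' deconvolution. Synthetic: mimics the shape (CpGs x cell types, betas in
#' (0,1)) of a leukocyte reference, not its actual values.
#'
#' @param n_cpgs panel size.
#' @param cell_types number of cell types (default 6, a typical leukocyte
#'   panel size).
#' @param seed RNG seed.
#' @return list of class `cell_reference` with `cpg_ids`, `means` (CpGs x
#'   cell types), `cell_type_names`.
#' @export
make_cell_reference <- function(n_cpgs = 200, cell_types = 6, seed = 99) {
  stopifnot(cell_types >= 2, n_cpgs >= cell_types)
  set.seed(seed)
  base <- rnorm(n_cpgs, 0, 1.5)
  dev <- matrix(rnorm(n_cpgs * cell_types, 0, 2), n_cpgs, cell_types)
  means <- 1 / (1 + 2^-(base + dev))
  means <- pmin(pmax(means, 0.02), 0.98)
  ids <- sprintf("cg_cell_%04d", seq_len(n_cpgs))
  types <- paste0("cell", seq_len(cell_types))
  dimnames(means) <- list(ids, types)
  structure(list(cpg_ids = ids, means = means, cell_type_names = types),
            class = "cell_reference")
}

# Phenotype variance budget (fractions of total trait variance). The causal
# share is the config's target; the rest emulates adult-cohort-like nuisance structure:
# modest age/sex/family effects (removed later by residualization) and
# cell/smoking/batch confounding shared with the methylome. The batch share
# is configurable so batch can act as a strong unmeasured confounder.
variance_budget <- function(v_causal, batch_share = 0.02) {
  stopifnot(v_causal + 0.155 + batch_share < 1)
  list(causal = v_causal, age = 0.02, age2 = 0.005, sex = 0.01, family = 0.03,
       cell = 0.05, smoking = 0.04, batch = batch_share,
       resid = 1 - v_causal - 0.155 - batch_share)
}

scale_to_var <- function(x, v) {
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s * sqrt(v)
}

# Assemble a phenotype from components with exact variance shares: each
# component is orthogonalized against the preceding ones (the causal signal
# comes first and is left untouched) and scaled to its share, so the causal
# CpGs explain exactly their target fraction of trait variance.
assemble_phenotype <- function(components, shares) {
  n <- length(components[[1]])
  basis <- matrix(1, n, 1)
  y <- rep(0, n)
  for (k in seq_along(components)) {
    x <- components[[k]]
    if (sd(x) < 1e-12) next
    r <- lm.fit(basis, x)$residuals
    if (sd(r) < 1e-12) next
    r <- scale_to_var(r, shares[[k]])
    y <- y + r
    basis <- cbind(basis, r)
  }
  y
}

#' Simulate a training cohort
#'
#' Generates betas by a logistic squash of Gaussian latent block factors (so
#' the M-value transform is the exact inverse), a quantitative phenotype
#' driven by causal CpG M-values plus age, sex, cell-composition, smoking,
#' batch and family components, a sibling-cluster kinship matrix, and a
#' ground-truth record for parameter-recovery tests.
#'
#' @param config a [sim_config()].
#' @return list of class `cohort_bundle` with elements `methylation`
#'   (beta-scale [methylation_matrix()]), `phenotypes` (data.frame with
#'   sample_id, trait, age, sex, batch, subgroup), `kinship` (square matrix,
#'   diag 0.5, sibling off-diagonal 0.5), `truth`, and `generator` (internal
#'   parameters reused by [simulate_test_cohort()]).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_samples; p <- config$n_cpgs
  cs <- config$confounder_spec
  budget <- variance_budget(config$target_variance_explained,
                            batch_share = cs$batch_pheno_share %||% 0.02)

  cpg_ids <- sprintf("cg%07d", seq_len(p))
  sample_idv <- sprintf("S%05d", seq_len(n))

  # CpG panels: cell-reference panel, smoking panel, causal set (disjoint)
  n_cell_panel <- min(200, max(0, p - config$n_causal - 120))
  n_smoke_panel <- min(100, max(0, p - config$n_causal - n_cell_panel))
  cell_idx <- seq_len(n_cell_panel)
  smoke_idx <- seq_len(n_smoke_panel) + n_cell_panel
  free_idx <- setdiff(seq_len(p), c(cell_idx, smoke_idx))
  causal_idx <- if (config$n_causal > 0)
    sort(sample(free_idx, config$n_causal)) else integer(0)

  # block-correlated latent M-values
  block <- rep(seq_len(config$n_blocks), length.out = p)
  block <- sort(block)                       # contiguous blocks
  rho <- config$within_block_corr
  fac <- matrix(rnorm(n * config$n_blocks), n, config$n_blocks)
  z <- sqrt(rho) * fac[, block, drop = FALSE] +
    sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
  mu <- rnorm(p, 0, 2)
  s_cpg <- runif(p, 0.5, 1.5)
  M <- sweep(sweep(z, 2, s_cpg, "*"), 2, mu, "+")

  # confounders
  cellref <- make_cell_reference(n_cpgs = max(n_cell_panel, 2),
                                 cell_types = cs$cell_types,
                                 seed = derive_seed(config$seed, "cellref"))
  if (n_cell_panel > 0) {
    # the reference panel maps onto the cohort's cell-informative CpGs
    cellref$cpg_ids <- cpg_ids[cell_idx]
    rownames(cellref$means) <- cellref$cpg_ids
  }
  frac <- rdirichlet(n, alpha = c(6, 3, 2, 1.5, 1, rep(0.8, max(0, cs$cell_types - 5)))[seq_len(cs$cell_types)])
  colnames(frac) <- cellref$cell_type_names
  rownames(frac) <- sample_idv
  if (n_cell_panel > 0) {
    mix_beta <- frac %*% t(cellref$means[seq_len(n_cell_panel), , drop = FALSE]) +
      matrix(rnorm(n * n_cell_panel, 0, 0.02), n, n_cell_panel)
    mix_beta <- pmin(pmax(mix_beta, 1e-4), 1 - 1e-4)
    M[, cell_idx] <- log2(mix_beta / (1 - mix_beta))
  }
  smoking <- rnorm(n)
  smoke_w <- numeric(0)
  if (n_smoke_panel > 0) {
    smoke_w <- runif(n_smoke_panel, 0.5, 1.5) *
      sample(c(-1, 1), n_smoke_panel, replace = TRUE)
    M[, smoke_idx] <- M[, smoke_idx] +
      cs$smoking_effect * outer(smoking, smoke_w)
  }
  batch <- factor(sample(sprintf("B%02d", seq_len(cs$batch_count)), n, replace = TRUE))
  batch_shift <- matrix(rnorm(cs$batch_count * p, 0, cs$batch_effect_sd),
                        cs$batch_count, p)
  batch_shift[, causal_idx] <- 0   # causal sites carry clean signal
  M <- M + batch_shift[as.integer(batch), , drop = FALSE]

  # demographics and family structure (family-based adult-cohort age distribution)
  age <- pmin(pmax(rnorm(n, 47.5, 14.9), 18), 95)
  sex <- rbinom(n, 1, 0.59)
  fs <- config$family_spec
  n_fam_members <- fs$n_families * fs$sibs_per_family
  family <- c(rep(seq_len(fs$n_families), each = fs$sibs_per_family),
              fs$n_families + seq_len(n - n_fam_members))
  fam_effect <- rnorm(max(family))[family]

  # phenotype assembly on the standardized scale (unit total variance)
  # effect magnitudes bounded away from zero so every causal site carries
  # detectable signal (a plain Gaussian draw makes ~20% of "causal" sites
  # arbitrarily weak, which no method could recover); effect_sd controls the
  # heterogeneity of magnitudes around the base (0 = equal-magnitude loci)
  eff_raw <- if (config$n_causal > 0) {
    sample(c(-1, 1), config$n_causal, replace = TRUE) *
      (0.5 + config$effect_sd * abs(rnorm(config$n_causal)))
  } else numeric(0)
  g <- if (config$n_causal > 0 && budget$causal > 0) {
    Mc <- scale(M[, causal_idx, drop = FALSE])
    scale_to_var(as.numeric(Mc %*% eff_raw), budget$causal)
  } else rep(0, n)
  age_c <- age - mean(age)
  pheno <- assemble_phenotype(
    list(g, age_c, age_c^2, sex, fam_effect, frac[, 1], smoking,
         rnorm(cs$batch_count)[as.integer(batch)], rnorm(n)),
    c(if (config$n_causal > 0) budget$causal else 0, budget$age, budget$age2,
      budget$sex, budget$family, budget$cell, budget$smoking, budget$batch,
      budget$resid + if (config$n_causal > 0) 0 else budget$causal))

  beta <- 1 / (1 + 2^-M)
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  dimnames(beta) <- list(sample_idv, cpg_ids)

  kin <- kinship_from_families(family, sample_idv)

  phenotypes <- data.frame(sample_id = sample_idv, trait = pheno, age = age,
                           sex = sex, batch = as.character(batch),
                           subgroup = "all", family = family,
                           stringsAsFactors = FALSE)

  truth <- list(
    causal_cpg_ids = cpg_ids[causal_idx],
    causal_effects = eff_raw,
    true_cell_fractions = frac,
    true_variance_explained = if (config$n_causal > 0) budget$causal else 0,
    smoking_cpg_ids = cpg_ids[smoke_idx],
    smoking_weights = smoke_w,
    smoking_exposure = setNames(smoking, sample_idv),
    cell_cpg_ids = cpg_ids[cell_idx],
    cell_reference = cellref
  )
  generator <- list(config = config, mu = mu, s_cpg = s_cpg, block = block,
                    causal_idx = causal_idx, eff_raw = eff_raw,
                    cell_idx = cell_idx, smoke_idx = smoke_idx,
                    smoke_w = smoke_w, cellref = cellref, budget = budget,
                    cpg_ids = cpg_ids)

  structure(list(methylation = methylation_matrix(beta, "beta"),
                 phenotypes = phenotypes, kinship = kin, truth = truth,
                 generator = generator),
            class = "cohort_bundle")
}

kinship_from_families <- function(family, ids) {
  n <- length(family)
  kin <- matrix(0, n, n, dimnames = list(ids, ids))
  for (f in unique(family)) {
    m <- which(family == f)
    kin[m, m] <- 0.5
  }
  diag(kin) <- 0.5
  kin
}

#' Simulate a test cohort on a reduced probe set
#'
#' Draws new samples from the training cohort's generative model, keeps a
#' random fraction of probes (emulating a different array), and injects
#' missing values. Optional subgroups with different CpG-trait coupling
#' emulate heterogeneous score transferability across populations.
#'
#' @param train a `cohort_bundle` from [simulate_cohort()].
#' @param probe_fraction fraction of training CpGs retained, in (0,1].
#' @param n_samples number of test samples.
#' @param seed RNG seed.
#' @param missing_rate fraction of entries set missing (default 0.02).
#' @param subgroups optional named list; each element
#'   `list(prop = , coupling = )` gives the subgroup's sampling proportion
#'   and a multiplier on the causal-CpG share of trait variance (coupling 1 =
#'   training-strength coupling; < 1 = weaker coupling).
#' @return `cohort_bundle` for the test cohort.
#' @export
simulate_test_cohort <- function(train, probe_fraction, n_samples, seed,
                                 missing_rate = 0.02, subgroups = NULL) {
  stopifnot(inherits(train, "cohort_bundle"))
  assert_that(probe_fraction > 0 && probe_fraction <= 1,
              "probe_fraction must lie in (0, 1]")
  gen <- train$generator
  cfg <- gen$config
  set.seed(seed)
  n <- n_samples; p <- cfg$n_cpgs
  budget <- gen$budget

  if (is.null(subgroups)) subgroups <- list(all = list(prop = 1, coupling = 1))
  props <- vapply(subgroups, `[[`, numeric(1), "prop")
  grp <- sample(names(subgroups), n, replace = TRUE, prob = props)
  coupling <- vapply(subgroups, `[[`, numeric(1), "coupling")[grp]

  rho <- cfg$within_block_corr
  fac <- matrix(rnorm(n * cfg$n_blocks), n, cfg$n_blocks)
  z <- sqrt(rho) * fac[, gen$block, drop = FALSE] +
    sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
  M <- sweep(sweep(z, 2, gen$s_cpg, "*"), 2, gen$mu, "+")

  cs <- cfg$confounder_spec
  frac <- rdirichlet(n, alpha = c(6, 3, 2, 1.5, 1, rep(0.8, max(0, cs$cell_types - 5)))[seq_len(cs$cell_types)])
  colnames(frac) <- gen$cellref$cell_type_names
  if (length(gen$cell_idx) > 0) {
    mix_beta <- frac %*% t(gen$cellref$means[seq_along(gen$cell_idx), , drop = FALSE]) +
      matrix(rnorm(n * length(gen$cell_idx), 0, 0.02), n, length(gen$cell_idx))
    mix_beta <- pmin(pmax(mix_beta, 1e-4), 1 - 1e-4)
    M[, gen$cell_idx] <- log2(mix_beta / (1 - mix_beta))
  }
  smoking <- rnorm(n)
  if (length(gen$smoke_idx) > 0)
    M[, gen$smoke_idx] <- M[, gen$smoke_idx] +
      cs$smoking_effect * outer(smoking, gen$smoke_w)
  batch <- factor(sample(sprintf("TB%02d", seq_len(max(2, cs$batch_count %/% 2))),
                         n, replace = TRUE))
  nb <- nlevels(batch)
  tshift <- matrix(rnorm(nb * p, 0, cs$batch_effect_sd), nb, p)
  tshift[, gen$causal_idx] <- 0
  M <- M + tshift[as.integer(batch), , drop = FALSE]

  age <- pmin(pmax(rnorm(n, 55, 10), 25), 90)
  sex <- rbinom(n, 1, 0.55)
  sample_idv <- sprintf("T%05d", seq_len(n))

  g <- rep(0, n)
  has_causal <- length(gen$causal_idx) > 0 && budget$causal > 0
  if (has_causal) {
    Mc <- scale(M[, gen$causal_idx, drop = FALSE])
    g <- as.numeric(Mc %*% gen$eff_raw) * coupling
  }
  age_c <- age - mean(age)
  pheno <- assemble_phenotype(
    list(g, age_c, age_c^2, sex, frac[, 1], smoking, rnorm(n)),
    c(if (has_causal) budget$causal else 0, budget$age, budget$age2,
      budget$sex, budget$cell, budget$smoking,
      budget$resid + budget$family + budget$batch +
        if (has_causal) 0 else budget$causal))

  beta <- 1 / (1 + 2^-M)
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  dimnames(beta) <- list(sample_idv, gen$cpg_ids)

  keep_p <- if (probe_fraction < 1) {
    sort(sample(p, round(probe_fraction * p)))
  } else seq_len(p)
  beta <- beta[, keep_p, drop = FALSE]
  if (missing_rate > 0) {
    nmiss <- round(missing_rate * length(beta))
    if (nmiss > 0) beta[sample(length(beta), nmiss)] <- NA
  }

  kin <- diag(0.5, n); dimnames(kin) <- list(sample_idv, sample_idv)
  phenotypes <- data.frame(sample_id = sample_idv, trait = pheno, age = age,
                           sex = sex, batch = as.character(batch),
                           subgroup = grp, family = seq_len(n),
                           stringsAsFactors = FALSE)
  truth <- list(causal_cpg_ids = gen$cpg_ids[gen$causal_idx],
                causal_effects = gen$eff_raw,
                true_cell_fractions = frac,
                true_variance_explained = if (length(gen$causal_idx)) budget$causal else 0,
                smoking_exposure = setNames(smoking, sample_idv),
                coupling = setNames(coupling, sample_idv))
  structure(list(methylation = methylation_matrix(beta, "beta"),
                 phenotypes = phenotypes, kinship = kin, truth = truth,
                 generator = gen),
            class = "cohort_bundle")
}

#' Simulate longitudinal cognitive test scores
#'
#' Per-sample latent intercept (g0) and per-year slope (g1) of general
#' cognitive function, correlated with the cohort trait at the given
#' standardized coefficients, observed through several tests at waves spaced
#' three years apart (ages about 70 to 82, a triennial late-life follow-up design).
#'
#' @param cohort a `cohort_bundle`; its `phenotypes$trait` drives g0/g1.
#' @param n_tests number of cognitive tests (>= 2).
#' @param n_waves number of waves (>= 2), 3 years apart.
#' @param intercept_assoc standardized coefficient of trait on g0.
#' @param slope_assoc standardized coefficient of trait on g1.
#' @param seed RNG seed.
#' @param loadings optional numeric vector of test loadings (default drawn
#'   uniformly in \[0.7, 1.3\]).
#' @param noise_sd test-specific residual SD (default 0.5).
#' @param slope_sd SD of the latent slope in SD-units of g0 per year
#'   (default 0.05).
#' @param dropout per-wave monotone dropout probability (default 0).
#' @return long data.frame (sample_id, wave, age, test, score) with attribute
#'   `truth` (sample_id, g0, g1, baseline_age) and attribute `loadings`.
#' @export
simulate_cognition <- function(cohort, n_tests = 5, n_waves = 5,
                               intercept_assoc = -0.1, slope_assoc = 0,
                               seed = 1, loadings = NULL, noise_sd = 0.5,
                               slope_sd = 0.05, dropout = 0) {
  stopifnot(n_tests >= 2, n_waves >= 2)
  stopifnot(abs(intercept_assoc) <= 1, abs(slope_assoc) <= 1)
  set.seed(seed)
  ph <- as.numeric(scale(cohort$phenotypes$trait))
  n <- length(ph)
  ids <- cohort$phenotypes$sample_id
  g0 <- intercept_assoc * ph + sqrt(1 - intercept_assoc^2) * rnorm(n)
  g1 <- slope_sd * (slope_assoc * ph + sqrt(1 - slope_assoc^2) * rnorm(n))
  if (is.null(loadings)) loadings <- runif(n_tests, 0.7, 1.3)
  stopifnot(length(loadings) == n_tests)
  baseline_age <- rnorm(n, 70, 0.8)

  last_wave <- rep(n_waves, n)
  if (dropout > 0) {
    for (w in 2:n_waves) {
      drop_now <- runif(n) < dropout & last_wave == n_waves
      last_wave[drop_now] <- w - 1
    }
  }
  rows <- vector("list", n_waves * n_tests)
  k <- 0
  for (w in seq_len(n_waves)) {
    dt <- 3 * (w - 1)
    latent <- g0 + g1 * dt
    present <- last_wave >= w
    for (t in seq_len(n_tests)) {
      k <- k + 1
      sc <- loadings[t] * latent + rnorm(n, 0, noise_sd)
      rows[[k]] <- data.frame(sample_id = ids[present], wave = w,
                              age = baseline_age[present] + dt,
                              test = sprintf("test%02d", t),
                              score = sc[present], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- data.frame(sample_id = ids, g0 = g0, g1 = g1,
                                   baseline_age = baseline_age,
                                   stringsAsFactors = FALSE)
  attr(out, "loadings") <- loadings
  out
}
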