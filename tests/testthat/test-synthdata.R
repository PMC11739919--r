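test_that("identical configs give bit-identical cohorts, test cohorts and cognition tables", {
  cfg <- sim_config(n_samples = 120, n_cpgs = 400, n_blocks = 50, n_causal = 5,
                    family_spec = list(n_families = 20, sibs_per_family = 2),
                    seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$methylation$values, b$methylation$values)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$kinship, b$kinship)
  ta <- simulate_test_cohort(a, 0.5, 80, seed = 3)
  tb <- simulate_test_cohort(b, 0.5, 80, seed = 3)
  expect_identical(ta$methylation$values, tb$methylation$values)
  expect_identical(ta$phenotypes, tb$phenotypes)
  ca <- simulate_cognition(a, n_tests = 3, n_waves = 3, seed = 5)
  cb <- simulate_cognition(b, n_tests = 3, n_waves = 3, seed = 5)
  expect_identical(ca, cb)
})

test_that("cohort bundle satisfies its structural invariants", {
  b <- small_cohort()
  expect_s3_class(b$methylation, "methylation_matrix")
  v <- b$methylation$values
  expect_true(all(v > 0 & v < 1))
  expect_identical(rownames(v), b$phenotypes$sample_id)
  expect_identical(rownames(v), rownames(b$kinship))
  expect_true(max(abs(b$kinship - t(b$kinship))) == 0)
  expect_true(all(diag(b$kinship) == 0.5))
  off <- b$kinship[upper.tri(b$kinship)]
  expect_true(all(off >= 0 & off <= 0.5))
  expect_simplex(b$truth$true_cell_fractions)
  expect_length(b$truth$causal_cpg_ids, 10)
})

test_that("a null config without confounder links yields a phenotype unrelated to the methylome", {
  # zero causal sites AND neutralized smoking/batch links; the cell and
  # smoking panel CpGs are excluded since cell composition always feeds both
  # the methylome and the trait
  b0 <- simulate_cohort(sim_config(n_samples = 500, n_cpgs = 600, n_blocks = 100,
                                   n_causal = 0,
                                   confounder_spec = list(cell_types = 6,
                                                          smoking_effect = 0,
                                                          batch_count = 5,
                                                          batch_effect_sd = 0),
                                   family_spec = list(n_families = 30, sibs_per_family = 2),
                                   seed = 11))
  expect_identical(b0$truth$true_variance_explained, 0)
  expect_length(b0$truth$causal_cpg_ids, 0)
  panels <- c(b0$truth$cell_cpg_ids, b0$truth$smoking_cpg_ids)
  m <- beta_to_m(b0$methylation)$values
  m <- m[, setdiff(colnames(m), panels)]
  p <- apply(m, 2, function(x) cor.test(x, b0$phenotypes$trait)$p.value)
  expect_lt(mean(p < 0.05), 0.10)
  expect_gt(mean(p < 0.05), 0.01)
})

test_that("infeasible configs are rejected with a message", {
  expect_error(sim_config(n_samples = 100, n_cpgs = 50, n_causal = 60),
               "n_causal")
  expect_error(sim_config(within_block_corr = 1), "within_block_corr")
  expect_error(sim_config(n_samples = 10,
                          family_spec = list(n_families = 10, sibs_per_family = 2)),
               "family_spec")
})

test_that("within-block correlation matches the configured level", {
  # rho = 0: off-diagonals centred on zero at n = 5,000
  b <- simulate_cohort(sim_config(n_samples = 5000, n_cpgs = 340, n_blocks = 340,
                                  within_block_corr = 0, n_causal = 5,
                                  family_spec = list(n_families = 50, sibs_per_family = 2),
                                  seed = 12))
  m <- beta_to_m(b$methylation)$values[, -seq_len(300)]  # past the cell/smoking panels
  cc <- cor(m)
  expect_lt(abs(mean(cc[upper.tri(cc)])), 0.01)

  # rho = 0.6: mean within-block correlation within +/- 0.02 at n = 2,000
  b2 <- simulate_cohort(sim_config(n_samples = 2000, n_cpgs = 800, n_blocks = 40,
                                   within_block_corr = 0.6, n_causal = 5,
                                   family_spec = list(n_families = 50, sibs_per_family = 2),
                                   seed = 13))
  m2 <- beta_to_m(b2$methylation)$values
  blk <- b2$generator$block
  within <- unlist(lapply(unique(blk)[20:30], function(bl) {
    cc <- cor(m2[, blk == bl])
    cc[upper.tri(cc)]
  }))
  expect_lt(abs(mean(within) - 0.6), 0.02)
})

test_that("causal CpGs explain the configured fraction of phenotype variance", {
  cfg <- sim_config(n_samples = 2000, n_cpgs = 20000, n_causal = 50,
                    target_variance_explained = 0.4, seed = 1)
  b <- simulate_cohort(cfg)
  m <- beta_to_m(b$methylation)
  r2 <- summary(lm(b$phenotypes$trait ~ m$values[, b$truth$causal_cpg_ids]))$r.squared
  expect_lt(abs(r2 - 0.40), 0.05)
})

test_that("test cohorts retain the requested probe subset", {
  b <- small_cohort()
  t1 <- simulate_test_cohort(b, probe_fraction = 1, n_samples = 50, seed = 4,
                             missing_rate = 0)
  expect_identical(colnames(t1$methylation$values), colnames(b$methylation$values))
  expect_false(anyNA(t1$methylation$values))
  t2 <- simulate_test_cohort(b, probe_fraction = 0.5, n_samples = 50, seed = 4)
  expect_identical(ncol(t2$methylation$values), 400L)
  expect_gt(mean(is.na(t2$methylation$values)), 0.015)
  expect_error(simulate_test_cohort(b, probe_fraction = 0, n_samples = 10, seed = 1),
               "probe_fraction")
})

test_that("cognition tables follow the latent growth construction", {
  b <- small_cohort()
  # zero association: latent intercept/slope unrelated to the trait
  c0 <- simulate_cognition(b, n_tests = 3, n_waves = 3, intercept_assoc = 0,
                           slope_assoc = 0, seed = 21)
  tr <- attr(c0, "truth")
  expect_lt(abs(cor(tr$g0, b$phenotypes$trait)), 2.5 / sqrt(nrow(tr)) * 2)
  expect_lt(abs(cor(tr$g1, b$phenotypes$trait)), 2.5 / sqrt(nrow(tr)) * 2)
  # unit loadings, zero noise: score == g0 + g1 * years exactly
  c1 <- simulate_cognition(b, n_tests = 2, n_waves = 4, intercept_assoc = -0.1,
                           seed = 22, loadings = c(1, 1), noise_sd = 0)
  tr1 <- attr(c1, "truth")
  i <- match(c1$sample_id, tr1$sample_id)
  expected <- tr1$g0[i] + tr1$g1[i] * 3 * (c1$wave - 1)
  expect_lt(max(abs(c1$score - expected)), 1e-12)
  # waves are three years apart
  expect_identical(sort(unique(round(c1$age - tr1$baseline_age[i], 6))),
                   c(0, 3, 6, 9))
})

test_that("latent intercept association is recoverable by oracle regression at n = 861", {
  cfg <- sim_config(n_samples = 861, n_cpgs = 400, n_blocks = 50, n_causal = 5,
                    family_spec = list(n_families = 40, sibs_per_family = 2),
                    seed = 31)
  b <- simulate_cohort(cfg)
  cog <- simulate_cognition(b, n_tests = 5, n_waves = 5, intercept_assoc = -0.10,
                            seed = 32)
  tr <- attr(cog, "truth")
  beta <- coef(lm(scale(tr$g0) ~ scale(b$phenotypes$trait)))[2]
  expect_lt(abs(beta - (-0.10)), 0.07)
})

test_that("monotone dropout removes later waves only", {
  b <- small_cohort()
  cd <- simulate_cognition(b, n_tests = 2, n_waves = 4, seed = 23, dropout = 0.2)
  waves <- tapply(cd$wave, cd$sample_id, function(w) sort(unique(w)))
  expect_true(all(vapply(waves, function(w) identical(w, seq_along(w)), logical(1))))
  expect_lt(length(unique(cd$sample_id[cd$wave == 4])),
            length(unique(cd$sample_id[cd$wave == 1])))
})
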