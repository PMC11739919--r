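test_that("probe intersection is sorted and rejects disjoint sets", {
  expect_identical(intersect_probes(c("a", "b", "c"), c("c", "b", "a")), c("a", "b", "c"))
  expect_identical(intersect_probes(c("a", "b", "c"), c("c", "b", "d")), c("b", "c"))
  expect_error(intersect_probes(c("a"), c("b")), "no shared probes")
  b <- small_cohort()
  t1 <- simulate_test_cohort(b, 0.5, 20, seed = 2)
  shared <- intersect_probes(b$methylation, t1$methylation)
  expect_identical(shared, sort(colnames(t1$methylation$values)))
})

test_that("coordinate descent reproduces the single-predictor closed form", {
  set.seed(91)
  x <- rnorm(8); x <- x - mean(x); x <- x / sqrt(mean(x^2))  # 1/n-norm 1
  y <- x * 1.0                                               # OLS coefficient 1
  b <- elnet_fit(matrix(x), y, lambda = 0.5, alpha = 0.5)
  expect_lt(abs(b - 0.6), 1e-6)   # S(1, 0.25)/(1 + 0.25)
  # lasso and ridge limits of the same problem
  expect_lt(abs(elnet_fit(matrix(x), y, lambda = 0.5, alpha = 1) - 0.5), 1e-6)
  expect_lt(abs(elnet_fit(matrix(x), y, lambda = 0.5, alpha = 0) - 1 / 1.5), 1e-6)
})

test_that("coordinate descent matches glmnet at matched penalties on dense instances", {
  set.seed(92)
  n <- 200; p <- 50
  X <- scale(matrix(rnorm(n * p), n, p)) * sqrt(n / (n - 1))  # 1/n-standardized
  beta <- c(rnorm(5), rep(0, p - 5))
  y <- as.numeric(X %*% beta + rnorm(n))
  yc <- y - mean(y); y <- yc / sqrt(mean(yc^2))  # glmnet standardizes y internally
  lams <- c(2, 1, 0.5, 0.2, 0.05)   # glmnet needs a decreasing path for accuracy
  g <- glmnet::glmnet(X, y, alpha = 0.5, lambda = lams, standardize = FALSE,
                      thresh = 1e-14)
  for (lam in c(0.05, 0.2, 0.5)) {
    own <- elnet_fit(X, y, lambda = lam, alpha = 0.5)
    expect_lt(max(abs(as.numeric(coef(g, s = lam, exact = TRUE, x = X, y = y))[-1] - own)),
              1e-4)
  }
  # lasso: non-zero count is non-increasing in lambda
  nz <- vapply(c(0.01, 0.05, 0.2, 0.5, 1),
               function(l) sum(elnet_fit(X, y, lambda = l, alpha = 1) != 0), numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("cross-validated training recovers causal CpGs and honours contracts", {
  set.seed(93)
  n <- 2000; p <- 5000
  mm <- ind_matrix(n, p, seed = 94)
  causal <- sort(sample(p, 50))
  eff <- sample(c(-1, 1), 50, TRUE) * (0.5 + abs(rnorm(50)))
  g <- mm$values[, causal] %*% eff
  y <- setNames(as.numeric(g / sd(g) * sqrt(0.4)) + rnorm(n, 0, sqrt(0.6)),
                rownames(mm$values))
  model <- train_elnet(y, mm, seed = 95)
  expect_gte(mean(colnames(mm$values)[causal] %in% names(model$weights)), 0.8)
  expect_true(all(model$weights != 0))
  expect_identical(model$alpha, 0.5)
  expect_identical(model$n_folds, 20L)
  expect_gt(model$lambda_selected, 0)
  expect_error(train_elnet(y, mm, n_folds = n + 1), "folds")
  expect_error(train_elnet(y, mm, probes = "cg_nope"), "absent")
})

test_that("a pure-noise phenotype trains to an empty or near-empty model", {
  mm <- ind_matrix(1000, 5000, seed = 96)
  nz <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    y <- setNames(rnorm(1000), rownames(mm$values))
    length(train_elnet(y, mm, seed = s)$weights)
  }, numeric(1))
  expect_lte(median(nz), 5)
})

test_that("projection imputes with training means and is order-invariant", {
  model <- structure(list(trait_name = "t",
                          weights = c(cgA = 0.5, cgB = -0.25),
                          intercept = 2,
                          training_cpg_means = c(cgA = 1, cgB = 3),
                          training_cpg_sds = c(cgA = 2, cgB = 0.5)),
                     class = "episcore_model")
  v <- matrix(c(1, 5, 3, 4), 2, 2, dimnames = list(c("s1", "s2"), c("cgA", "cgB")))
  mm <- methylation_matrix(v, "M")
  sc <- project_score(model, mm)
  # s1 sits exactly at the training means -> intercept
  expect_equal(unname(sc["s1"]), 2)
  expect_equal(unname(sc["s2"]), 2 + 0.5 * (5 - 1) / 2 - 0.25 * (4 - 3) / 0.5)
  # column order invariance
  mm_r <- methylation_matrix(v[, c("cgB", "cgA")], "M")
  expect_equal(project_score(model, mm_r), sc)
  # all weight CpGs absent: every score = intercept, flagged
  v2 <- matrix(c(0.2, 0.4), 2, 1, dimnames = list(c("s1", "s2"), "cgZ"))
  expect_warning(sc2 <- project_score(model, methylation_matrix(v2, "M")), "absent")
  expect_equal(unname(sc2), c(2, 2), ignore_attr = TRUE)
  expect_true(attr(sc2, "flagged"))
  # per-sample missing entries impute to the training mean
  v3 <- v; v3[2, "cgB"] <- NA
  sc3 <- project_score(model, methylation_matrix(v3, "M"))
  expect_equal(unname(sc3["s2"]), 2 + 0.5 * (5 - 1) / 2)
  expect_gt(attr(sc3, "imputed_fraction"), 0)
})

test_that("episcore models round-trip through the TSV weight format", {
  model <- structure(list(trait_name = "bmi", weights = c(cgA = 0.5, cgB = -1e-6),
                          intercept = 0.25, training_cpg_means = c(cgA = 1.5, cgB = 2.5),
                          training_cpg_sds = c(cgA = 1, cgB = 2), alpha = 0.5,
                          lambda_selected = 0.033, n_folds = 20L, training_n = 100L,
                          probe_universe_size = 500L),
                     class = "episcore_model")
  path <- tempfile(fileext = ".tsv")
  write_episcore_model(model, path)
  back <- read_episcore_model(path)
  expect_equal(back$weights, model$weights)
  expect_equal(back$intercept, model$intercept)
  expect_equal(back$training_cpg_means, model$training_cpg_means)
  expect_identical(back$probe_universe_size, model$probe_universe_size)
})

test_that("Bayesian posterior-mean scores track elastic-net scores under a simple truth", {
  set.seed(97)
  n <- 600; p <- 400
  mm <- ind_matrix(n, p, seed = 98)
  y <- setNames(sqrt(0.3) * mm$values[, 11] + sqrt(0.7) * rnorm(n), rownames(mm$values))
  post <- run_bayes_ewas(y, mm, NULL, bayes_config(n_iterations = 400, burn_in = 150, seed = 5))
  model <- train_elnet(y, mm, seed = 6)
  test <- ind_matrix(300, p, seed = 99)
  ctr <- colMeans(mm$values); scl <- apply(mm$values, 2, sd)
  bs <- bayes_score(post, test, ctr, scl)
  es <- project_score(model, test)
  expect_gt(cor(bs, es), 0.8)
  # all-zero posterior means give a constant score
  post0 <- post
  post0$table$mean_effect <- 0
  expect_identical(var(bayes_score(post0, test, ctr, scl)), 0)
  # sign flip negates about the intercept
  postn <- post
  postn$table$mean_effect <- -postn$table$mean_effect
  expect_lt(max(abs(bayes_score(postn, test, ctr, scl) + bs)), 1e-10)
})

test_that("incremental R2 satisfies its nesting and invariance identities", {
  set.seed(100)
  n <- 2000
  covs <- data.frame(age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5))
  g <- rnorm(n)
  trait <- sqrt(0.2) * scale(g) + 0.1 * scale(covs$age) + sqrt(0.78) * rnorm(n)
  score <- g   # a score explaining 20% of trait variance, orthogonal to age/sex
  ev <- incremental_r2(as.numeric(trait), score, covs)
  expect_lt(abs(ev$overall$incremental_r2 - 0.20), 0.04)
  expect_gte(ev$overall$full_r2, ev$overall$base_r2)
  expect_equal(ev$overall$incremental_r2, ev$overall$full_r2 - ev$overall$base_r2)
  # affine rescaling of the score changes nothing
  ev2 <- incremental_r2(as.numeric(trait), 3 - 2 * score, covs)
  expect_lt(abs(ev2$overall$incremental_r2 - ev$overall$incremental_r2), 1e-10)
  # orthogonal score: incremental R2 near zero
  ev0 <- incremental_r2(as.numeric(trait), rnorm(n), covs)
  expect_lt(ev0$overall$incremental_r2, 2.5 * 2 / n + 0.004)
  # score identical to the trait: full R2 = 1
  # score identical to the trait: R's lm warns about the perfect fit
  ev1 <- suppressWarnings(incremental_r2(as.numeric(trait), as.numeric(trait), covs))
  expect_equal(ev1$overall$full_r2, 1)
  expect_equal(ev1$overall$incremental_r2, 1 - ev1$overall$base_r2)
  # subgroups: small groups flagged, pooled model uses subgroup dummies
  grp <- c(rep("big", n - 20), rep("tiny", 20))
  ev3 <- incremental_r2(as.numeric(trait), score, covs, subgroup = grp)
  expect_identical(ev3$by_subgroup$small_sample, c(FALSE, TRUE))
  expect_identical(ev3$by_subgroup$subgroup, c("big", "tiny"))
})

test_that("projected scores generalize to a held-out cohort from the same model", {
  cfg <- sim_config(n_samples = 800, n_cpgs = 2500, n_blocks = 250, n_causal = 30,
                    target_variance_explained = 0.4,
                    family_spec = list(n_families = 80, sibs_per_family = 2),
                    seed = 111)
  b <- simulate_cohort(cfg)
  test <- simulate_test_cohort(b, probe_fraction = 0.9, n_samples = 700, seed = 112)
  mc <- precorrect_m_values(beta_to_m(b$methylation), b$phenotypes)
  ph <- residualize_phenotype(b)
  probes <- intersect_probes(mc, test$methylation)
  model <- train_elnet(ph, mc, probes, seed = 113)
  tm <- precorrect_m_values(beta_to_m(test$methylation), test$phenotypes)
  sc <- project_score(model, tm)
  expect_lt(abs(cor(sc, test$phenotypes$trait) - sqrt(model$cv_r2)), 0.05)
})
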