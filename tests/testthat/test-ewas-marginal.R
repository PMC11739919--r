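test_that("single-CpG statistics match hand-computed OLS on printed points", {
  x <- c(1.2, -0.7, 0.3, 2.1, -1.5, 0.6)
  y <- c(0.9, -0.2, 0.1, 1.7, -1.1, 0.4)
  v <- matrix(x, 6, 1, dimnames = list(paste0("s", 1:6), "cg1"))
  mm <- methylation_matrix(v, "M")
  res <- run_marginal_ewas(setNames(y, rownames(v)), mm)
  xs <- as.numeric(scale(x))
  fit <- summary(lm(y ~ xs))$coefficients["xs", ]
  expect_lt(abs(res$table$t - fit["t value"]), 1e-10)
  expect_lt(abs(res$table$p - fit["Pr(>|t|)"]), 1e-10)
  expect_lt(abs(res$table$effect - fit["Estimate"]), 1e-10)
})

test_that("per-CpG statistics match a closed-form OLS oracle with covariates", {
  mm <- ind_matrix(300, 150, seed = 51)
  set.seed(52)
  covs <- data.frame(c1 = rnorm(300), c2 = rbinom(300, 1, 0.4))
  y <- setNames(0.3 * mm$values[, 5] + 0.5 * covs$c1 + rnorm(300), rownames(mm$values))
  res <- run_marginal_ewas(y, mm, covs)
  for (j in sample(150, 100)) {
    d <- data.frame(y = y, x = as.numeric(scale(mm$values[, j])), covs)
    sm <- summary(lm(y ~ x + c1 + c2, data = d))$coefficients["x", ]
    i <- match(colnames(mm$values)[j], res$table$cpg_id)
    expect_lt(abs(res$table$effect[i] - sm[1]), 1e-8)
    expect_lt(abs(res$table$se[i] - sm[2]), 1e-8)
    expect_lt(abs(res$table$p[i] - sm[4]), 1e-8)
  }
  # p is consistent with t and the residual df
  expect_lt(max(abs(res$table$p -
                      2 * pt(-abs(res$table$t), res$table$n_used - ncol(covs) - 2))),
            1e-10)
})

test_that("a standardized effect of 0.1 at n = 2000 gives t near its power prediction", {
  set.seed(53)
  n <- 2000
  mm <- ind_matrix(n, 20, seed = 54)
  y <- setNames(0.1 * mm$values[, 3] + sqrt(1 - 0.01) * rnorm(n), rownames(mm$values))
  res <- run_marginal_ewas(y, mm)
  expect_lt(abs(res$table$t[3] - 0.1 * sqrt(n)), 1.5)
})

test_that("CpGs with missing samples are tested on complete cases", {
  mm <- ind_matrix(120, 30, seed = 55)
  mm$values[1:10, 4] <- NA
  set.seed(56)
  y <- setNames(rnorm(120), rownames(mm$values))
  covs <- data.frame(c1 = rnorm(120))
  res <- run_marginal_ewas(y, mm, covs)
  i <- match(colnames(mm$values)[4], res$table$cpg_id)
  expect_identical(res$table$n_used[i], 110L)
  obs <- !is.na(mm$values[, 4])
  d <- data.frame(y = y[obs], x = as.numeric(scale(mm$values[obs, 4])), c1 = covs$c1[obs])
  sm <- summary(lm(y ~ x + c1, data = d))$coefficients["x", ]
  expect_lt(abs(res$table$t[i] - sm[3]), 1e-8)
})

test_that("degenerate and collinear inputs follow the error contracts", {
  mm <- ind_matrix(50, 10, seed = 57)
  mm$values[, 2] <- 1  # zero-variance probe
  y <- setNames(rnorm(50), rownames(mm$values))
  res <- run_marginal_ewas(y, mm)
  expect_identical(res$dropped_cpgs, colnames(mm$values)[2])
  expect_false(colnames(mm$values)[2] %in% res$table$cpg_id)
  covs <- data.frame(a = rnorm(50))
  covs$b <- covs$a
  expect_error(run_marginal_ewas(y, mm, covs), "collinear")
})

test_that("significance calling sorts by p with lexicographic ties and respects thresholds", {
  tab <- data.frame(cpg_id = c("cgB", "cgA", "cgC"), effect = 1, se = 1,
                    t = c(6, 6, 2), p = c(1e-9, 1e-9, 1e-7), n_used = 100)
  res <- structure(list(table = tab, trait_name = "t", model_tag = "base",
                        lambda_gc = 1, df = 97, dropped_cpgs = character(0)),
                   class = "ewas_result")
  expect_identical(call_significant(res), c("cgA", "cgB"))
  expect_identical(call_significant(res, 1), c("cgA", "cgB", "cgC"))
  empty <- res; empty$table <- tab[0, ]
  expect_identical(call_significant(empty), character(0))
  # non-increasing in stricter thresholds
  thresholds <- c(1, 1e-6, 1e-8, 1e-10)
  counts <- vapply(thresholds, function(th) length(call_significant(res, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("lambda_gc is calibrated on uniform p-values", {
  set.seed(58)
  expect_lt(abs(lambda_gc(runif(20000)) - 1), 0.03)
})

test_that("independent-signal counting matches block eigenstructure", {
  set.seed(59)
  Q <- qr.Q(qr(matrix(rnorm(100 * 10), 100, 10)))
  dimnames(Q) <- list(sprintf("s%03d", 1:100), sprintf("cg%02d", 1:10))
  expect_identical(count_independent_signals(methylation_matrix(Q, "M"), colnames(Q)), 8L)
  F5 <- matrix(rnorm(100 * 5), 100, 5)
  B <- F5[, rep(1:5, each = 4)]
  dimnames(B) <- list(sprintf("s%03d", 1:100), sprintf("cg%02d", 1:20))
  expect_identical(count_independent_signals(methylation_matrix(B, "M"), colnames(B)), 4L)
  expect_identical(count_independent_signals(methylation_matrix(B, "M"), "cg03"), 1L)
})

test_that("cross-trait overlap is plain set intersection", {
  expect_identical(cross_trait_overlap(list(a = c("x", "y"), b = c("z"))), character(0))
  expect_identical(cross_trait_overlap(list(a = c("y", "x"), b = c("x", "y"))), c("x", "y"))
  expect_identical(cross_trait_overlap(list(t1 = c("A", "B", "C"), t2 = c("B", "C"), t3 = "C")), "C")
  expect_error(cross_trait_overlap(list(a = "x")), ">= 2")
})

test_that("manifest annotation keeps unmapped CpGs flagged and copies fields verbatim", {
  man <- data.frame(cpg_id = c("cg1", "cg2"), chrom = c("chr1", "chr7"),
                    position = c(100L, 2000L), gene = c("ABCG1", ""))
  out <- annotate_cpgs(c("cg1", "cg2", "cg9"), man)
  expect_identical(nrow(out), 3L)
  expect_identical(out$gene[1], "ABCG1")
  expect_identical(out$chrom[2], "chr7")
  expect_true(out$unmapped[3])
  expect_identical(out$gene[3], "")
  man2 <- rbind(man, data.frame(cpg_id = "cg1", chrom = "chrX", position = 1L, gene = "Z"))
  expect_warning(out2 <- annotate_cpgs("cg1", man2), "duplicate")
  expect_identical(out2$chrom, "chr1")
})

test_that("adding methylome PCs reduces confounded false positives", {
  cfg <- sim_config_confounded(seed = 61, n_samples = 600, n_cpgs = 3000)
  b <- simulate_cohort(cfg)
  mc <- precorrect_m_values(beta_to_m(b$methylation), b$phenotypes[, c("age", "sex")])
  ph <- residualize_phenotype(b)
  cells <- deconvolve_cells(b$methylation, b$truth$cell_reference)
  covs <- data.frame(cells[, -1])
  base <- run_marginal_ewas(ph, mc, covs)
  pcs <- methylome_pcs(mc, 20)
  pcadj <- run_marginal_ewas(ph, mc, cbind(covs, pcs$scores), model_tag = "pc_adjusted")
  null_ids <- setdiff(colnames(mc$values), b$truth$causal_cpg_ids)
  fp <- function(res) {
    tab <- res$table[res$table$cpg_id %in% null_ids, ]
    sum(tab$p < 1e-4, na.rm = TRUE)
  }
  expect_lt(fp(pcadj), fp(base))
  expect_lt(pcadj$lambda_gc, base$lambda_gc)
})
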