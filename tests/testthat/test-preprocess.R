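test_that("beta/M transforms are exact inverses with the documented anchor points", {
  v <- matrix(c(0.5, 0.8, 0.2, 0.999), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  mb <- methylation_matrix(v, "beta")
  m <- beta_to_m(mb)
  expect_equal(m$values["a", "x"], 0)
  expect_equal(m$values["b", "x"], 2)  # log2(0.8/0.2)
  expect_identical(m$scale, "M")
  back <- m_to_beta(m)
  expect_lt(max(abs(back$values - v)), 1e-10)
  m2 <- beta_to_m(m_to_beta(m))
  expect_lt(max(abs(m2$values - m$values)), 1e-10)
  expect_error(beta_to_m(m), "beta-scale")
  # missing stays missing
  v[1, 2] <- NA
  expect_true(is.na(beta_to_m(methylation_matrix(v, "beta"))$values[1, 2]))
})

test_that("quantile normalization equalizes per-sample distributions", {
  m <- methylation_matrix(matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE,
                                 dimnames = list(c("a", "b"), c("x", "y", "z"))), "M")
  qn <- quantile_normalize(m)
  expect_equal(unname(qn$values["a", ]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values["b", ]), c(2.5, 3.5, 4.5))
  # identical samples unchanged
  m2 <- methylation_matrix(matrix(rep(c(0.3, 1.2, -0.5, 2), 2), 2, 4, byrow = TRUE,
                                  dimnames = list(c("a", "b"), paste0("c", 1:4))), "M")
  expect_equal(quantile_normalize(m2)$values, m2$values)
  # arbitrary input: sorted rows identical afterwards
  set.seed(1)
  m3 <- methylation_matrix(matrix(rnorm(60), 4, 15,
                                  dimnames = list(paste0("s", 1:4), paste0("c", 1:15))), "M")
  q3 <- quantile_normalize(m3)$values
  sorted <- apply(q3, 1, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  # all-missing sample rejected
  bad <- m3
  bad$values[2, ] <- NA
  expect_error(quantile_normalize(bad), "all-missing")
})

test_that("outlier masking follows the single-pass SD rule", {
  expect_identical(remove_outliers(c(0, 0, 0, 100), k_sd = 1, cap = 1),
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(remove_outliers(rep(3, 10))))
  expect_true(all(remove_outliers(c(rnorm(20), 50), k_sd = Inf)))
  expect_warning(remove_outliers(c(rep(0, 5), 10, -10), k_sd = 1, cap = 0.01),
                 "cap")
})

test_that("kinship LMM reduces to OLS when 2K is the identity", {
  set.seed(41)
  n <- 200
  age <- rnorm(n, 50, 10)
  X <- cbind(1, age - mean(age), (age - mean(age))^2, rbinom(n, 1, 0.5))
  y <- setNames(X %*% c(1, 0.05, 0.001, 0.3) + rnorm(n), sprintf("S%03d", 1:n))
  K <- diag(0.5, n); dimnames(K) <- list(names(y), names(y))
  fit <- fit_kinship_lmm(y, X, K)
  expect_identical(fit$variance_components$sigma2_g, 0)
  expect_lt(max(abs(fit$residuals - lm.fit(X, y)$residuals)), 1e-8)
  # exact linear response leaves ~zero residuals
  y2 <- setNames(as.numeric(X %*% c(1, 0.05, 0.001, 0.3)), names(y))
  expect_lt(max(abs(fit_kinship_lmm(y2, X, K)$residuals)), 1e-6)
  # contract violations
  expect_error(fit_kinship_lmm(y, cbind(X, X[, 2]), K), "singular")
  Kbad <- K; Kbad[1, 2] <- Kbad[2, 1] <- 5
  expect_error(fit_kinship_lmm(y, X, Kbad), "positive semidefinite")
})

test_that("kinship LMM recovers the variance ratio from sib-pair data", {
  set.seed(42)
  n <- 4000
  fam <- rep(seq_len(n / 2), each = 2)
  ids <- sprintf("S%04d", seq_len(n))
  K <- episcope:::kinship_from_families(fam, ids)
  age <- rnorm(n, 50, 10)
  X <- cbind(1, age - mean(age), (age - mean(age))^2, rbinom(n, 1, 0.5))
  make_y <- function(sg, se) setNames(as.numeric(
    X %*% c(1, 0.05, 0.001, 0.3) + sqrt(sg) * rnorm(n / 2)[fam] + sqrt(se) * rnorm(n)),
    ids)
  fit1 <- fit_kinship_lmm(make_y(1, 1), X, K)
  expect_lt(abs(fit1$variance_components$lambda - 1), 0.2)
  # the 1-D search discriminates low from high relatedness ratios
  fit_lo <- fit_kinship_lmm(make_y(0.25, 1), X, K)
  fit_hi <- fit_kinship_lmm(make_y(4, 1), X, K)
  expect_lt(fit_lo$variance_components$lambda, 0.6)
  expect_gt(fit_hi$variance_components$lambda, 2)
  # conditional residuals shrink the family effect relative to marginal
  fitm <- fit_kinship_lmm(make_y(1, 1), X, K, residual_type = "marginal")
  expect_gt(var(fitm$residuals), var(fit1$residuals))
})

test_that("M-value pre-correction equals per-CpG regression residuals", {
  b <- small_cohort()
  m <- beta_to_m(b$methylation)
  mc <- precorrect_m_values(m, b$phenotypes)
  expect_identical(mc$scale, "corrected-M")
  X <- model.matrix(~ age + sex + factor(batch), data = b$phenotypes)
  set.seed(43)
  for (j in sample(ncol(m$values), 100)) {
    oracle <- lm.fit(X, m$values[, j])$residuals
    expect_lt(max(abs(mc$values[, j] - oracle)), 1e-8)
  }
  # idempotence: residuals are already orthogonal to the design
  mc2 <- precorrect_m_values(mc, b$phenotypes)
  expect_lt(max(abs(mc2$values - mc$values)), 1e-8)
  # a CpG that is an exact linear function of age residualizes to zero
  m$values[, 5] <- 0.2 * b$phenotypes$age - 3
  expect_lt(max(abs(precorrect_m_values(m, b$phenotypes)$values[, 5])), 1e-8)
})

test_that("pre-correction preserves missingness and merges singleton batches", {
  b <- small_cohort()
  m <- beta_to_m(b$methylation)
  m$values[3, 7] <- NA
  mc <- precorrect_m_values(m, b$phenotypes)
  expect_true(is.na(mc$values[3, 7]))
  expect_identical(sum(is.na(mc$values)), 1L)
  # covariates orthogonal to a CpG: output is input minus its mean
  cov0 <- data.frame(age = rep(c(1, 2), length.out = nrow(m$values)),
                     sex = rep(c(0, 1, 0, 1), length.out = nrow(m$values)))
  x <- rep(c(1, -1, -1, 1), length.out = nrow(m$values)) + 5
  m2 <- m
  m2$values[, 1] <- x
  out <- precorrect_m_values(m2, cov0)$values[, 1]
  expect_lt(max(abs(out - (x - mean(x)))), 1e-10)
  ph <- b$phenotypes
  ph$batch[1] <- "LONE"
  expect_warning(precorrect_m_values(m, ph), "single-sample batch")
})

test_that("phenotype residualization removes age, age squared and sex", {
  b <- covariate_cohort()
  ph <- residualize_phenotype(b)
  expect_length(ph$residuals, nrow(b$phenotypes))
  age_c <- b$phenotypes$age - mean(b$phenotypes$age)
  expect_lt(abs(cor(ph$residuals, age_c)), 0.05)
  expect_lt(abs(cor(ph$residuals, age_c^2)), 0.05)
  expect_lt(abs(cor(ph$residuals, b$phenotypes$sex)), 0.05)
  expect_gt(ph$variance_components$sigma2_e, 0)
})
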