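#' Beta to M-value transform
#'
#' M = log2(beta / (1 - beta)), after clipping betas to
#' \[eps, 1 - eps\] to avoid infinities at the boundaries. Missing values
#' stay missing.
#'
#' @param betas beta-scale [methylation_matrix()].
#' @param eps boundary clip (default 1e-6).
#' @return M-scale `methylation_matrix`.
#' @export
beta_to_m <- function(betas, eps = 1e-6) {
  stopifnot(inherits(betas, "methylation_matrix"))
  assert_that(betas$scale == "beta", "beta_to_m expects a beta-scale matrix")
  b <- pmin(pmax(betas$values, eps), 1 - eps)
  m <- log2(b / (1 - b))
  methylation_matrix(m, "M")
}

#' M-value to beta transform (inverse of [beta_to_m()])
#' @param mvals M-scale [methylation_matrix()].
#' @return beta-scale `methylation_matrix`.
#' @export
m_to_beta <- function(mvals) {
  stopifnot(inherits(mvals, "methylation_matrix"))
  assert_that(mvals$scale == "M", "m_to_beta expects an M-scale matrix")
  methylation_matrix(1 / (1 + 2^-mvals$values), "beta")
}

#' Quantile normalization across samples
#'
#' Each sample's sorted values are replaced by the across-sample mean of
#' order statistics; ties receive the mean of tied ranks (delegated to
#' \code{limma::normalizeQuantiles}).
#'
#' @param mat a [methylation_matrix()] (any scale; >= 2 samples).
#' @return `methylation_matrix` on the same scale.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(inherits(mat, "methylation_matrix"))
  assert_that(nrow(mat$values) >= 2, "quantile normalization needs >= 2 samples")
  all_missing <- rowSums(!is.na(mat$values)) == 0
  assert_that(!any(all_missing),
              paste("all-missing sample(s):",
                    paste(rownames(mat$values)[all_missing], collapse = ", ")))
  # limma normalizes columns; our samples are rows
  qn <- t(limma::normalizeQuantiles(t(mat$values), ties = TRUE))
  dimnames(qn) <- dimnames(mat$values)
  out <- mat
  out$values <- qn
  out
}

#' SD-based outlier mask
#'
#' Keep-mask that is FALSE where |x - mean| > k_sd * SD, computed once
#' (non-iterative). Zero-variance input keeps everything. A warning is
#' emitted when more than `cap` of the values are removed.
#'
#' @param values numeric vector (NAs kept, flagged TRUE).
#' @param k_sd SD multiplier (> 0, default 4).
#' @param cap warn when the removed fraction exceeds this (default 0.01).
#' @return logical keep-mask, same length as `values`.
#' @export
remove_outliers <- function(values, k_sd = 4, cap = 0.01) {
  assert_that(is.numeric(k_sd) && k_sd > 0, "k_sd must be > 0")
  m <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(values)))
  keep <- is.na(values) | abs(values - m) <= k_sd * s
  removed <- mean(!keep)
  if (removed > cap)
    warning(sprintf("remove_outliers: %.2f%% of values removed (cap %.2f%%)",
                    100 * removed, 100 * cap))
  keep
}

#' Kinship linear mixed model and phenotype residualization
#'
#' Fits y = Xb + g + e with g ~ N(0, sigma2_g * 2K) and e ~ N(0, sigma2_e I)
#' by REML: after eigendecomposition of 2K the restricted likelihood is
#' profiled down to a one-dimensional search over log(lambda),
#' lambda = sigma2_g / sigma2_e, solved by Brent's method on \[-10, 10\]
#' (tolerance 1e-6). When 2K is identity-equivalent the random effect is
#' unidentifiable and absorbed: sigma2_g is set to 0 and the fit reduces to
#' OLS.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (must include an intercept column).
#' @param K kinship matrix (symmetric PSD; diag 0.5, sibs 0.5). The model
#'   uses 2K, so a sibling pair shares the full family effect.
#' @param residual_type "conditional" (y - Xb - BLUP g, default) or
#'   "marginal" (y - Xb).
#' @param trait_name label stored in the result.
#' @return object of class `residualized_phenotype`: `residuals` (named),
#'   `variance_components` (sigma2_g, sigma2_e, lambda), `fixed_effects`
#'   (coefficient table), `residual_type`, `trait_name`.
#' @export
fit_kinship_lmm <- function(y, X, K, residual_type = c("conditional", "marginal"),
                            trait_name = "trait") {
  residual_type <- match.arg(residual_type)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  assert_that(max(abs(K - t(K))) < 1e-8, "kinship matrix must be symmetric")
  q <- ncol(X)
  assert_that(qr(X)$rank == q, "singular fixed-effect design")

  G <- 2 * K
  ids <- names(y) %||% rownames(K)

  if (max(abs(G - diag(n))) < 1e-8) {
    fit <- lm.fit(X, y)
    res <- setNames(as.numeric(fit$residuals), ids)
    sigma2_e <- sum(res^2) / (n - q)
    return(structure(list(trait_name = trait_name, residuals = res,
                          variance_components = list(sigma2_g = 0,
                                                     sigma2_e = sigma2_e,
                                                     lambda = 0),
                          fixed_effects = coef_table(fit$coefficients, colnames(X)),
                          residual_type = residual_type),
                     class = "residualized_phenotype"))
  }

  ed <- eigen(G, symmetric = TRUE)
  assert_that(min(ed$values) > -1e-8, "kinship matrix is not positive semidefinite")
  D <- pmax(ed$values, 0)
  yt <- crossprod(ed$vectors, y)
  Xt <- crossprod(ed$vectors, X)

  reml_nll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- lam * D + 1
    Xw <- Xt / w
    XtWX <- crossprod(Xt, Xw)
    b <- solve(XtWX, crossprod(Xw, yt))
    r <- yt - Xt %*% b
    rss <- sum(r^2 / w)
    s2 <- rss / (n - q)
    0.5 * ((n - q) * log(s2) + sum(log(w)) + determinant(XtWX, logarithm = TRUE)$modulus[1])
  }
  opt <- optimize(reml_nll, interval = c(-10, 10), tol = 1e-6)
  lam <- exp(opt$minimum)

  w <- lam * D + 1
  Xw <- Xt / w
  XtWX <- crossprod(Xt, Xw)
  b <- solve(XtWX, crossprod(Xw, yt))
  rt <- yt - Xt %*% b
  sigma2_e <- sum(rt^2 / w) / (n - q)
  sigma2_g <- lam * sigma2_e
  # BLUP of g in the rotated basis: shrink marginal residuals by lam*D/(lam*D+1)
  g_hat <- ed$vectors %*% (rt * (lam * D / w))
  marginal <- as.numeric(y - X %*% b)
  res <- if (residual_type == "conditional") marginal - as.numeric(g_hat) else marginal
  structure(list(trait_name = trait_name, residuals = setNames(res, ids),
                 variance_components = list(sigma2_g = sigma2_g,
                                            sigma2_e = sigma2_e, lambda = lam),
                 fixed_effects = coef_table(as.numeric(b), colnames(X)),
                 residual_type = residual_type),
            class = "residualized_phenotype")
}

coef_table <- function(b, nm) {
  data.frame(term = nm %||% paste0("b", seq_along(b)), estimate = as.numeric(b),
             stringsAsFactors = FALSE)
}

#' Residualize a cohort trait on age, age-squared, sex and family structure
#'
#' Convenience wrapper: builds the fixed-effect design (intercept,
#' mean-centred age, its square, sex) from the cohort phenotype table and
#' calls [fit_kinship_lmm()] with the cohort kinship matrix.
#'
#' @param bundle a `cohort_bundle`.
#' @param trait column of `bundle$phenotypes` to residualize (default "trait").
#' @param residual_type passed to [fit_kinship_lmm()].
#' @return `residualized_phenotype`.
#' @export
residualize_phenotype <- function(bundle, trait = "trait",
                                  residual_type = c("conditional", "marginal")) {
  residual_type <- match.arg(residual_type)
  ph <- bundle$phenotypes
  age_c <- ph$age - mean(ph$age)
  X <- cbind(intercept = 1, age = age_c, age2 = age_c^2, sex = ph$sex)
  y <- setNames(ph[[trait]], ph$sample_id)
  fit_kinship_lmm(y, X, bundle$kinship, residual_type = residual_type,
                  trait_name = trait)
}

#' Pre-correct M-values for technical covariates
#'
#' Per CpG, replaces M-values by the residuals of a linear regression on
#' intercept + age + sex (+ batch dummies when a batch column is supplied).
#' Missing entries are ignored per CpG and remain missing. Batches with a
#' single sample are merged into the reference level with a warning.
#'
#' @param mat M-scale [methylation_matrix()].
#' @param covariates data.frame with `age`, `sex` and optionally `batch`,
#'   rows aligned with the samples of `mat`.
#' @return corrected-M [methylation_matrix()].
#' @export
precorrect_m_values <- function(mat, covariates) {
  stopifnot(inherits(mat, "methylation_matrix"))
  assert_that(mat$scale %in% c("M", "corrected-M"),
              "precorrect_m_values expects M-scale input")
  n <- nrow(mat$values)
  stopifnot(nrow(covariates) == n)
  X <- cbind(intercept = 1, age = covariates$age, sex = covariates$sex)
  if (!is.null(covariates$batch)) {
    batch <- factor(covariates$batch)
    tab <- table(batch)
    if (any(tab < 2)) {
      warning(sprintf("merging %d single-sample batch(es) into the reference level",
                      sum(tab < 2)))
      levels(batch)[levels(batch) %in% names(tab)[tab < 2]] <- levels(batch)[match(names(tab)[tab >= 2][1], levels(batch))]
    }
    if (nlevels(batch) > 1) {
      dummies <- model.matrix(~ batch)[, -1, drop = FALSE]
      X <- cbind(X, dummies)
    }
  }
  V <- mat$values
  has_na <- colSums(is.na(V)) > 0
  out <- V
  if (any(!has_na)) {
    qrX <- qr(X)
    out[, !has_na] <- qr.resid(qrX, V[, !has_na, drop = FALSE])
  }
  for (j in which(has_na)) {
    obs <- !is.na(V[, j])
    if (sum(obs) > ncol(X)) {
      out[obs, j] <- lm.fit(X[obs, , drop = FALSE], V[obs, j])$residuals
    } else {
      out[obs, j] <- V[obs, j] - mean(V[obs, j])
    }
  }
  res <- mat
  res$values <- out
  res$scale <- "corrected-M"
  res
}
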