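#' Probe intersection between cohorts
#'
#' Sorted intersection of CpG IDs; training features must be restricted to
#' this set before model fitting so weights project onto the test array.
#'
#' @param train,test [methylation_matrix()] objects (or character ID vectors).
#' @return sorted character vector of shared CpG IDs.
#' @export
intersect_probes <- function(train, test) {
  a <- if (inherits(train, "methylation_matrix")) cpg_ids(train) else train
  b <- if (inherits(test, "methylation_matrix")) cpg_ids(test) else test
  shared <- sort(intersect(a, b))
  assert_that(length(shared) > 0, "no shared probes between cohorts")
  shared
}

#' Elastic net at a fixed penalty by coordinate descent
#'
#' Minimizes 1/(2n) ||y - X b||^2 + lambda (alpha |b|_1 + (1-alpha)/2 |b|_2^2)
#' by cyclic coordinate descent with the closed-form single-coordinate
#' update b_j = S(rho_j, lambda alpha) / (x_j'x_j/n + lambda (1-alpha)).
#' Intended for small dense instances and analytic checks; full
#' cross-validated training goes through [train_elnet()].
#'
#' @param X predictor matrix (used as given; no internal standardization).
#' @param y response (centred internally; no intercept is fit).
#' @param lambda penalty > 0.
#' @param alpha elastic-net mixing in \[0,1\] (1 = lasso, 0 = ridge).
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_iter maximum passes.
#' @return numeric coefficient vector (length ncol(X)).
#' @export
elnet_fit <- function(X, y, lambda, alpha = 0.5, tol = 1e-10, max_iter = 10000) {
  X <- as.matrix(X)
  n <- nrow(X)
  yc <- y - mean(y)
  p <- ncol(X)
  b <- numeric(p)
  xtx_n <- colSums(X^2) / n
  r <- yc
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      rho <- sum(X[, j] * r) / n + xtx_n[j] * b[j]
      bj <- sign(rho) * max(abs(rho) - lambda * alpha, 0) /
        (xtx_n[j] + lambda * (1 - alpha))
      if (bj != b[j]) {
        r <- r - X[, j] * (bj - b[j])
        delta <- max(delta, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    if (delta < tol) break
  }
  b
}

#' Train an elastic-net EpiScore
#'
#' Cross-validated elastic net (default alpha 0.5, 20 folds) of a
#' residualized trait on standardized CpG M-values restricted to a probe
#' universe, via glmnet's coordinate descent over a log-spaced lambda path
#' (100 values, min/max ratio 1e-3); lambda minimizing the cross-validated
#' MSE is selected and CpGs with non-zero coefficients are retained.
#' Coefficients are stored on the standardized scale together with the
#' training means/SDs so projection reproduces the training scaling and can
#' mean-impute missing probes.
#'
#' @param pheno `residualized_phenotype` or numeric vector.
#' @param mat training [methylation_matrix()] (M or corrected-M scale).
#' @param probes probe universe (e.g. from [intersect_probes()]); NULL uses
#'   all CpGs of `mat`.
#' @param alpha elastic-net mixing (default 0.5).
#' @param n_folds CV folds (default 20).
#' @param seed seed for the fold assignment.
#' @return object of class `episcore_model`: `weights` (named non-zero
#'   coefficients, standardized scale), `intercept`, `training_cpg_means`,
#'   `training_cpg_sds`, `alpha`, `lambda_selected`, `n_folds`, `training_n`,
#'   `probe_universe_size`, `cv_r2` (CV estimate of score-trait R^2).
#' @export
train_elnet <- function(pheno, mat, probes = NULL, alpha = 0.5, n_folds = 20,
                        seed = 1) {
  stopifnot(inherits(mat, "methylation_matrix"))
  y <- if (inherits(pheno, "residualized_phenotype")) pheno$residuals else pheno
  trait_name <- if (inherits(pheno, "residualized_phenotype")) pheno$trait_name else "trait"
  if (is.null(probes)) probes <- cpg_ids(mat)
  missing_probes <- setdiff(probes, cpg_ids(mat))
  assert_that(length(missing_probes) == 0, "probes absent from training matrix")
  n <- nrow(mat$values)
  assert_that(n_folds <= n, "more folds than samples")
  V <- mat$values[, probes, drop = FALSE]
  if (anyNA(V)) {
    mu <- colMeans(V, na.rm = TRUE)
    idx <- which(is.na(V), arr.ind = TRUE)
    V[idx] <- mu[idx[, 2]]
  }
  std <- standardize_columns(V)
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = n))
  cv <- glmnet::cv.glmnet(std$x, as.numeric(y), alpha = alpha, foldid = foldid,
                          standardize = FALSE, nlambda = 100,
                          lambda.min.ratio = 1e-3)
  co <- as.matrix(coef(cv, s = "lambda.min"))
  w <- co[-1, 1]
  nz <- which(w != 0)
  i_min <- which(cv$lambda == cv$lambda.min)
  cv_r2 <- 1 - cv$cvm[i_min] / var(as.numeric(y))
  structure(list(trait_name = trait_name,
                 weights = w[nz],
                 intercept = co[1, 1],
                 training_cpg_means = std$center[nz],
                 training_cpg_sds = std$scale[nz],
                 alpha = alpha, lambda_selected = cv$lambda.min,
                 n_folds = as.integer(n_folds), training_n = n,
                 probe_universe_size = length(probes),
                 cv_r2 = max(cv_r2, 0)),
            class = "episcore_model")
}

#' @export
print.episcore_model <- function(x, ...) {
  cat(sprintf("<episcore_model> trait=%s non-zero CpGs=%d lambda=%.4g alpha=%.2f (n=%d, universe=%d)\n",
              x$trait_name, length(x$weights), x$lambda_selected, x$alpha,
              x$training_n, x$probe_universe_size))
  invisible(x)
}

#' Project an EpiScore into a test cohort
#'
#' score_i = intercept + sum_j w_j (x_ij - m_j)/s_j over the model's weight
#' CpGs, with test values taken on the model's training scale. Weight CpGs
#' absent from the test matrix, or missing per sample, are imputed with the
#' training mean (contributing zero on the standardized scale). A warning is
#' emitted when more than half the weight CpGs are absent.
#'
#' @param model an `episcore_model`.
#' @param test test-cohort [methylation_matrix()] on the training scale
#'   (M/corrected-M for elastic-net EpiScores).
#' @return numeric score per test sample with attributes `n_absent_cpgs`,
#'   `imputed_fraction`, `flagged`.
#' @export
project_score <- function(model, test) {
  stopifnot(inherits(model, "episcore_model"), inherits(test, "methylation_matrix"))
  ids <- names(model$weights)
  present <- ids %in% cpg_ids(test)
  n_absent <- sum(!present)
  flagged <- FALSE
  if (length(ids) > 0 && n_absent > 0.5 * length(ids)) {
    warning(sprintf("%d of %d weight CpGs absent from the test matrix; scores flagged",
                    n_absent, length(ids)))
    flagged <- TRUE
  }
  n <- nrow(test$values)
  score <- rep(model$intercept, n)
  imputed <- if (length(ids) > 0) n_absent / length(ids) else 0
  if (any(present)) {
    Xs <- sweep(sweep(test$values[, ids[present], drop = FALSE], 2,
                      model$training_cpg_means[present], "-"),
                2, model$training_cpg_sds[present], "/")
    na_frac <- mean(is.na(Xs))
    Xs[is.na(Xs)] <- 0   # training mean on the standardized scale
    imputed <- (n_absent + na_frac * sum(present)) / length(ids)
    score <- score + as.numeric(Xs %*% model$weights[present])
  }
  names(score) <- sample_ids(test)
  attr(score, "n_absent_cpgs") <- n_absent
  attr(score, "imputed_fraction") <- imputed
  attr(score, "flagged") <- flagged
  score
}

#' Project Bayesian posterior-mean scores into a test cohort
#'
#' Weighted sum using posterior mean effects of a [run_bayes_ewas()] fit as
#' weights; same probe intersection and mean-imputation contract as
#' [project_score()]. The posterior effects are on the standardized
#' training scale, so test columns are standardized with training means/SDs.
#'
#' @param post a `bayes_posterior` fitted on the intersected probe set.
#' @param test test-cohort [methylation_matrix()].
#' @param training_means,training_sds named training CpG means/SDs on the
#'   model scale (names = CpG IDs of `post$table`).
#' @param min_abs_effect drop CpGs with |posterior mean| below this
#'   (default 0 keeps all).
#' @return numeric score per test sample (attributes as [project_score()]).
#' @export
bayes_score <- function(post, test, training_means, training_sds,
                        min_abs_effect = 0) {
  stopifnot(inherits(post, "bayes_posterior"))
  keep <- abs(post$table$mean_effect) > min_abs_effect
  model <- structure(list(trait_name = post$trait_name,
                          weights = setNames(post$table$mean_effect[keep],
                                             post$table$cpg_id[keep]),
                          intercept = 0,
                          training_cpg_means = training_means[post$table$cpg_id[keep]],
                          training_cpg_sds = training_sds[post$table$cpg_id[keep]]),
                     class = "episcore_model")
  project_score(model, test)
}

#' Incremental R-squared of a score over covariates
#'
#' Base model: trait ~ covariates (age, sex, plus subgroup dummies for a
#' pooled multi-subgroup cohort). Full model adds the score. Incremental
#' R^2 = R^2(full) - R^2(base), computed on complete cases for the whole
#' cohort and per subgroup (subgroup models omit the subgroup covariate).
#' Subgroups with n < 30 are flagged as small-sample.
#'
#' @param trait numeric outcome (raw trait in the test cohort).
#' @param score numeric EpiScore per sample.
#' @param covariates data.frame (e.g. age, sex).
#' @param subgroup optional subgroup label vector.
#' @return list of class `projection_result`: `overall` (data.frame with
#'   base_r2, full_r2, incremental_r2, n) and `by_subgroup` (data.frame or
#'   NULL, with a `small_sample` flag).
#' @export
incremental_r2 <- function(trait, score, covariates, subgroup = NULL) {
  covariates <- as.data.frame(covariates)
  cc <- complete.cases(trait, score, covariates) &
    (if (is.null(subgroup)) TRUE else !is.na(subgroup))
  trait <- trait[cc]; score <- score[cc]
  covariates <- covariates[cc, , drop = FALSE]
  if (!is.null(subgroup)) subgroup <- subgroup[cc]

  r2_pair <- function(y, sc, cov, grp = NULL) {
    d <- data.frame(y = y, score = sc, cov)
    base_form <- stats::reformulate(c(names(cov), if (!is.null(grp)) "grp"), "y")
    full_form <- stats::reformulate(c(names(cov), if (!is.null(grp)) "grp", "score"), "y")
    if (!is.null(grp)) d$grp <- factor(grp)
    base <- summary(lm(base_form, data = d))$r.squared
    full <- summary(lm(full_form, data = d))$r.squared
    c(base_r2 = base, full_r2 = full, incremental_r2 = full - base, n = length(y))
  }
  multi <- !is.null(subgroup) && length(unique(subgroup)) > 1
  overall <- as.data.frame(as.list(
    r2_pair(trait, score, covariates, grp = if (multi) subgroup else NULL)))
  by_subgroup <- NULL
  if (multi) {
    rows <- lapply(sort(unique(subgroup)), function(g) {
      i <- subgroup == g
      v <- r2_pair(trait[i], score[i], covariates[i, , drop = FALSE])
      data.frame(subgroup = g, as.list(v), small_sample = sum(i) < 30)
    })
    by_subgroup <- do.call(rbind, rows)
  }
  structure(list(overall = overall, by_subgroup = by_subgroup),
            class = "projection_result")
}

#' Serialize an EpiScore model as TSV
#'
#' Header metadata lines (trait, alpha, lambda, n_train, universe) followed
#' by cpg_id, weight, train_mean, train_sd columns.
#'
#' @param model an `episcore_model`.
#' @param path output file.
#' @return `path` invisibly; `read_episcore_model` returns the model.
#' @export
write_episcore_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# trait: %s", model$trait_name),
               sprintf("# alpha: %.17g", model$alpha),
               sprintf("# lambda: %.17g", model$lambda_selected),
               sprintf("# intercept: %.17g", model$intercept),
               sprintf("# n_train: %d", model$training_n),
               sprintf("# probe_universe_size: %d", model$probe_universe_size)), con)
  write.table(data.frame(cpg_id = names(model$weights),
                         weight = model$weights,
                         train_mean = model$training_cpg_means,
                         train_sd = model$training_cpg_sds),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_episcore_model
#' @export
read_episcore_model <- function(path) {
  hdr <- readLines(path, n = 6)
  get <- function(key) sub(sprintf("# %s: ", key), "", hdr[grepl(paste0("# ", key, ":"), hdr)])
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(list(trait_name = get("trait"),
                 weights = setNames(df$weight, df$cpg_id),
                 intercept = as.numeric(get("intercept")),
                 training_cpg_means = setNames(df$train_mean, df$cpg_id),
                 training_cpg_sds = setNames(df$train_sd, df$cpg_id),
                 alpha = as.numeric(get("alpha")),
                 lambda_selected = as.numeric(get("lambda")),
                 n_folds = NA_integer_,
                 training_n = as.integer(get("n_train")),
                 probe_universe_size = as.integer(get("probe_universe_size"))),
            class = "episcore_model")
}
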