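#' Latent growth model of general cognitive function
#'
#' Two-stage estimator of a per-person latent level (intercept) and per-year
#' change (slope) of general cognitive function from multi-test, multi-wave
#' data. Stage 1 extracts a single common factor across tests: loadings are
#' the first eigenvector of the pooled (across waves) test covariance matrix,
#' fixed across waves, and the per-sample-wave factor score is the
#' loading-weighted combination (weights normalized to sum to one so that
#' with unit loadings the factor score is the plain test mean). Stage 2 fits
#' a random-intercept, random-slope linear mixed model of factor scores on
#' years since baseline and returns the empirical-Bayes (BLUP) intercept and
#' slope per sample.
#'
#' @param scores long data.frame with columns sample_id, wave, age, test,
#'   score (>= 2 tests, >= 2 waves).
#' @param standardize "none" keeps factor scores on the test scale;
#'   "baseline" (default) standardizes them to mean 0, SD 1 at wave 1.
#' @return object of class `growth_estimates`: `estimates` (sample_id,
#'   intercept_hat, slope_hat, n_waves_used), `loadings` (per test),
#'   `variance_components` (intercept var, slope var, covariance, residual
#'   var), `dropped` (samples with no observed tests).
#' @export
fit_growth_model <- function(scores, standardize = c("baseline", "none")) {
  standardize <- match.arg(standardize)
  need <- c("sample_id", "wave", "age", "test", "score")
  assert_that(all(need %in% names(scores)), "scores needs sample_id, wave, age, test, score")
  all_ids <- unique(scores$sample_id)
  scores <- scores[!is.na(scores$score), , drop = FALSE]
  tests <- sort(unique(scores$test))
  waves <- sort(unique(scores$wave))
  assert_that(length(tests) >= 2 && length(waves) >= 2, "need >= 2 tests and >= 2 waves")

  # wide matrix per (sample, wave)
  key <- interaction(scores$sample_id, scores$wave, drop = TRUE)
  wide <- matrix(NA_real_, nlevels(key), length(tests),
                 dimnames = list(levels(key), tests))
  wide[cbind(as.integer(key), match(scores$test, tests))] <- scores$score
  meta <- scores[!duplicated(key), c("sample_id", "wave", "age")]
  meta <- meta[match(levels(key), key[!duplicated(key)]), ]

  complete <- rowSums(is.na(wide)) == 0
  assert_that(sum(complete) >= length(tests) + 2,
              "too few complete sample-waves for the pooled covariance")
  S <- cov(wide[complete, , drop = FALSE])
  ev <- eigen(S, symmetric = TRUE)
  load <- ev$vectors[, 1]
  if (sum(load) < 0) load <- -load
  w <- load / sum(load)

  # factor score per sample-wave; samples missing some tests use the
  # renormalized weights of their observed tests
  fscore <- apply(wide, 1, function(row) {
    obs <- !is.na(row)
    if (!any(obs)) return(NA_real_)
    sum(row[obs] * w[obs]) / sum(w[obs])
  })
  ok <- !is.na(fscore)
  dropped <- union(unique(meta$sample_id[!ok]),
                   setdiff(all_ids, unique(meta$sample_id[ok])))
  meta <- meta[ok, , drop = FALSE]
  fscore <- fscore[ok]

  base_age <- tapply(meta$age[meta$wave == min(waves)],
                     meta$sample_id[meta$wave == min(waves)], min)
  baseline <- unname(base_age[match(meta$sample_id, names(base_age))])
  # samples absent at wave 1: take their earliest observed age
  miss <- is.na(baseline)
  if (any(miss)) {
    first_age <- tapply(meta$age, meta$sample_id, min)
    baseline[miss] <- first_age[match(meta$sample_id[miss], names(first_age))]
  }
  time <- meta$age - baseline

  if (standardize == "baseline") {
    b0 <- meta$wave == min(waves)
    mu <- mean(fscore[b0]); s <- sd(fscore[b0])
    if (!is.finite(s) || s == 0) s <- 1
    fscore <- (fscore - mu) / s
  }

  d <- data.frame(id = meta$sample_id, time = time, f = fscore)

  # per-sample OLS (used for the exact-fit degenerate case and as fallback)
  ols <- function() {
    ids_u <- unique(d$id)
    est <- t(vapply(ids_u, function(s) {
      i <- d$id == s
      if (sum(i) == 1 || length(unique(d$time[i])) == 1)
        return(c(mean(d$f[i]), 0))
      co <- coef(lm.fit(cbind(1, d$time[i]), d$f[i]))
      c(co[1], co[2])
    }, numeric(2)))
    list(est = data.frame(sample_id = ids_u, intercept_hat = est[, 1],
                          slope_hat = est[, 2], stringsAsFactors = FALSE),
         vc = list(intercept_var = var(est[, 1]), slope_var = var(est[, 2]),
                   intercept_slope_cov = cov(est[, 1], est[, 2]),
                   residual_var = 0))
  }
  # residual SD of the saturated per-sample linear fits; (near-)zero noise
  # makes the mixed model degenerate, where OLS is already exact
  sat <- ols()
  pred <- sat$est$intercept_hat[match(d$id, sat$est$sample_id)] +
    sat$est$slope_hat[match(d$id, sat$est$sample_id)] * d$time
  exact_fit <- sd(d$f - pred) < 1e-8 * max(sd(d$f), 1e-12)

  if (exact_fit) {
    est <- sat$est
    vc_list <- sat$vc
  } else {
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(f ~ time + (1 + time | id), data = d,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))))
    re <- coef(fit)$id
    vc <- as.data.frame(lme4::VarCorr(fit))
    est <- data.frame(sample_id = rownames(re),
                      intercept_hat = re[["(Intercept)"]],
                      slope_hat = re[["time"]],
                      stringsAsFactors = FALSE)
    vc_list <- list(
      intercept_var = vc$vcov[vc$var1 %in% "(Intercept)" & is.na(vc$var2)][1],
      slope_var = vc$vcov[vc$var1 %in% "time" & is.na(vc$var2)][1],
      intercept_slope_cov = vc$vcov[!is.na(vc$var2)][1],
      residual_var = vc$vcov[vc$grp == "Residual"][1])
  }
  nw <- tapply(d$time, d$id, function(t) length(unique(t)))
  est$n_waves_used <- as.integer(nw[match(est$sample_id, names(nw))])
  structure(list(estimates = est,
                 loadings = setNames(load, tests),
                 variance_components = vc_list,
                 dropped = dropped),
            class = "growth_estimates")
}

#' Associations of predictors with cognitive intercept and slope
#'
#' For each predictor separately, OLS of the (standardized) cognitive
#' intercept and slope on the standardized predictor plus covariates;
#' Benjamini-Hochberg FDR is applied across the predictor family within each
#' outcome.
#'
#' @param growth a `growth_estimates`.
#' @param predictors data.frame of predictors keyed by row order of
#'   `sample_id` column (must contain sample_id).
#' @param covariates data.frame with sample_id plus covariate columns
#'   (basic model: age, sex).
#' @param model_tag label ("basic" or "full").
#' @return data.frame of class `association_result`: predictor, outcome,
#'   beta (standardized), se, p, p_fdr, n, model_tag.
#' @export
test_associations <- function(growth, predictors, covariates, model_tag = "basic") {
  stopifnot(inherits(growth, "growth_estimates"))
  est <- growth$estimates
  stopifnot("sample_id" %in% names(predictors), "sample_id" %in% names(covariates))
  pred_names <- setdiff(names(predictors), "sample_id")
  cov_names <- setdiff(names(covariates), "sample_id")
  rows <- list()
  for (outcome in c("intercept", "slope")) {
    yv <- if (outcome == "intercept") est$intercept_hat else est$slope_hat
    for (pn in pred_names) {
      x <- predictors[[pn]][match(est$sample_id, predictors$sample_id)]
      assert_that(sd(x, na.rm = TRUE) > 0, sprintf("constant predictor: %s", pn))
      cv <- covariates[match(est$sample_id, covariates$sample_id), cov_names, drop = FALSE]
      cc <- complete.cases(yv, x, cv)
      d <- data.frame(y = as.numeric(scale(yv[cc])), x = as.numeric(scale(x[cc])),
                      cv[cc, , drop = FALSE])
      fit <- lm(stats::reformulate(c("x", cov_names), "y"), data = d)
      sm <- summary(fit)$coefficients["x", ]
      rows[[length(rows) + 1]] <- data.frame(
        predictor = pn, outcome = outcome, beta = sm[1], se = sm[2], p = sm[4],
        n = sum(cc), model_tag = model_tag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_fdr <- NA_real_
  for (outcome in unique(out$outcome)) {
    i <- out$outcome == outcome
    out$p_fdr[i] <- p.adjust(out$p[i], method = "BH")
  }
  class(out) <- c("association_result", class(out))
  out
}

#' Variance decomposition: measured trait vs EpiScore vs both
#'
#' Incremental R^2 over age + sex in the cognitive intercept for (a) the
#' measured trait alone, (b) the EpiScore alone, (c) both together.
#'
#' @param growth a `growth_estimates`.
#' @param measured named numeric vector (names = sample IDs).
#' @param episcore named numeric vector (names = sample IDs).
#' @param covariates data.frame with sample_id, age, sex.
#' @return data.frame with model ("measured", "episcore", "both") and
#'   incremental_r2.
#' @export
variance_decomposition <- function(growth, measured, episcore, covariates) {
  est <- growth$estimates
  m <- measured[est$sample_id]
  e <- episcore[est$sample_id]
  cv <- covariates[match(est$sample_id, covariates$sample_id),
                   setdiff(names(covariates), "sample_id"), drop = FALSE]
  cc <- complete.cases(est$intercept_hat, m, e, cv)
  d <- data.frame(y = est$intercept_hat[cc], m = m[cc], e = e[cc], cv[cc, , drop = FALSE])
  cov_names <- setdiff(names(d), c("y", "m", "e"))
  r2 <- function(terms) summary(lm(stats::reformulate(terms, "y"), data = d))$r.squared
  base <- r2(cov_names)
  data.frame(model = c("measured", "episcore", "both"),
             incremental_r2 = c(r2(c(cov_names, "m")) - base,
                                r2(c(cov_names, "e")) - base,
                                r2(c(cov_names, "m", "e")) - base))
}
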