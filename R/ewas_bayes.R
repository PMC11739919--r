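#' Configuration for the joint Bayesian EWAS
#'
#' Spike-and-slab Gaussian mixture prior on per-CpG effects: a point mass at
#' zero plus slabs whose variances are the given fractions of a sampled
#' effect-variance scale (the standard small/medium/large-effect grid).
#'
#' @param component_variances strictly increasing positive slab variance
#'   fractions (default 1e-4, 1e-3, 1e-2).
#' @param n_iterations total Gibbs iterations (default 10000).
#' @param burn_in burn-in iterations (default 5000, < n_iterations).
#' @param thin thinning interval for variance-explained draws (default 5).
#' @param seed integer RNG seed.
#' @param pip_threshold high-confidence call threshold (default 0.95).
#' @param spike_only force all mixture mass to the spike (diagnostic limit;
#'   posterior effects are all zero).
#' @param force_inclusion disable the spike so every CpG carries a slab
#'   effect (with a single fixed-variance component this is a Bayesian ridge;
#'   diagnostic limit).
#' @param fixed_effect_scale if positive, hold the effect-variance scale
#'   fixed at this value instead of sampling it.
#' @param scale_prior_shape,scale_prior_mean inverse-gamma prior on the
#'   effect-variance scale: shape, and mean as a multiple of var(y). The
#'   default (6, 10) keeps the smallest slab separated from the spike under
#'   a null phenotype (the smallest detectable effect is about 0.1% of trait
#'   variance); a collapsing scale makes the spike/slab Bayes factor tend to
#'   1 and lets null CpGs diffuse into the slabs.
#' @param dir_prior Dirichlet pseudo-counts c(spike, each slab) for the
#'   mixture-weight update.
#' @return list of class `bayes_config`.
#' @export
bayes_config <- function(component_variances = c(1e-4, 1e-3, 1e-2),
                         n_iterations = 10000, burn_in = 5000, thin = 5,
                         seed = 7, pip_threshold = 0.95, spike_only = FALSE,
                         force_inclusion = FALSE, fixed_effect_scale = -1,
                         scale_prior_shape = 6, scale_prior_mean = 10,
                         dir_prior = c(1, 1)) {
  assert_that(all(component_variances > 0) || spike_only,
              "component variances must be > 0")
  assert_that(!is.unsorted(component_variances, strictly = TRUE),
              "component variances must be strictly increasing")
  assert_that(burn_in < n_iterations, "burn_in must be < n_iterations")
  assert_that(pip_threshold > 0 && pip_threshold <= 1,
              "pip_threshold must lie in (0,1]")
  structure(list(component_variances = component_variances,
                 n_iterations = n_iterations, burn_in = burn_in, thin = thin,
                 seed = seed, pip_threshold = pip_threshold,
                 spike_only = spike_only, force_inclusion = force_inclusion,
                 fixed_effect_scale = fixed_effect_scale,
                 scale_prior_shape = scale_prior_shape,
                 scale_prior_mean = scale_prior_mean, dir_prior = dir_prior),
            class = "bayes_config")
}

#' Joint Bayesian EWAS (spike-and-slab Gibbs over all CpGs)
#'
#' Gibbs sampler over the joint model y = W alpha + X beta + e where X holds
#' all standardized CpGs and beta has a spike-and-slab mixture prior. Each
#' iteration sweeps the CpGs in a freshly permuted order, sampling the
#' mixture component from its conditional marginal likelihood given the
#' current residual and then the effect (zero in the spike), keeps the
#' residual vector updated incrementally, resamples the unpenalized covariate
#' effects, the mixture proportions (Dirichlet(counts + prior)), the
#' effect-variance scale and the residual variance (inverse-gamma
#' conditionals). The per-CpG posterior inclusion probability (PIP) is the
#' fraction of post-burn-in iterations in a slab; variance explained is
#' var(X beta)/var(y) per thinned iteration.
#'
#' @param pheno `residualized_phenotype` or named numeric vector.
#' @param mat corrected-M [methylation_matrix()]; columns are standardized
#'   internally (zero-variance CpGs dropped with a warning).
#' @param covariates data.frame/matrix of unpenalized covariates or NULL
#'   (an intercept is always included).
#' @param config a [bayes_config()].
#' @return object of class `bayes_posterior`: `table` (cpg_id, pip,
#'   mean_effect, sd_effect), `variance_explained` (mean, ci95 lower/upper,
#'   draws), `sigma2_e_mean`, `component_proportions`, `ess_varexp`,
#'   `residual_check` (max abs deviation of the final incremental residual
#'   from y - W alpha - X beta), `config`.
#' @export
run_bayes_ewas <- function(pheno, mat, covariates = NULL, config = bayes_config()) {
  stopifnot(inherits(mat, "methylation_matrix"), inherits(config, "bayes_config"))
  y <- if (inherits(pheno, "residualized_phenotype")) pheno$residuals else pheno
  trait_name <- if (inherits(pheno, "residualized_phenotype")) pheno$trait_name else "trait"
  V <- mat$values
  stopifnot(length(y) == nrow(V))
  if (anyNA(V)) {
    mu <- colMeans(V, na.rm = TRUE)
    idx <- which(is.na(V), arr.ind = TRUE)
    V[idx] <- mu[idx[, 2]]
  }
  sds <- apply(V, 2, sd)
  const <- sds < .Machine$double.eps * 100
  if (any(const)) {
    warning(sprintf("dropping %d zero-variance CpG(s)", sum(const)))
    V <- V[, !const, drop = FALSE]
  }
  X <- scale(V)
  W <- cbind(intercept = rep(1, nrow(X)))
  if (!is.null(covariates) && ncol(as.matrix(covariates)) > 0)
    W <- cbind(W, as.matrix(covariates))

  gam <- if (config$spike_only) numeric(0) else config$component_variances
  set.seed(config$seed)
  fit <- bayesr_gibbs(X, as.numeric(y), W, gam,
                      n_iter = config$n_iterations, burn_in = config$burn_in,
                      thin = config$thin,
                      force_inclusion = config$force_inclusion,
                      fixed_sigma2_b = config$fixed_effect_scale,
                      scale_prior_shape = config$scale_prior_shape,
                      scale_prior_mean = config$scale_prior_mean,
                      dir_spike = config$dir_prior[1],
                      dir_slab = config$dir_prior[2])

  resid_check <- max(abs(as.numeric(y) - as.numeric(W %*% fit$final_alpha) -
                           as.numeric(X %*% fit$final_beta) - fit$final_residual))
  ve <- fit$varexp_draws
  tab <- data.frame(cpg_id = colnames(V), pip = fit$pip,
                    mean_effect = fit$beta_mean, sd_effect = fit$beta_sd,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, trait_name = trait_name,
                 variance_explained = list(mean = mean(ve),
                                           ci95 = unname(quantile(ve, c(0.025, 0.975))),
                                           draws = ve),
                 sigma2_e_mean = mean(fit$sigma2e_draws),
                 component_proportions = as.numeric(fit$component_proportions),
                 ess_varexp = ess(ve),
                 residual_check = resid_check,
                 final_state = list(beta = setNames(fit$final_beta, colnames(V)),
                                    alpha = setNames(fit$final_alpha, colnames(W))),
                 config = config),
            class = "bayes_posterior")
}

#' @export
print.bayes_posterior <- function(x, ...) {
  cat(sprintf("<bayes_posterior> trait=%s CpGs=%d PIP>=%.2f: %d varexp=%.3f [%.3f, %.3f]\n",
              x$trait_name, nrow(x$table), x$config$pip_threshold,
              sum(x$table$pip >= x$config$pip_threshold),
              x$variance_explained$mean, x$variance_explained$ci95[1],
              x$variance_explained$ci95[2]))
  invisible(x)
}

# effective sample size from the empirical autocorrelation (initial positive
# sequence truncation)
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) < 1e-300) return(n)
  rho <- as.numeric(stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf)[-1]
  neg <- which(rho < 0)
  if (length(neg) > 0) rho <- rho[seq_len(neg[1] - 1)]
  n / (1 + 2 * sum(rho))
}

#' High-confidence CpGs from a Bayesian posterior
#'
#' CpGs with PIP at or above the threshold (inclusive), sorted by descending
#' PIP then CpG ID.
#'
#' @param post a `bayes_posterior`.
#' @param threshold PIP threshold in (0,1\], default 0.95.
#' @return character vector of CpG IDs.
#' @export
call_high_confidence <- function(post, threshold = 0.95) {
  stopifnot(inherits(post, "bayes_posterior"))
  assert_that(threshold > 0 && threshold <= 1, "threshold must lie in (0,1]")
  tab <- post$table[post$table$pip >= threshold, , drop = FALSE]
  tab$cpg_id[order(-tab$pip, tab$cpg_id)]
}

#' Overlap between marginal and Bayesian significant sets
#'
#' @param marginal_ids CpGs significant in the (PC-adjusted) marginal EWAS.
#' @param bayes_ids CpGs at PIP >= threshold in the joint model.
#' @return list with counts `n_bayes`, `n_marginal`, `n_shared`,
#'   `bayes_only`, `marginal_only`, `shared`, and `label` in the
#'   "bayes (shared)" reporting shape.
#' @export
compare_marginal_bayes <- function(marginal_ids, bayes_ids) {
  shared <- intersect(bayes_ids, marginal_ids)
  list(n_bayes = length(bayes_ids), n_marginal = length(marginal_ids),
       n_shared = length(shared),
       bayes_only = sort(setdiff(bayes_ids, marginal_ids)),
       marginal_only = sort(setdiff(marginal_ids, bayes_ids)),
       shared = sort(shared),
       label = sprintf("%d (%d)", length(bayes_ids), length(shared)))
}
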