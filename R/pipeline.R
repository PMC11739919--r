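#' Write / read a cohort bundle as plain-text files
#'
#' methylation.tsv (samples in rows, header = CpG IDs), phenotypes.tsv,
#' kinship.tsv (square, ID-labelled) and truth.json.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mv <- format(bundle$methylation$values, digits = 8, trim = TRUE)
  write.table(data.frame(sample_id = rownames(bundle$methylation$values), mv,
                         check.names = FALSE),
              file.path(dir, "methylation.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bundle$phenotypes, file.path(dir, "phenotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = rownames(bundle$kinship),
                         format(bundle$kinship, digits = 6, trim = TRUE),
                         check.names = FALSE),
              file.path(dir, "kinship.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- bundle$truth
  truth$cell_reference <- NULL
  truth$true_cell_fractions <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir directory containing methylation.tsv, phenotypes.tsv,
#'   kinship.tsv (truth.json optional).
#' @return a `cohort_bundle` (without generator state).
#' @export
read_cohort <- function(dir) {
  m <- read.delim(file.path(dir, "methylation.tsv"), check.names = FALSE)
  vals <- as.matrix(m[, -1, drop = FALSE])
  rownames(vals) <- m$sample_id
  ph <- read.delim(file.path(dir, "phenotypes.tsv"), stringsAsFactors = FALSE)
  k <- read.delim(file.path(dir, "kinship.tsv"), check.names = FALSE)
  kin <- as.matrix(k[, -1, drop = FALSE])
  rownames(kin) <- k$sample_id
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  structure(list(methylation = methylation_matrix(vals, "beta"),
                 phenotypes = ph, kinship = kin, truth = truth,
                 generator = NULL),
            class = "cohort_bundle")
}

#' Default desk-scale run configuration
#'
#' A small end-to-end preset (500 training samples, 2,000 CpGs, reduced
#' Gibbs chains) that exercises every stage in a few minutes.
#'
#' @param seed global seed; per-stage seeds are derived from it by
#'   [derive_seed()].
#' @param out_dir output directory.
#' @return nested configuration list for [run_pipeline()].
#' @export
default_run_config <- function(seed = 1, out_dir = tempfile("episcope_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = list(simulate = TRUE, preprocess = TRUE, covariates = TRUE,
                  ewas = TRUE, bayes = TRUE, episcore = TRUE, cognition = TRUE),
    sim = list(n_samples = 500, n_cpgs = 2000, n_blocks = 200,
               within_block_corr = 0.6, n_causal = 20,
               target_variance_explained = 0.4,
               family_spec = list(n_families = 60, sibs_per_family = 2)),
    ewas = list(threshold = 3.6e-8, n_pcs = 20, bacon = TRUE,
                bacon_iter = 2000, bacon_burn = 800),
    bayes = list(n_iterations = 800, burn_in = 300, thin = 5),
    episcore = list(alpha = 0.5, n_folds = 20, probe_fraction = 0.8,
                    n_test_samples = 400, missing_rate = 0.02),
    cognition = list(n_tests = 4, n_waves = 5, intercept_assoc = -0.1,
                     slope_assoc = 0, noise_sd = 0.5),
    inputs = list()
  )
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in dependency order (simulate, preprocess,
#' covariates, marginal EWAS with optional PC adjustment and bacon
#' correction, Bayesian EWAS, EpiScore training/projection/evaluation,
#' cognition), writing summary TSV/JSON outputs and a run manifest (package
#' version, per-stage seeds, wall times, output paths and MD5 hashes) under
#' `config$out_dir`. Per-stage seeds are derived deterministically from the
#' global seed and the stage name, so re-running an identical configuration
#' reproduces byte-identical summary outputs.
#'
#' @param config nested list as from [default_run_config()], or a path to a
#'   YAML file with the same structure.
#' @return the manifest (list), invisibly; also written as manifest.json.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  seed <- config$seed %||% 1

  for (nm in names(config$inputs %||% list())) {
    path <- config$inputs[[nm]]
    if (!is.null(path) && !file.exists(path))
      stop(sprintf("configuration error: %s input file not found: %s", nm, path),
           call. = FALSE)
  }
  if (isTRUE(stages$preprocess) && !isTRUE(stages$simulate) &&
      is.null(config$inputs$kinship))
    stop("configuration error: mixed-model residualization enabled but no kinship file configured",
         call. = FALSE)

  manifest <- list(package_version = as.character(utils::packageVersion("episcope")),
                   global_seed = seed, stages = list())
  state <- list()
  t_all <- proc.time()[3]

  run_stage <- function(name, fun) {
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    outputs <- res$outputs %||% character(0)
    manifest$stages[[name]] <<- list(
      seed = derive_seed(seed, name),
      wall_time_s = round(proc.time()[3] - t0, 3),
      outputs = as.list(outputs),
      output_md5 = as.list(unname(tools::md5sum(outputs))))
    state <<- res$state
  }

  if (isTRUE(stages$simulate)) run_stage("simulate", function() {
    sim_args <- config$sim %||% list()
    sim_args$seed <- derive_seed(seed, "simulate")
    cfg <- do.call(sim_config, sim_args)
    state$train <- simulate_cohort(cfg)
    ep <- config$episcore %||% list()
    state$test <- simulate_test_cohort(state$train,
                                       probe_fraction = ep$probe_fraction %||% 0.8,
                                       n_samples = ep$n_test_samples %||% 400,
                                       seed = derive_seed(seed, "simulate_test"),
                                       missing_rate = ep$missing_rate %||% 0.02,
                                       subgroups = ep$subgroups)
    f <- file.path(out_dir, "sim_summary.tsv")
    write.table(data.frame(cohort = c("train", "test"),
                           n = c(nrow(state$train$methylation$values),
                                 nrow(state$test$methylation$values)),
                           p = c(ncol(state$train$methylation$values),
                                 ncol(state$test$methylation$values))),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(state = state, outputs = f)
  })

  if (isTRUE(stages$preprocess)) run_stage("preprocess", function() {
    if (is.null(state$train)) {
      assert_that(!is.null(config$inputs$cohort_dir),
                  "configuration error: no simulated cohort and no cohort_dir input")
      state$train <- read_cohort(config$inputs$cohort_dir)
      kin <- read.delim(config$inputs$kinship, check.names = FALSE)
      km <- as.matrix(kin[, -1, drop = FALSE]); rownames(km) <- kin[[1]]
      state$train$kinship <- km
    }
    m <- beta_to_m(state$train$methylation)
    state$mvals <- precorrect_m_values(m, state$train$phenotypes)
    state$pheno <- residualize_phenotype(state$train)
    f <- file.path(out_dir, "residualized_phenotype.tsv")
    write.table(data.frame(sample_id = names(state$pheno$residuals),
                           residual = sprintf("%.10g", state$pheno$residuals)),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    fj <- file.path(out_dir, "residualization.json")
    jsonlite::write_json(list(variance_components = state$pheno$variance_components,
                              fixed_effects = state$pheno$fixed_effects),
                         fj, auto_unbox = TRUE, digits = 10)
    list(state = state, outputs = c(f, fj))
  })

  if (isTRUE(stages$covariates)) run_stage("covariates", function() {
    truth <- state$train$truth
    smoke_wt <- weight_table(truth$smoking_cpg_ids, truth$smoking_weights)
    sm <- smoking_score(state$train$methylation, smoke_wt)
    cells <- deconvolve_cells(state$train$methylation, truth$cell_reference)
    pcs <- methylome_pcs(state$mvals, n_pcs = min(config$ewas$n_pcs %||% 20,
                                                  nrow(state$mvals$values) - 2))
    state$covariates <- data.frame(smoking = as.numeric(sm),
                                   cells[, -1, drop = FALSE])  # drop reference type
    state$pcs <- pcs
    f <- file.path(out_dir, "covariates.tsv")
    write.table(data.frame(sample_id = sample_ids(state$train$methylation),
                           round(state$covariates, 8)),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(state = state, outputs = f)
  })

  if (isTRUE(stages$ewas)) run_stage("ewas", function() {
    thr <- config$ewas$threshold %||% 3.6e-8
    base <- run_marginal_ewas(state$pheno, state$mvals, state$covariates,
                              model_tag = "base")
    n_pcs <- min(config$ewas$n_pcs %||% 20, ncol(state$pcs$scores))
    pcadj <- run_marginal_ewas(state$pheno, state$mvals,
                               cbind(state$covariates,
                                     state$pcs$scores[, seq_len(n_pcs), drop = FALSE]),
                               model_tag = "pc_adjusted")
    state$ewas <- list(base = base, pc_adjusted = pcadj)
    state$sig <- list(base = call_significant(base, thr),
                      pc_adjusted = call_significant(pcadj, thr))
    outs <- c(file.path(out_dir, "ewas_base.tsv"),
              file.path(out_dir, "ewas_pc_adjusted.tsv"))
    write_ewas_tsv(base, outs[1])
    write_ewas_tsv(pcadj, outs[2])
    if (isTRUE(config$ewas$bacon)) {
      bf <- fit_bacon(ewas_z(pcadj), seed = derive_seed(seed, "bacon"),
                      n_iter = config$ewas$bacon_iter %||% 5000,
                      burn_in = config$ewas$bacon_burn %||% 2000)
      bc <- apply_bacon(pcadj, bf)
      state$ewas$bacon_corrected <- bc
      state$sig$bacon_corrected <- call_significant(bc, thr)
      outs <- c(outs, file.path(out_dir, "ewas_bacon_corrected.tsv"))
      write_ewas_tsv(bc, outs[3])
    }
    list(state = state, outputs = outs)
  })

  if (isTRUE(stages$bayes)) run_stage("bayes", function() {
    bc <- config$bayes %||% list()
    cfg <- bayes_config(n_iterations = bc$n_iterations %||% 800,
                        burn_in = bc$burn_in %||% 300,
                        thin = bc$thin %||% 5,
                        seed = derive_seed(seed, "bayes"))
    state$bayes <- run_bayes_ewas(state$pheno, state$mvals, state$covariates, cfg)
    f <- file.path(out_dir, "bayes_posterior.tsv")
    tab <- state$bayes$table
    tab$pip <- sprintf("%.6f", tab$pip)
    tab$mean_effect <- sprintf("%.8g", tab$mean_effect)
    tab$sd_effect <- sprintf("%.8g", tab$sd_effect)
    write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    fj <- file.path(out_dir, "bayes_report.json")
    jsonlite::write_json(list(variance_explained = state$bayes$variance_explained[c("mean", "ci95")],
                              sigma2_e_mean = state$bayes$sigma2_e_mean,
                              ess_varexp = state$bayes$ess_varexp,
                              n_iterations = cfg$n_iterations),
                         fj, auto_unbox = TRUE, digits = 8)
    list(state = state, outputs = c(f, fj))
  })

  if (isTRUE(stages$episcore)) run_stage("episcore", function() {
    ep <- config$episcore %||% list()
    probes <- intersect_probes(state$mvals, state$test$methylation)
    model <- train_elnet(state$pheno, state$mvals, probes,
                         alpha = ep$alpha %||% 0.5, n_folds = ep$n_folds %||% 20,
                         seed = derive_seed(seed, "elnet_folds"))
    test_m <- precorrect_m_values(beta_to_m(state$test$methylation),
                                  state$test$phenotypes)
    score <- project_score(model, test_m)
    ev <- incremental_r2(state$test$phenotypes$trait, score,
                         state$test$phenotypes[, c("age", "sex")],
                         subgroup = state$test$phenotypes$subgroup)
    state$episcore <- list(model = model, score = score, evaluation = ev)
    f1 <- file.path(out_dir, "episcore_weights.tsv")
    write_episcore_model(model, f1)
    f2 <- file.path(out_dir, "episcore_evaluation.tsv")
    evtab <- ev$overall
    if (!is.null(ev$by_subgroup)) {
      evtab <- rbind(cbind(subgroup = "(all)", ev$overall, small_sample = FALSE),
                     ev$by_subgroup)
    }
    num <- vapply(evtab, is.numeric, logical(1))
    evtab[num] <- lapply(evtab[num], function(z) sprintf("%.8g", z))
    write.table(evtab, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    list(state = state, outputs = c(f1, f2))
  })

  if (isTRUE(stages$cognition)) run_stage("cognition", function() {
    cg <- config$cognition %||% list()
    cog <- simulate_cognition(state$test, n_tests = cg$n_tests %||% 4,
                              n_waves = cg$n_waves %||% 5,
                              intercept_assoc = cg$intercept_assoc %||% -0.1,
                              slope_assoc = cg$slope_assoc %||% 0,
                              seed = derive_seed(seed, "cognition"),
                              noise_sd = cg$noise_sd %||% 0.5)
    growth <- fit_growth_model(cog)
    preds <- data.frame(sample_id = state$test$phenotypes$sample_id,
                        measured_trait = state$test$phenotypes$trait,
                        episcore = as.numeric(state$episcore$score))
    covs <- state$test$phenotypes[, c("sample_id", "age", "sex")]
    assoc <- test_associations(growth, preds, covs, model_tag = "basic")
    state$cognition <- list(growth = growth, associations = assoc)
    f <- file.path(out_dir, "cognition_associations.tsv")
    atab <- assoc
    num <- vapply(atab, is.numeric, logical(1))
    atab[num] <- lapply(atab[num], function(z) sprintf("%.8g", z))
    write.table(atab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(state = state, outputs = f)
  })

  if (!is.null(state$ewas) && !is.null(state$bayes)) {
    t2 <- make_table2(list(trait = list(
      base = state$ewas$base, pc_adjusted = state$ewas$pc_adjusted,
      bayes = state$bayes, mat = state$mvals,
      threshold = config$ewas$threshold %||% 3.6e-8)))
    f <- file.path(out_dir, "table2.tsv")
    write.table(t2, f, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$table2 <- f
  }

  manifest$total_wall_time_s <- round(proc.time()[3] - t_all, 3)
  # wall times vary run to run; hash-relevant outputs do not include them
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Per-trait significant-CpG count table
#'
#' The synthetic analogue of the headline EWAS comparison: per trait, counts
#' of epigenome-wide significant CpGs in the base and DNAm-PC-adjusted
#' marginal EWAS, the number of high-confidence Bayesian CpGs with their
#' overlap into the PC-adjusted set in parentheses, and the number of PCs
#' needed for >= 80% of the variance of each significant set.
#'
#' @param results named list per trait; each element a list with
#'   `base`/`pc_adjusted` (`ewas_result`), `bayes` (`bayes_posterior`), `mat`
#'   (the methylation matrix for PC counting) and optionally `threshold`.
#' @return data.frame, one row per trait.
#' @export
make_table2 <- function(results) {
  rows <- lapply(names(results), function(tr) {
    r <- results[[tr]]
    thr <- r$threshold %||% 3.6e-8
    n_base <- n_pc <- NA_integer_
    bayes_label <- NA_character_
    pcs_base <- pcs_pc <- NA_integer_
    sig_base <- sig_pc <- character(0)
    if (!is.null(r$base)) {
      sig_base <- call_significant(r$base, thr)
      n_base <- length(sig_base)
    } else warning(sprintf("trait %s: base EWAS missing", tr))
    if (!is.null(r$pc_adjusted)) {
      sig_pc <- call_significant(r$pc_adjusted, thr)
      n_pc <- length(sig_pc)
    } else warning(sprintf("trait %s: PC-adjusted EWAS missing", tr))
    if (!is.null(r$bayes)) {
      hc <- call_high_confidence(r$bayes, r$bayes$config$pip_threshold)
      bayes_label <- compare_marginal_bayes(sig_pc, hc)$label
    } else warning(sprintf("trait %s: Bayesian EWAS missing", tr))
    if (!is.null(r$mat)) {
      if (length(sig_base) > 0)
        pcs_base <- count_independent_signals(r$mat, sig_base)
      if (length(sig_pc) > 0)
        pcs_pc <- count_independent_signals(r$mat, sig_pc)
    }
    data.frame(trait = tr, n_sig_base = n_base, n_sig_pc_adjusted = n_pc,
               bayes_pip95 = bayes_label, n_pcs80_base = pcs_base,
               n_pcs80_pc_adjusted = pcs_pc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
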