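#!/usr/bin/env Rscript
# Train the elastic-net EpiScore on the training cohort (probe universe =
# intersection with the test array), project it and the Bayesian
# posterior-mean score into the test cohort with mean imputation, and
# evaluate incremental R2 over age + sex, overall and by subgroup.
suppressMessages(library(episcope))

train <- readRDS("scratch/analysis/train.rds")
test <- readRDS("scratch/analysis/test.rds")
mc <- readRDS("scratch/analysis/train_corrected_m.rds")
ph <- readRDS("scratch/analysis/train_residualized.rds")
post <- readRDS("scratch/analysis/bayes_posterior.rds")
dir.create("results/episcore", showWarnings = FALSE, recursive = TRUE)

probes <- intersect_probes(mc, test$methylation)
message(sprintf("probe universe: %d shared CpGs", length(probes)))
model <- train_elnet(ph, mc, probes, alpha = 0.5, n_folds = 20, seed = 20260106)
message(sprintf("elastic net kept %d CpGs (lambda = %.4g, CV R2 = %.3f)",
                length(model$weights), model$lambda_selected, model$cv_r2))

test_m <- precorrect_m_values(beta_to_m(test$methylation), test$phenotypes)
score <- project_score(model, test_m)
message(sprintf("projection imputed %.2f%% of weight-CpG entries",
                100 * attr(score, "imputed_fraction")))

ev <- incremental_r2(test$phenotypes$trait, score,
                     test$phenotypes[, c("age", "sex")],
                     subgroup = test$phenotypes$subgroup)
message(sprintf("incremental R2 over age+sex, whole cohort: %.3f",
                ev$overall$incremental_r2))
print(ev$by_subgroup)

# Bayesian posterior-mean score, same projection contract
ctr <- colMeans(mc$values[, post$table$cpg_id, drop = FALSE])
scl <- apply(mc$values[, post$table$cpg_id, drop = FALSE], 2, sd)
bscore <- bayes_score(post, test_m, ctr, scl)
evb <- incremental_r2(test$phenotypes$trait, bscore,
                      test$phenotypes[, c("age", "sex")],
                      subgroup = test$phenotypes$subgroup)
message(sprintf("Bayesian score incremental R2: %.3f (elnet/Bayes score r = %.3f)",
                evb$overall$incremental_r2, cor(score, bscore)))

write_episcore_model(model, "results/episcore/weights.tsv")
evtab <- rbind(cbind(method = "elnet", subgroup = "(all)", ev$overall),
               cbind(method = "elnet", ev$by_subgroup[, 1:5]),
               cbind(method = "bayes", subgroup = "(all)", evb$overall),
               cbind(method = "bayes", evb$by_subgroup[, 1:5]))
write.table(format(evtab, digits = 6), "results/episcore/evaluation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(list(model = model, score = score, bscore = bscore),
        "scratch/analysis/episcore.rds")
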