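#!/usr/bin/env Rscript
# Preprocess the training cohort: M-value transform, pre-correction of
# M-values for age/sex/batch, and kinship-aware residualization of the trait
# on age, age^2, sex and family structure.
suppressMessages(library(episcope))

train <- readRDS("scratch/analysis/train.rds")
dir.create("results/preprocess", showWarnings = FALSE, recursive = TRUE)

m <- beta_to_m(train$methylation)
mc <- precorrect_m_values(m, train$phenotypes)
ph <- residualize_phenotype(train)

saveRDS(mc, "scratch/analysis/train_corrected_m.rds")
saveRDS(ph, "scratch/analysis/train_residualized.rds")

vc <- ph$variance_components
message(sprintf("REML variance components: sigma2_g = %.3f, sigma2_e = %.3f (lambda = %.3f)",
                vc$sigma2_g, vc$sigma2_e, vc$lambda))
message(sprintf("phenotype residual SD: %.3f", sd(ph$residuals)))

write.table(data.frame(sample_id = names(ph$residuals),
                       residual = sprintf("%.8g", ph$residuals)),
            "results/preprocess/residualized_trait.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(variance_components = vc, fixed_effects = ph$fixed_effects),
                     "results/preprocess/residualization.json",
                     auto_unbox = TRUE, digits = 8)
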