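#!/usr/bin/env Rscript
# Build the EWAS covariates: the weighted-CpG smoking score, reference-based
# cell-type proportions (simplex-constrained least squares) and the first 20
# methylome principal components, each checked against the generator truth.
suppressMessages(library(episcope))

train <- readRDS("scratch/analysis/train.rds")
mc <- readRDS("scratch/analysis/train_corrected_m.rds")
dir.create("results/covariates", showWarnings = FALSE, recursive = TRUE)

wt <- weight_table(train$truth$smoking_cpg_ids, train$truth$smoking_weights)
smoke <- smoking_score(train$methylation, wt)
message(sprintf("smoking score vs true exposure: r = %.3f",
                cor(smoke, train$truth$smoking_exposure)))

cells <- deconvolve_cells(train$methylation, train$truth$cell_reference)
message(sprintf("cell fractions: mean |error| vs truth = %.4f",
                mean(abs(cells - train$truth$true_cell_fractions))))

pcs <- methylome_pcs(mc, n_pcs = 20)
message(sprintf("first 20 methylome PCs explain %.1f%% of corrected-M variance",
                100 * sum(pcs$variance_fraction)))

covs <- data.frame(smoking = as.numeric(smoke), cells[, -1, drop = FALSE])
saveRDS(list(covariates = covs, pcs = pcs), "scratch/analysis/train_covariates.rds")
write.table(cbind(sample_id = rownames(cells), round(as.data.frame(cells), 6),
                  smoking = round(as.numeric(smoke), 6)),
            "results/covariates/covariates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(pc = seq_along(pcs$variance_fraction),
                       variance_fraction = round(pcs$variance_fraction, 6)),
            "results/covariates/pc_variance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
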