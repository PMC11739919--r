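#' Marginal (per-CpG) EWAS
#'
#' Ordinary least squares of the residualized trait on each standardized CpG
#' plus fixed covariates, one CpG at a time. With complete data the covariates
#' are projected out once (QR) and every CpG is tested in closed form;
#' CpGs with missing samples fall back to a per-CpG fit on their complete
#' cases. Effects are per SD of (corrected) M-value, in residualized-trait
#' units; p-values are two-sided Student-t with the exact residual df.
#'
#' @param pheno a `residualized_phenotype` or a named numeric vector.
#' @param mat corrected-M [methylation_matrix()] (M scale accepted).
#' @param covariates data.frame/matrix of fixed covariates (e.g. smoking
#'   score and cell fractions with one reference type dropped; optionally 20
#'   methylome PCs), or NULL. An intercept is always added.
#' @param model_tag label: "base", "pc_adjusted" or "bacon_corrected".
#' @return object of class `ewas_result`: data.frame `table` (cpg_id, effect,
#'   se, t, p, n_used), `trait_name`, `model_tag`, `lambda_gc`, `df`,
#'   `dropped_cpgs` (zero-variance probes excluded with p = NA).
#' @export
run_marginal_ewas <- function(pheno, mat, covariates = NULL, model_tag = "base") {
  stopifnot(inherits(mat, "methylation_matrix"))
  y <- if (inherits(pheno, "residualized_phenotype")) pheno$residuals else pheno
  trait_name <- if (inherits(pheno, "residualized_phenotype")) pheno$trait_name else "trait"
  V <- mat$values
  n <- nrow(V)
  stopifnot(length(y) == n)
  if (!is.null(names(y)) && !is.null(rownames(V)))
    stopifnot(identical(names(y), rownames(V)))

  C <- cbind(intercept = rep(1, n))
  if (!is.null(covariates) && ncol(as.matrix(covariates)) > 0)
    C <- cbind(C, as.matrix(covariates))
  assert_that(kappa(crossprod(C), exact = FALSE) < 1e10,
              "covariate design is (near-)collinear")
  q <- ncol(C)
  df <- n - q - 1
  assert_that(df > 0, "not enough samples for the covariate design")

  sds <- apply(V, 2, sd, na.rm = TRUE)
  dropped <- colnames(V)[!is.finite(sds) | sds < .Machine$double.eps * 100]
  keep <- setdiff(colnames(V), dropped)
  V <- V[, keep, drop = FALSE]

  eff <- se <- tt <- rep(NA_real_, ncol(V))
  n_used <- rep(n, ncol(V))
  has_na <- colSums(is.na(V)) > 0

  qrC <- qr(C)
  y_r <- qr.resid(qrC, y)
  yty <- sum(y_r^2)
  if (any(!has_na)) {
    Xs <- scale(V[, !has_na, drop = FALSE])
    Xr <- qr.resid(qrC, Xs)
    xtx <- colSums(Xr^2)
    xty <- as.numeric(crossprod(Xr, y_r))
    b <- xty / xtx
    rss <- pmax(yty - b * xty, 0)
    s2 <- rss / df
    eff[!has_na] <- b
    se[!has_na] <- sqrt(s2 / xtx)
    tt[!has_na] <- b / se[!has_na]
  }
  for (j in which(has_na)) {
    obs <- !is.na(V[, j])
    nj <- sum(obs)
    dfj <- nj - q - 1
    if (dfj <= 0) { n_used[j] <- nj; next }
    x <- as.numeric(scale(V[obs, j]))
    D <- cbind(x, C[obs, , drop = FALSE])
    fit <- lm.fit(D, y[obs])
    s2 <- sum(fit$residuals^2) / dfj
    XtXinv_11 <- chol2inv(chol(crossprod(D)))[1, 1]
    eff[j] <- fit$coefficients[1]
    se[j] <- sqrt(s2 * XtXinv_11)
    tt[j] <- eff[j] / se[j]
    n_used[j] <- nj
  }
  dfs <- n_used - q - 1
  p <- 2 * pt(-abs(tt), df = dfs)
  p <- pmax(p, .Machine$double.xmin)
  tab <- data.frame(cpg_id = colnames(V), effect = eff, se = se, t = tt, p = p,
                    n_used = n_used, stringsAsFactors = FALSE)
  structure(list(table = tab, trait_name = trait_name, model_tag = model_tag,
                 lambda_gc = lambda_gc(tab$p[is.finite(tab$p)]),
                 df = df, dropped_cpgs = dropped),
            class = "ewas_result")
}

#' @export
print.ewas_result <- function(x, ...) {
  cat(sprintf("<ewas_result> trait=%s model=%s CpGs=%d lambda_GC=%.3f\n",
              x$trait_name, x$model_tag, nrow(x$table), x$lambda_gc))
  invisible(x)
}

#' Call epigenome-wide significant CpGs
#'
#' CpGs with p strictly below the threshold, sorted by ascending p with ties
#' broken lexicographically by CpG ID. The default threshold 3.6e-8 is the
#' simulation-derived epigenome-wide significance level for EPIC-array EWAS.
#'
#' @param result an `ewas_result`.
#' @param threshold significance level in (0,1\].
#' @return character vector of CpG IDs.
#' @export
call_significant <- function(result, threshold = 3.6e-8) {
  stopifnot(inherits(result, "ewas_result"))
  assert_that(threshold > 0 && threshold <= 1, "threshold must lie in (0,1]")
  tab <- result$table
  hit <- !is.na(tab$p) & tab$p < threshold
  tab <- tab[hit, , drop = FALSE]
  tab$cpg_id[order(tab$p, tab$cpg_id)]
}

#' Count approximately independent signals by PCA
#'
#' PCA on the standardized submatrix of significant CpGs; returns the
#' smallest number of components whose cumulative variance fraction reaches
#' the target (default 80%).
#'
#' @param mat [methylation_matrix()] containing the significant CpGs.
#' @param significant_ids CpG IDs to analyse (>= 1).
#' @param variance_target cumulative variance fraction (default 0.80).
#' @return integer count of components.
#' @export
count_independent_signals <- function(mat, significant_ids, variance_target = 0.80) {
  stopifnot(inherits(mat, "methylation_matrix"))
  assert_that(length(significant_ids) >= 1, "need at least one significant CpG")
  if (length(significant_ids) == 1) return(1L)
  missing_ids <- setdiff(significant_ids, cpg_ids(mat))
  assert_that(length(missing_ids) == 0,
              paste("CpGs absent from matrix:", paste(head(missing_ids), collapse = ", ")))
  X <- mat$values[, significant_ids, drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  Xs <- scale(X)
  n <- nrow(Xs)
  ev <- if (n < ncol(Xs)) {
    eigen(tcrossprod(Xs) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
  } else {
    eigen(crossprod(Xs) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
  }
  ev <- pmax(ev, 0)
  frac <- cumsum(ev) / ncol(Xs)
  as.integer(which(frac >= variance_target - 1e-12)[1])
}

#' Intersection of significant CpGs across traits
#'
#' @param results named list mapping trait to its significant CpG ID vector.
#' @return sorted character vector of CpGs significant for every trait.
#' @export
cross_trait_overlap <- function(results) {
  assert_that(length(results) >= 2, "need >= 2 traits")
  sort(Reduce(intersect, results))
}

#' Annotate CpGs against an array manifest
#'
#' Left join onto a manifest table (cpg_id, chrom, position, gene; hg19
#' 1-based positions). Unmapped CpGs keep empty annotation and are flagged.
#' Duplicate manifest rows for a CpG keep the first occurrence with a
#' warning.
#'
#' @param ids character CpG IDs.
#' @param manifest data.frame with columns cpg_id, chrom, position, gene.
#' @return data.frame (cpg_id, chrom, position, gene, unmapped).
#' @export
annotate_cpgs <- function(ids, manifest) {
  need <- c("cpg_id", "chrom", "position", "gene")
  assert_that(all(need %in% names(manifest)),
              "manifest needs columns cpg_id, chrom, position, gene")
  if (anyDuplicated(manifest$cpg_id)) {
    warning("duplicate manifest rows; keeping the first per CpG")
    manifest <- manifest[!duplicated(manifest$cpg_id), , drop = FALSE]
  }
  i <- match(ids, manifest$cpg_id)
  out <- data.frame(cpg_id = ids,
                    chrom = manifest$chrom[i],
                    position = manifest$position[i],
                    gene = ifelse(is.na(i), "", manifest$gene[i]),
                    unmapped = is.na(i), stringsAsFactors = FALSE)
  out
}

#' Write EWAS summary statistics as TSV
#'
#' @param result `ewas_result`.
#' @param path output file.
#' @param manifest optional manifest for chrom/position annotation.
#' @return `path`, invisibly.
#' @export
write_ewas_tsv <- function(result, path, manifest = NULL) {
  tab <- result$table
  if (!is.null(manifest)) {
    ann <- annotate_cpgs(tab$cpg_id, manifest)
    tab <- cbind(tab[, "cpg_id", drop = FALSE], ann[, c("chrom", "position")],
                 tab[, setdiff(names(tab), "cpg_id")])
  }
  tab$model_tag <- result$model_tag
  write.table(format(tab, digits = 10, trim = TRUE, scientific = NA),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
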