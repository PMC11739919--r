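#' Weight table constructor
#'
#' CpG weight vector with an intercept, used for the smoking score and for
#' serialized EpiScore weights.
#'
#' @param cpg_ids character CpG IDs (unique).
#' @param weights finite numeric weights, one per CpG.
#' @param intercept scalar added to every score (default 0).
#' @return list of class `weight_table`.
#' @export
weight_table <- function(cpg_ids, weights, intercept = 0) {
  assert_that(!anyDuplicated(cpg_ids), "duplicate CpG IDs in weight table")
  assert_that(length(cpg_ids) == length(weights), "cpg_ids/weights length mismatch")
  assert_that(all(is.finite(weights)), "weights must be finite")
  structure(list(cpg_ids = as.character(cpg_ids), weights = as.numeric(weights),
                 intercept = intercept), class = "weight_table")
}

#' Weighted CpG smoking score
#'
#' score_i = intercept + sum_j w_j * beta_ij over the CpGs shared between the
#' weight table and the matrix (the 187-site weighted-sum design of published
#' smoking scores). Missing values are imputed with the cohort mean beta of
#' the CpG; weight CpGs absent from the matrix are dropped and counted.
#'
#' @param betas beta-scale [methylation_matrix()].
#' @param weights a [weight_table()].
#' @return numeric score per sample, with attributes `n_missing_cpgs`
#'   (weight CpGs absent from the matrix) and `imputed_fraction`.
#' @export
smoking_score <- function(betas, weights) {
  stopifnot(inherits(betas, "methylation_matrix"), inherits(weights, "weight_table"))
  assert_that(betas$scale == "beta", "smoking_score operates on beta values")
  present <- weights$cpg_ids %in% cpg_ids(betas)
  assert_that(any(present), "no overlap between weight CpGs and matrix CpGs")
  ids <- weights$cpg_ids[present]
  w <- weights$weights[present]
  B <- betas$values[, ids, drop = FALSE]
  imputed <- mean(is.na(B))
  if (anyNA(B)) {
    mu <- colMeans(B, na.rm = TRUE)
    idx <- which(is.na(B), arr.ind = TRUE)
    B[idx] <- mu[idx[, 2]]
  }
  score <- as.numeric(weights$intercept + B %*% w)
  names(score) <- sample_ids(betas)
  attr(score, "n_missing_cpgs") <- sum(!present)
  attr(score, "imputed_fraction") <- imputed
  score
}

# Equality-constrained least squares min ||y - R w||^2 s.t. sum(w)=1,
# restricted to a support set; returns w on the full index set (zeros off
# support) or NULL when the KKT system is singular.
eq_ls_support <- function(R, y, support) {
  k <- ncol(R)
  Rs <- R[, support, drop = FALSE]
  ks <- length(support)
  A <- rbind(cbind(crossprod(Rs), rep(1, ks)), c(rep(1, ks), 0))
  b <- c(crossprod(Rs, y), 1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  w <- numeric(k)
  w[support] <- sol[seq_len(ks)]
  w
}

#' Reference-based cell-type deconvolution
#'
#' For each sample solves min || beta_i - R w ||^2 subject to w >= 0 and
#' sum(w) = 1 (constrained least squares on the shared CpG panel). The
#' simplex-constrained problem is solved exactly by enumerating supports of
#' the small cell-type panel and checking feasibility; the feasible support
#' with minimal residual is returned. Missing betas are dropped per sample.
#'
#' @param betas beta-scale [methylation_matrix()].
#' @param ref a `cell_reference` (see [make_cell_reference()]).
#' @return matrix samples x cell types of fractions on the simplex, with
#'   attribute `residual_norm` (per-sample residual norm).
#' @export
deconvolve_cells <- function(betas, ref) {
  stopifnot(inherits(betas, "methylation_matrix"))
  assert_that(betas$scale == "beta", "deconvolve_cells operates on beta values")
  shared <- intersect(ref$cpg_ids, cpg_ids(betas))
  assert_that(length(shared) >= 10, "need >= 10 CpGs shared with the reference")
  R <- ref$means[shared, , drop = FALSE]
  k <- ncol(R)
  assert_that(k >= 2, "reference needs >= 2 cell types")
  assert_that(k <= 12, "support enumeration supports at most 12 cell types")
  cn <- kappa(R, exact = TRUE)
  if (qr(R)$rank < k)
    warning(sprintf("rank-deficient cell reference (condition number %.3g)", cn))
  B <- betas$values[, shared, drop = FALSE]
  n <- nrow(B)
  W <- matrix(NA_real_, n, k, dimnames = list(rownames(B), colnames(R)))
  rn <- numeric(n)
  supports <- lapply(seq_len(2^k - 1), function(s) which(bitwAnd(s, 2^(seq_len(k) - 1)) > 0))
  supports <- supports[order(-lengths(supports))]
  for (i in seq_len(n)) {
    obs <- !is.na(B[i, ])
    yi <- B[i, obs]
    Ri <- R[obs, , drop = FALSE]
    best <- NULL; best_rss <- Inf
    for (sup in supports) {
      w <- eq_ls_support(Ri, yi, sup)
      if (is.null(w) || any(w < -1e-10)) next
      rss <- sum((yi - Ri %*% w)^2)
      if (rss < best_rss - 1e-12) { best_rss <- rss; best <- w }
    }
    W[i, ] <- pmax(best, 0)
    W[i, ] <- W[i, ] / sum(W[i, ])
    rn[i] <- sqrt(best_rss)
  }
  attr(W, "residual_norm") <- rn
  W
}

#' Methylome principal components
#'
#' PCs of the column-standardized matrix via an eigendecomposition of the
#' smaller-dimension cross-product (exact truncated SVD). Constant CpGs are
#' dropped with a warning; the sign of each PC is fixed so that its largest
#' absolute loading is positive.
#'
#' @param mat a [methylation_matrix()] (typically corrected-M).
#' @param n_pcs number of components.
#' @return list with `scores` (samples x n_pcs), `variance_fraction`
#'   (length n_pcs, non-increasing), `loadings` (CpGs x n_pcs).
#' @export
methylome_pcs <- function(mat, n_pcs = 20) {
  stopifnot(inherits(mat, "methylation_matrix"))
  V <- mat$values
  if (anyNA(V)) {
    mu <- colMeans(V, na.rm = TRUE)
    idx <- which(is.na(V), arr.ind = TRUE)
    V[idx] <- mu[idx[, 2]]
  }
  sds <- apply(V, 2, sd)
  const <- sds < .Machine$double.eps * 100
  if (any(const)) {
    warning(sprintf("dropping %d constant CpG(s) before standardization", sum(const)))
    V <- V[, !const, drop = FALSE]
  }
  assert_that(n_pcs <= min(dim(V)), "n_pcs exceeds matrix rank bound")
  Xs <- scale(V)
  n <- nrow(Xs)
  total_var <- sum(Xs^2) / (n - 1)
  if (n <= ncol(Xs)) {
    ed <- eigen(tcrossprod(Xs) / (n - 1), symmetric = TRUE)
    ev <- pmax(ed$values, 0)
    scores <- ed$vectors[, seq_len(n_pcs), drop = FALSE] %*%
      diag(sqrt(ev[seq_len(n_pcs)] * (n - 1)), n_pcs)
    loadings <- crossprod(Xs, ed$vectors[, seq_len(n_pcs), drop = FALSE]) %*%
      diag(1 / sqrt(ev[seq_len(n_pcs)] * (n - 1)), n_pcs)
  } else {
    ed <- eigen(crossprod(Xs) / (n - 1), symmetric = TRUE)
    ev <- pmax(ed$values, 0)
    loadings <- ed$vectors[, seq_len(n_pcs), drop = FALSE]
    scores <- Xs %*% loadings
  }
  for (j in seq_len(n_pcs)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_pcs))
  rownames(scores) <- rownames(V)
  list(scores = scores,
       variance_fraction = ev[seq_len(n_pcs)] / total_var,
       loadings = loadings)
}

#' Read / write weight tables as TSV
#'
#' TSV with columns `cpg_id`, `weight`; the intercept travels in a
#' `# intercept:` header line.
#'
#' @param x a [weight_table()].
#' @param path file path.
#' @return `write_weight_table` returns `path` invisibly;
#'   `read_weight_table` returns a [weight_table()].
#' @export
write_weight_table <- function(x, path) {
  stopifnot(inherits(x, "weight_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# intercept: %.17g", x$intercept), con)
  write.table(data.frame(cpg_id = x$cpg_ids, weight = x$weights),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  first <- readLines(path, n = 1)
  intercept <- if (startsWith(first, "# intercept:"))
    as.numeric(sub("# intercept:", "", first)) else 0
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  weight_table(df$cpg_id, df$weight, intercept)
}
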