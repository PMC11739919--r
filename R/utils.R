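#' Column standardization
#'
#' Centre and scale the columns of a numeric matrix, tolerating missing
#' values. Zero-variance columns are returned as all-zero rather than NaN.
#'
#' @param x numeric matrix.
#' @return list with `x` (standardized matrix), `center`, `scale`.
#' @keywords internal
standardize_columns <- function(x) {
  ctr <- colMeans(x, na.rm = TRUE)
  scl <- apply(x, 2, sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  list(x = xs, center = ctr, scale = scl)
}

#' Derive a stage-specific seed from a global seed
#'
#' Deterministic hash of the global seed and a stage name, kept inside the
#' 32-bit integer range so it is a valid `set.seed()` argument.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genomic inflation factor from p-values
#'
#' lambda_GC = median observed chi-squared(1) / its null median (0.4549).
#'
#' @param p numeric vector of two-sided p-values.
#' @return scalar inflation factor.
#' @export
lambda_gc <- function(p) {
  p <- p[is.finite(p)]
  stopifnot(length(p) > 0, all(p > 0), all(p <= 1))
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

# Dirichlet draw (rows = observations)
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
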