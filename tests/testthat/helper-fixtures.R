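# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small training cohort exercising every confounder
small_cohort <- function() fixture("small_cohort", function() {
  simulate_cohort(sim_config(
    n_samples = 300, n_cpgs = 800, n_blocks = 100, n_causal = 10,
    family_spec = list(n_families = 40, sibs_per_family = 2), seed = 101))
})

# mid-size cohort for covariate-recovery checks (smoking r > 0.9 needs n ~ 2000)
covariate_cohort <- function() fixture("covariate_cohort", function() {
  simulate_cohort(sim_config(
    n_samples = 2000, n_cpgs = 1000, n_blocks = 150, n_causal = 10,
    family_spec = list(n_families = 100, sibs_per_family = 2), seed = 102))
})

# independent standardized "corrected-M" matrix with optional causal signal
ind_matrix <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%05d", seq_len(n)),
                              sprintf("cg%05d", seq_len(p))))
  mm <- methylation_matrix(X, "M")
  mm$scale <- "corrected-M"
  mm
}

expect_simplex <- function(W, tol = 1e-8) {
  expect_true(all(W >= -1e-10))
  expect_true(all(abs(rowSums(W) - 1) < tol))
}
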