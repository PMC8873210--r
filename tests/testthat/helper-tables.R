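# Published per-study p-values (4 dp) for the 12-study geriatric
# rehabilitation table, in study order: left-, right-, and two-sided.
published_study_pvalues <- matrix(c(
  0.6044, 0.3956, 0.7911,
  0.3928, 0.6072, 0.7857,
  0.7119, 0.2881, 0.5762,
  0.5638, 0.4362, 0.8724,
  0.3778, 0.6222, 0.7555,
  0.7948, 0.2052, 0.4103,
  0.7317, 0.2683, 0.5366,
  0.9949, 0.0051, 0.0102,
  0.5866, 0.4134, 0.8269,
  0.9995, 0.0005, 0.0011,
  0.9924, 0.0076, 0.0152,
  0.9844, 0.0156, 0.0313),
  ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("p_left", "p_right", "p_two")))

# absolute-tolerance comparison (testthat's tolerance is relative); the
# published tables fix an absolute printed precision per cell
expect_near <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}

# random p-value vectors with reproducible seeds, for property loops
random_pvalue_cases <- function(n_cases, seed, max_k = 20L) {
  set.seed(seed)
  lapply(seq_len(n_cases), function(i) {
    k <- sample(1:max_k, 1L)
    list(p = stats::runif(k), weights = stats::runif(k))
  })
}
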