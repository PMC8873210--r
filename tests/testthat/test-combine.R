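test_that("cauchy transform hits its exact anchor points and is antisymmetric", {
  expect_equal(cauchy_transform(0.5), 0)
  expect_equal(cauchy_transform(0.25), 1)
  expect_equal(cauchy_transform(0.75), -1)
  p <- c(0.01, 0.2, 0.4, 0.49, 0.6, 0.999)
  expect_equal(cauchy_transform(1 - p), -cauchy_transform(p),
               tolerance = 1e-12)
  # strictly decreasing
  grid <- seq(0.001, 0.999, by = 0.001)
  expect_true(all(diff(cauchy_transform(grid)) < 0))
  expect_error(cauchy_transform(0), "out of")
  expect_error(cauchy_transform(1), "out of")
  expect_error(cauchy_transform(1.5), "1.5")
})

test_that("cauchy transform stays accurate in the extreme tails", {
  # the cotangent and direct forms agree where both are accurate
  for (p in c(0.2, 0.24999, 0.251, 0.3)) {
    expect_equal(cauchy_transform(p), 1 / tan(pi * p), tolerance = 1e-12)
  }
  # a single tiny p-value round-trips through CCT to relative error < 1e-6
  for (p in c(1e-20, 1e-100, 1e-300)) {
    expect_equal(cct_pvalue(p)$pvalue, p, tolerance = 1e-6)
  }
})

test_that("CCT reproduces its closed-form and frozen example values", {
  # pair summing to one: the transforms cancel and the p-value is 0.5
  # (up to round-off of the stored complement 1 - p)
  for (p in c(0.1, 0.3, 0.45, 0.0001)) {
    expect_equal(cct_pvalue(c(p, 1 - p))$pvalue, 0.5, tolerance = 1e-9)
  }
  # identical p-values invert to themselves
  expect_equal(cct_pvalue(rep(0.1, 3))$pvalue, 0.1, tolerance = 1e-12)
  expect_equal(cct_pvalue(rep(0.73, 7))$pvalue, 0.73, tolerance = 1e-12)
  # frozen direct evaluation of the two-value combination
  expect_equal(cct_pvalue(c(0.996635, 0.0064627))$pvalue, 0.985969367827,
               tolerance = 1e-10)
  # p-value is the upper-tail Cauchy probability of the statistic
  res <- cct_pvalue(c(0.02, 0.6, 0.9))
  expect_equal(res$pvalue, pcauchy(res$statistic, lower.tail = FALSE),
               tolerance = 1e-14)
})

test_that("CCT weights are normalized and validated", {
  expect_equal(cct_pvalue(c(0.2, 0.8), weights = c(2, 2))$pvalue,
               cct_pvalue(c(0.2, 0.8))$pvalue)
  expect_equal(cct_pvalue(c(0.2, 0.8), weights = c(3, 1))$weights,
               c(0.75, 0.25))
  expect_error(cct_pvalue(c(0.2, 0.8), weights = c(0, 0)), "zero")
  expect_error(cct_pvalue(c(0.2, 0.8), weights = c(-1, 2)), "non-negative")
  expect_error(cct_pvalue(c(0.2, 0.8), weights = 1), "length")
  # p = 1 is clipped, not an error; a lone {1, 0.5} pair tends to 1
  expect_equal(cct_pvalue(c(1, 0.5))$pvalue, 1, tolerance = 1e-10)
  expect_error(cct_pvalue(c(0, 0.5)), "out of")
})

test_that("MinP implements Sidak and Bonferroni calibrations", {
  expect_equal(minp_pvalue(0.37)$pvalue, 0.37)               # k = 1
  expect_equal(minp_pvalue(0.37, "bonferroni")$pvalue, 0.37)
  p <- c(0.2, 0.05, 0.8)
  expect_equal(minp_pvalue(p, "sidak")$pvalue, 1 - (1 - 0.05)^3)
  expect_equal(minp_pvalue(p, "bonferroni")$pvalue, 0.15)
  expect_equal(minp_pvalue(c(0.99984, 0.000157), "bonferroni")$pvalue,
               0.000314)
  # Bonferroni caps at 1
  expect_equal(minp_pvalue(c(0.9, 0.8), "bonferroni")$pvalue, 1)
  # never below the minimum input
  expect_gte(minp_pvalue(p, "sidak")$pvalue, min(p))
  expect_error(minp_pvalue(p, "holm"), "arg")
})

test_that("MCM is the capped double of the smaller first-stage p-value", {
  res <- mcm_pvalue(c(0.99984, 0.000157), minp_mode = "bonferroni")
  expect_equal(res$pvalue, 0.000628)
  expect_true(is.na(res$statistic))
  expect_equal(mcm_pvalue(c(0.5, 0.5))$pvalue, 1)
  # identity MCM = min(1, 2 * min(p_cct, p_minp)) on random inputs
  for (case in random_pvalue_cases(25, seed = 42)) {
    p_cct <- cct_pvalue(case$p)$pvalue
    p_minp <- minp_pvalue(case$p, "bonferroni")$pvalue
    expect_equal(mcm_pvalue(case$p, "bonferroni")$pvalue,
                 min(1, 2 * min(p_cct, p_minp)))
  }
})

test_that("CMC applies an equal-weight CCT to the two first-stage p-values", {
  expect_near(cmc_pvalue(c(0.99984, 0.000157), "bonferroni")$pvalue,
              0.00063, 1.5e-5)
  # clipping handles a first-stage MinP of exactly 1
  expect_equal(cmc_pvalue(c(0.5, 0.5))$pvalue, 1, tolerance = 1e-10)
  for (case in random_pvalue_cases(25, seed = 43)) {
    p_cct <- cct_pvalue(case$p)$pvalue
    p_minp <- minp_pvalue(case$p, "bonferroni")$pvalue
    expect_equal(cmc_pvalue(case$p, "bonferroni")$pvalue,
                 cct_pvalue(c(p_cct, p_minp))$pvalue)
  }
})

test_that("Fisher matches the chi-square closed form", {
  expect_equal(fisher_pvalue(0.123)$pvalue, 0.123, tolerance = 1e-12)
  res <- fisher_pvalue(c(0.5, 0.5))
  expect_equal(res$statistic, -2 * log(0.25), tolerance = 1e-12)
  # oracle: chi-square(4) survival function (1 + x/2) exp(-x/2)
  x <- res$statistic
  expect_equal(res$pvalue, (1 + x / 2) * exp(-x / 2), tolerance = 1e-12)
  expect_error(fisher_pvalue(c(0, 0.5)), "out of")
})

test_that("Stouffer's z is symmetric and exact at k = 1", {
  expect_equal(stouffer_pvalue(0.321)$pvalue, 0.321, tolerance = 1e-12)
  p <- c(0.1, 0.37, 0.62, 0.9)
  expect_equal(stouffer_pvalue(p)$pvalue + stouffer_pvalue(1 - p)$pvalue, 1,
               tolerance = 1e-12)
  expect_error(stouffer_pvalue(c(0.5, 1)), "inside")
})

test_that("combine_pvalues runs all methods with per-test MinP conventions", {
  p <- c(0.02, 0.6, 0.9)
  tab <- combine_pvalues(p)
  expect_setequal(tab$method,
                  c("CCT", "MinP", "MCM", "CMC", "Fisher", "StoufferZ"))
  expect_equal(tab$pvalue[tab$method == "MinP"],
               minp_pvalue(p, "sidak")$pvalue)
  expect_equal(tab$pvalue[tab$method == "MCM"],
               mcm_pvalue(p, "bonferroni")$pvalue)
  tab2 <- combine_pvalues(p, minp_mode = "sidak")
  expect_equal(tab2$pvalue[tab2$method == "MCM"],
               mcm_pvalue(p, "sidak")$pvalue)
  expect_error(combine_pvalues(p, methods = "tippett"), "unknown method")
})
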