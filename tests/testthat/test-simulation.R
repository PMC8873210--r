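test_that("effect specs validate their shape", {
  expect_s3_class(effect_spec(10, 5, 2), "effect_spec")
  expect_error(effect_spec(2, 3, 1), "n_negative")
  expect_error(effect_spec(2, 0, 0), "null configuration")
  expect_error(effect_spec(0, 0, 1), "at least one")
  expect_error(effect_spec(1, 0, -1), "non-negative")
})

test_that("mean placement puts negative effects first by default", {
  eff <- effect_spec(4, 2, 1.5)
  expect_equal(robcomb:::.effect_mean(eff, 8),
               c(-1.5, -1.5, 1.5, 1.5, 0, 0, 0, 0))
  spread <- robcomb:::.effect_mean(eff, 20, placement = "spread")
  expect_equal(sum(spread != 0), 4L)
  expect_equal(sum(spread < 0), 2L)
})

test_that("mvn sampling is seeded, correlated, and mean-shifted correctly", {
  spec <- correlation_spec("expo", 2, 0.5)
  z1 <- sample_mvn(spec, effect_spec(), n = 1e5, seed = 4)
  z2 <- sample_mvn(spec, effect_spec(), n = 1e5, seed = 4)
  expect_identical(z1, z2)
  expect_equal(cor(z1)[1, 2], 0.5, tolerance = 0.01)
  # null calibration: column means within 4 SE of zero
  expect_true(all(abs(colMeans(z1)) < 4 / sqrt(1e5)))
  # alternative: shifted means
  za <- sample_mvn(correlation_spec("expo", 3, 0.5), effect_spec(2, 1, 2),
                   n = 2e4, seed = 5)
  expect_equal(colMeans(za), c(-2, 2, 0), tolerance = 0.05)
})

test_that("three-sided p-values satisfy their identities", {
  ps <- three_sided_pvalues(0)
  expect_equal(unlist(ps), c(left = 0.5, right = 0.5, two = 1))
  expect_equal(three_sided_pvalues(1.959964)$two, 0.05, tolerance = 1e-6)
  z <- c(-3, -0.5, 0.2, 4)
  ps <- three_sided_pvalues(z)
  expect_identical(ps$left + ps$right, rep(1, 4))
  expect_equal(ps$left, three_sided_pvalues(-z)$right)
  expect_equal(ps$two, 2 * pmin(ps$left, ps$right))
  expect_error(three_sided_pvalues(c(1, Inf)), "finite")
})

test_that("simulation configs validate and sort their fields", {
  spec <- correlation_spec("expo", 5, 0.5)
  cfg <- simulation_config(spec, n_replicates = 100,
                           alphas = c(0.001, 0.05, 0.01))
  expect_equal(cfg$alphas, c(0.05, 0.01, 0.001))
  expect_error(simulation_config(spec, n_replicates = 100, alphas = 0.6),
               "0, 0.5")
  expect_error(simulation_config(spec, n_replicates = 100, tests = "ACAT"),
               "subset")
  expect_error(simulation_config(spec, n_replicates = 100,
                                 tests = character()), "subset")
  expect_error(simulation_config(spec, effect = effect_spec(6, 0, 1),
                                 n_replicates = 100), "exceeds k")
})

test_that("rejection rates are reproducible and invariant to batching", {
  spec <- correlation_spec("expo", 3, 0.5)
  cfg <- function(n) simulation_config(spec, n_replicates = n, seed = 8,
                                       sides = "left", alphas = 0.05)
  t1 <- estimate_rejection_rates(cfg(5e4))
  t2 <- estimate_rejection_rates(cfg(5e4))
  expect_identical(t1, t2)
  # the first 1e5-replicate block does not depend on the total length:
  # a longer run restricted to the same alpha agrees with the binomial
  # envelope of the shorter one
  expect_equal(t1$ratio, estimate_rejection_rates(cfg(15e4))$ratio,
               tolerance = 0.15)
  expect_equal(t1$ratio, t1$rate / t1$alpha)
  expect_equal(t1$se, sqrt(t1$rate * (1 - t1$rate) / 5e4))
})

test_that("CCT and Sidak-MinP are calibrated under independence", {
  cfg <- simulation_config(correlation_spec("expo", 5, 0),
                           n_replicates = 1e5, alphas = c(0.05, 0.01),
                           seed = 31, sides = "left",
                           tests = c("CCT", "MinP"))
  tab <- estimate_rejection_rates(cfg)
  for (i in seq_len(nrow(tab))) {
    expect_lt(abs(tab$ratio[i] - 1), 4 * tab$se[i] / tab$alpha[i] + 1e-9)
  }
})

test_that("MinP, MCM and CMC do not exceed nominal level under dependence", {
  # small-alpha conservatism across the three models (reduced replicates)
  specs <- list(correlation_spec("expo", 10, 0.5),
                correlation_spec("poly", 10, 1.5),
                correlation_spec("sig", 10, 0.5))
  for (spec in specs) {
    cfg <- simulation_config(spec, n_replicates = 1e5, alphas = 0.001,
                             seed = 17, sides = "left",
                             tests = c("MinP", "MCM", "CMC"))
    tab <- estimate_rejection_rates(cfg)
    for (i in seq_len(nrow(tab))) {
      expect_lte(tab$ratio[i], 1 + 4 * tab$se[i] / tab$alpha[i])
    }
  }
})

test_that("MinP beats CCT when effects point both ways (one-sided p-values)", {
  cfg <- simulation_config(correlation_spec("expo", 20, 0.5),
                           effect = effect_spec(10, 5, 2),
                           n_replicates = 1e5, alphas = 0.05, seed = 41,
                           sides = "left", tests = c("CCT", "MinP"))
  tab <- estimate_rejection_rates(cfg)
  expect_gt(tab$rate[tab$test == "MinP"], tab$rate[tab$test == "CCT"])
})

test_that("run_grid stacks configs into the tidy layout", {
  cfgs <- table1_grid_configs(n_replicates = 1000, seed = 3)
  expect_length(cfgs, 12L)
  small <- run_grid(cfgs[c(1, 5)])
  expect_equal(names(small),
               c("model", "k", "parameter", "test", "side", "alpha",
                 "rate", "ratio", "se"))
  expect_equal(nrow(small), 32L)  # 2 configs x 4 tests x 4 alphas
  expect_setequal(unique(small$model), c("expo", "poly"))
  f <- tempfile(fileext = ".csv")
  run_grid(cfgs[1], file = f)
  expect_equal(nrow(read.csv(f)), 16L)
  expect_error(run_grid(list()), "non-empty")
})
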