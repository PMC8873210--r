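# Monte-Carlo machinery: multivariate normal z-scores under structured
# correlation, three-sided p-values, and empirical rejection-rate tables
# (type-I error ratios under the null, power under shifted means).

# Replicates are processed in fixed blocks so that memory stays bounded and
# results do not depend on how the work is batched: each block draws its own
# deterministic seed from (config seed, block index).
.BLOCK_SIZE <- 100000L

.block_seed <- function(seed, block) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                block * 2654435761) %% 2147483647)
}

#' Specify the mean shift of the alternative hypothesis
#'
#' Under the global alternative a subset of the z-score vector has mean
#' `+mu` or `-mu`: `n_significant` coordinates are shifted, the first
#' `n_negative` of them negatively. `mu = 0` (with no significant
#' coordinates) is the global null.
#'
#' @param n_significant number of shifted coordinates.
#' @param n_negative how many of the shifted coordinates get mean `-mu`.
#' @param mu non-negative effect magnitude (in z-score units).
#' @return an object of class `"effect_spec"`.
#' @examples
#' effect_spec()                   # global null
#' effect_spec(10, 5, mu = 2)      # 10 shifted, 5 of them negative
#' @export
effect_spec <- function(n_significant = 0L, n_negative = 0L, mu = 0) {
  if (n_significant < 0 || n_negative < 0 || n_negative > n_significant) {
    stop("need 0 <= n_negative <= n_significant", call. = FALSE)
  }
  if (mu < 0) stop("mu must be non-negative", call. = FALSE)
  if (mu == 0 && n_significant > 0) {
    stop("mu = 0 is the null configuration; use n_significant = 0",
         call. = FALSE)
  }
  if (mu > 0 && n_significant == 0) {
    stop("mu > 0 requires at least one significant coordinate",
         call. = FALSE)
  }
  structure(list(n_significant = as.integer(n_significant),
                 n_negative = as.integer(n_negative), mu = mu),
            class = "effect_spec")
}

# mean vector for k coordinates; placement decides which indices shift
.effect_mean <- function(effect, k, placement = c("head", "spread",
                                                  "random"), seed = NULL) {
  placement <- match.arg(placement)
  ns <- effect$n_significant
  if (ns > k) {
    stop("n_significant exceeds k", call. = FALSE)
  }
  mu <- numeric(k)
  if (ns == 0L) return(mu)
  idx <- switch(placement,
    head = seq_len(ns),
    spread = unique(round(seq(1, k, length.out = ns))),
    random = {
      if (!is.null(seed)) set.seed(seed)
      sort(sample.int(k, ns))
    }
  )
  if (length(idx) != ns) {
    stop("placement could not allocate distinct indices", call. = FALSE)
  }
  mu[idx] <- effect$mu
  mu[idx[seq_len(effect$n_negative)]] <- -effect$mu
  mu
}

#' Configure one Monte-Carlo rejection-rate experiment
#'
#' @param spec a [correlation_spec()].
#' @param effect an [effect_spec()]; defaults to the global null.
#' @param n_replicates number of Monte-Carlo replicates.
#' @param alphas significance levels, each in (0, 0.5); stored in
#'   decreasing order.
#' @param seed integer seed; the experiment is bit-reproducible given the
#'   seed and invariant to internal batching.
#' @param tests subset of `"CCT"`, `"MinP"`, `"MCM"`, `"CMC"` to evaluate.
#' @param sides subset of `"left"`, `"right"`, `"two"`: which per-variable
#'   p-values to combine.
#' @param minp_mode calibration of the MinP stage used throughout the
#'   experiment (also inside MCM/CMC): Sidak by default, exact under
#'   independence; switch to Bonferroni to bound the variant choice.
#' @param placement which coordinates receive the mean shift: the first
#'   `n_significant` (`"head"`, default), evenly spread, or random.
#' @return an object of class `"simulation_config"`.
#' @examples
#' simulation_config(correlation_spec("expo", 5, 0.5), n_replicates = 1e4)
#' @export
simulation_config <- function(spec, effect = effect_spec(),
                              n_replicates,
                              alphas = c(0.05, 0.01, 0.001, 0.0001),
                              seed = 1L,
                              tests = c("CCT", "MinP", "MCM", "CMC"),
                              sides = c("left", "right", "two"),
                              minp_mode = c("sidak", "bonferroni"),
                              placement = c("head", "spread", "random")) {
  stopifnot(inherits(spec, "correlation_spec"),
            inherits(effect, "effect_spec"))
  if (effect$n_significant > spec$k) {
    stop("n_significant exceeds k", call. = FALSE)
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (length(alphas) < 1 || any(alphas <= 0 | alphas >= 0.5)) {
    stop("significance levels must lie in (0, 0.5)", call. = FALSE)
  }
  known_tests <- c("CCT", "MinP", "MCM", "CMC")
  if (length(tests) == 0 || !all(tests %in% known_tests)) {
    stop("tests must be a non-empty subset of ",
         paste(known_tests, collapse = ", "), call. = FALSE)
  }
  known_sides <- c("left", "right", "two")
  if (length(sides) == 0 || !all(sides %in% known_sides)) {
    stop("sides must be a non-empty subset of left, right, two",
         call. = FALSE)
  }
  minp_mode <- match.arg(minp_mode)
  placement <- match.arg(placement)
  structure(list(spec = spec, effect = effect,
                 n_replicates = as.integer(n_replicates),
                 alphas = sort(unique(alphas), decreasing = TRUE),
                 seed = as.integer(seed), tests = unique(tests),
                 sides = unique(sides), minp_mode = minp_mode,
                 placement = placement),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config\n")
  print(x$spec)
  cat(sprintf("  effect: %d significant (%d negative), mu = %g\n",
              x$effect$n_significant, x$effect$n_negative, x$effect$mu))
  cat(sprintf("  %d replicates, seed %d, MinP mode %s\n",
              x$n_replicates, x$seed, x$minp_mode))
  cat("  tests:", paste(x$tests, collapse = ", "),
      "| sides:", paste(x$sides, collapse = ", "),
      "| alphas:", paste(x$alphas, collapse = ", "), "\n")
  invisible(x)
}

#' Draw correlated z-scores
#'
#' Samples `n` i.i.d. rows from MVN(mean, Sigma), where Sigma comes from
#' the correlation spec and the mean vector from the effect spec (zero
#' under the null). Sampling goes through the eigendecomposition factor,
#' so the singular `sig` model works like the full-rank models.
#'
#' @param spec a [correlation_spec()].
#' @param effect an [effect_spec()].
#' @param n number of replicates (rows).
#' @param seed integer seed; identical seeds give identical matrices.
#' @param placement see [simulation_config()].
#' @return an `n x k` numeric matrix of z-scores.
#' @examples
#' z <- sample_mvn(correlation_spec("expo", 2, 0.5), effect_spec(), 1e3, 1)
#' cor(z)[1, 2]
#' @export
sample_mvn <- function(spec, effect = effect_spec(), n, seed = 1L,
                       placement = "head") {
  stopifnot(inherits(spec, "correlation_spec"))
  b <- factorize_for_sampling(build_sigma(spec))
  mu <- .effect_mean(effect, spec$k, placement, seed = seed)
  .sample_mvn_factor(b, mu, n, seed)
}

.sample_mvn_factor <- function(b, mu, n, seed) {
  set.seed(seed)
  e <- matrix(stats::rnorm(n * nrow(b)), n, nrow(b))
  x <- e %*% b
  if (any(mu != 0)) x <- sweep(x, 2L, mu, "+")
  x
}

#' Left-, right-, and two-sided p-values of z-scores
#'
#' For each z: left p-value `pnorm(z)`, right p-value `1 - pnorm(z)`
#' (so left + right = 1 exactly), and two-sided p-value
#' `2 * min(left, right)`, i.e. `2 * pnorm(-|z|)`.
#'
#' @param z numeric vector or matrix of z-scores.
#' @return a list with elements `left`, `right`, `two`, each shaped like
#'   `z`.
#' @examples
#' three_sided_pvalues(c(-1.96, 0, 1.96))
#' @export
three_sided_pvalues <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  left <- stats::pnorm(z)
  right <- 1 - left
  list(left = left, right = right, two = 2 * pmin(left, right))
}

# Vectorized per-replicate combined p-values for an n x k p-value matrix.
# Returns a named list with one numeric vector (length n) per test.
# Equal CCT weights throughout (the simulation design).
.row_combine <- function(pm, tests, minp_mode) {
  n <- nrow(pm)
  k <- ncol(pm)
  out <- list()
  need_cct <- any(c("CCT", "MCM", "CMC") %in% tests)
  need_minp <- any(c("MinP", "MCM", "CMC") %in% tests)
  if (need_cct) {
    # clip: pnorm can underflow to 0 (|z| > 38) or round to 1
    pc <- pmin(pmax(pm, 1e-300), 1 - .CT_EPS)
    tstat <- rowMeans(matrix(.ct(pc), n, k))
    p_cct <- stats::pcauchy(tstat, lower.tail = FALSE)
  }
  if (need_minp) {
    mn <- pm[, 1L]
    if (k > 1L) for (j in 2:k) mn <- pmin(mn, pm[, j])
    p_minp <- if (minp_mode == "sidak") 1 - (1 - mn)^k else pmin(1, k * mn)
  }
  if ("CCT" %in% tests) out$CCT <- p_cct
  if ("MinP" %in% tests) out$MinP <- p_minp
  if ("MCM" %in% tests) out$MCM <- pmin(1, 2 * pmin(p_cct, p_minp, 0.5))
  if ("CMC" %in% tests) {
    t2 <- 0.5 * (matrix(.ct(pmax(pmin(p_cct, 1 - .CT_EPS), 1e-300)), n) +
                   matrix(.ct(pmax(pmin(p_minp, 1 - .CT_EPS), 1e-300)), n))
    out$CMC <- stats::pcauchy(as.numeric(t2), lower.tail = FALSE)
  }
  out
}

#' Estimate empirical rejection rates of the combined tests
#'
#' Runs the Monte-Carlo experiment described by a [simulation_config()]:
#' draws correlated z-scores, forms left/right/two-sided p-values per
#' replicate, applies the selected combination tests, and counts rejections
#' at each significance level. A replicate is rejected when the combined
#' p-value is `<= alpha` (the convention is inclusive; at the levels used
#' here the difference from strict inequality is negligible, but fixed).
#'
#' Under the global null the `ratio` column (rate / alpha) measures type-I
#' calibration: 1 is exact, below 1 conservative. Under a mean shift the
#' `rate` column is the empirical power.
#'
#' Replicates are processed in fixed 100,000-replicate blocks with
#' deterministic per-block seeds, so memory stays bounded (about 1 GB at
#' k = 100) and the result is identical however the blocks are scheduled.
#'
#' @param config a [simulation_config()].
#' @return a data frame of class `"rejection_table"` with columns `test`,
#'   `side`, `alpha`, `rate`, `ratio` (= rate/alpha) and `se` (binomial
#'   Monte-Carlo standard error `sqrt(rate (1-rate) / n)`), with the
#'   config attached as attribute `"config"`.
#' @examples
#' cfg <- simulation_config(correlation_spec("expo", 5, 0.5),
#'                          n_replicates = 2e4, sides = "left", seed = 7)
#' estimate_rejection_rates(cfg)
#' @export
estimate_rejection_rates <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  b <- factorize_for_sampling(build_sigma(config$spec))
  mu <- .effect_mean(config$effect, config$spec$k, config$placement,
                     seed = config$seed)
  n <- config$n_replicates
  n_blocks <- ceiling(n / .BLOCK_SIZE)
  counts <- array(
    0, dim = c(length(config$tests), length(config$sides),
               length(config$alphas)),
    dimnames = list(config$tests, config$sides, NULL))
  for (blk in seq_len(n_blocks)) {
    nb <- if (blk < n_blocks) .BLOCK_SIZE else n - (n_blocks - 1L) * .BLOCK_SIZE
    z <- .sample_mvn_factor(b, mu, nb, .block_seed(config$seed, blk))
    ps <- three_sided_pvalues(z)
    for (side in config$sides) {
      comb <- .row_combine(ps[[side]], config$tests, config$minp_mode)
      for (test in config$tests) {
        for (ai in seq_along(config$alphas)) {
          counts[test, side, ai] <- counts[test, side, ai] +
            sum(comb[[test]] <= config$alphas[ai])
        }
      }
    }
  }
  grid <- expand.grid(alpha = config$alphas, side = config$sides,
                      test = config$tests, stringsAsFactors = FALSE)
  rate <- mapply(function(test, side, ai) counts[test, side, ai] / n,
                 grid$test, grid$side,
                 match(grid$alpha, config$alphas))
  out <- data.frame(test = grid$test, side = grid$side, alpha = grid$alpha,
                    rate = rate, ratio = rate / grid$alpha,
                    se = sqrt(rate * (1 - rate) / n),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "config") <- config
  class(out) <- c("rejection_table", "data.frame")
  out
}

#' Run a grid of simulation configs
#'
#' Evaluates each config with [estimate_rejection_rates()] and stacks the
#' results into one tidy table with the model, dimension and parameter of
#' each config as leading columns; optionally written as CSV.
#'
#' @param configs a non-empty list of [simulation_config()] objects.
#' @param file optional path for a CSV copy of the combined table.
#' @return a data frame with columns
#'   `model, k, parameter, test, side, alpha, rate, ratio, se`.
#' @export
run_grid <- function(configs, file = NULL) {
  if (!is.list(configs) || length(configs) == 0 ||
      !all(vapply(configs, inherits, logical(1), "simulation_config"))) {
    stop("configs must be a non-empty list of simulation_config objects",
         call. = FALSE)
  }
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    tab <- tryCatch(estimate_rejection_rates(cfg), error = function(e) {
      stop(sprintf("config %d (%s, k = %d) failed: %s",
                   i, cfg$spec$model, cfg$spec$k, conditionMessage(e)),
           call. = FALSE)
    })
    cbind(data.frame(model = cfg$spec$model, k = cfg$spec$k,
                     parameter = cfg$spec$parameter,
                     stringsAsFactors = FALSE),
          as.data.frame(tab))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Configs for the null-calibration grid
#'
#' The standard type-I error grid: the three correlation models (expo
#' rho = 0.5, poly r = 1.5, sig d = 0.5) crossed with
#' k in \{5, 10, 20, 100\}, all four tests, left-sided p-values, and
#' significance levels 0.05 down to 1e-4 under the global null.
#'
#' @param n_replicates replicates per config.
#' @param seed base seed; config `i` uses `seed + i - 1`.
#' @param sides which p-value sides to evaluate (left-sided by default).
#' @return a list of [simulation_config()] objects (12 configs; the full
#'   grid yields 192 rows of rejection rates for the default sides).
#' @export
table1_grid_configs <- function(n_replicates = 1e6, seed = 1L,
                                sides = "left") {
  models <- list(c("expo", 0.5), c("poly", 1.5), c("sig", 0.5))
  ks <- c(5L, 10L, 20L, 100L)
  cfgs <- list()
  i <- 0L
  for (m in models) {
    for (k in ks) {
      i <- i + 1L
      cfgs[[i]] <- simulation_config(
        correlation_spec(m[[1]], k, as.numeric(m[[2]])),
        n_replicates = n_replicates, seed = seed + i - 1L, sides = sides)
    }
  }
  cfgs
}
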