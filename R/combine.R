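# Core p-value combination tests: Cauchy combination (CCT), MinP,
# the two-stage MCM and CMC, Fisher's chi-square, and Stouffer's z.

# p = 1 inputs to CCT are clipped to 1 - .CT_EPS before transforming
.CT_EPS <- 1e-15

#' Validate a vector of p-values and optional weights
#'
#' Checks that all p-values lie in (0, 1] and, if weights are supplied, that
#' they are non-negative with at least one positive entry and match the
#' p-values in length. Weights are normalized to sum to one; when absent,
#' equal weights 1/k are returned.
#'
#' @param p numeric vector of p-values, each in (0, 1].
#' @param weights optional numeric vector of non-negative weights.
#' @return a list with elements `p` and `weights` (normalized).
#' @keywords internal
validate_pvalues <- function(p, weights = NULL) {
  if (!is.numeric(p) || length(p) < 1L) {
    stop("p-values must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(p) || any(!is.finite(p))) {
    stop("p-values contain NA or non-finite entries", call. = FALSE)
  }
  bad <- p <= 0 | p > 1
  if (any(bad)) {
    stop(sprintf("p-value out of (0,1]: %.6g", p[which(bad)[1L]]),
         call. = FALSE)
  }
  k <- length(p)
  if (is.null(weights)) {
    weights <- rep(1 / k, k)
  } else {
    if (!is.numeric(weights) || length(weights) != k) {
      stop(sprintf("weights length (%d) must equal p-values length (%d)",
                   length(weights), k), call. = FALSE)
    }
    if (anyNA(weights) || any(weights < 0)) {
      stop("weights must be non-negative and non-missing", call. = FALSE)
    }
    if (sum(weights) <= 0) {
      stop("weights must not all be zero", call. = FALSE)
    }
    weights <- weights / sum(weights)
  }
  list(p = p, weights = weights)
}

#' Cauchy transform of p-values
#'
#' Maps a p-value to the standard Cauchy scale via `tan((0.5 - p) * pi)`.
#' Under a uniform null the result is standard Cauchy distributed. The
#' transform is strictly decreasing in `p`, and `p` and `1 - p` map to
#' values of opposite sign.
#'
#' Away from the center the argument `0.5 - p` cannot represent `p`
#' accurately, so for `p < 0.25` the algebraically identical cotangent
#' form `1 / tan(p * pi)` is used and for `p > 0.75` the mirrored form
#' `-1 / tan((1 - p) * pi)`; this keeps the relative error below 1e-6
#' (in practice a few ulp) for p-values as small as 1e-300.
#'
#' @param p numeric vector of p-values, each strictly inside (0, 1).
#' @return numeric vector of transformed values on the Cauchy scale.
#' @examples
#' cauchy_transform(c(0.25, 0.5, 0.75))
#' @export
cauchy_transform <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  bad <- !is.finite(p) | p <= 0 | p >= 1
  if (any(bad)) {
    stop(sprintf("p-value out of the open interval (0,1): %.6g",
                 p[which(bad)[1L]]), call. = FALSE)
  }
  .ct(p)
}

# unchecked transform core, shared by the vectorized simulation path;
# branch bounds chosen so each expression keeps full relative precision
# (1 - p is exact for p >= 0.5, and tanpi is accurate near 0)
.ct <- function(p) {
  out <- numeric(length(p))
  lo <- p < 0.25
  hi <- p > 0.75
  mid <- !lo & !hi
  out[lo] <- 1 / tanpi(p[lo])
  out[hi] <- -1 / tanpi(1 - p[hi])
  out[mid] <- tanpi(0.5 - p[mid])
  out
}

# p = 1 is a legal input to CCT; the transform's pole there is handled by
# clipping to 1 - 1e-15 (the limit convention: tan((0.5 - 1) * pi) -> -Inf).
.clip_for_cct <- function(p) pmin(p, 1 - .CT_EPS)

.combined_result <- function(method, statistic, pvalue, k,
                             minp_mode = NA_character_, weights = NULL) {
  structure(
    list(method = method, statistic = statistic, pvalue = pvalue, k = k,
         minp_mode = minp_mode, weights = weights),
    class = "combined_pvalue"
  )
}

#' @export
print.combined_pvalue <- function(x, digits = 4L, ...) {
  cat(x$method, "p-value combination\n")
  cat("  k =", x$k)
  if (!is.na(x$minp_mode)) cat(", MinP mode =", x$minp_mode)
  cat("\n")
  if (!is.na(x$statistic)) {
    cat("  statistic =", signif(x$statistic, digits), "\n")
  }
  cat("  combined p-value =", signif(x$pvalue, digits), "\n")
  invisible(x)
}

#' @export
format.combined_pvalue <- function(x, ...) {
  sprintf("%s: p = %s", x$method, format(x$pvalue, ...))
}

#' Cauchy combination test (CCT)
#'
#' Combines p-values through the weighted sum of their Cauchy transforms,
#' \eqn{T = \sum_i w_i \tan[(0.5 - P_i)\pi]}, and reports the upper-tail
#' standard Cauchy probability of the observed statistic. Under the global
#' null with independent uniform p-values the statistic is exactly standard
#' Cauchy for any weights summing to one; under dependence the Cauchy tail
#' still bounds the type-I error at small significance levels.
#'
#' The combined p-value always lies between the smallest and largest input
#' p-value, so CCT can never give stronger evidence than the strongest
#' individual study. For a pair `p` and `1 - p` (e.g. left- and right-sided
#' p-values of the same statistic) the transforms cancel and the combined
#' p-value is exactly 0.5, making the test powerless in that configuration.
#'
#' Inputs equal to 1 are clipped to `1 - 1e-15` before transforming;
#' zero p-values are rejected.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param weights optional non-negative weights, normalized internally to
#'   sum to one; equal weights by default.
#' @return an object of class `"combined_pvalue"` with elements `method`,
#'   `statistic`, `pvalue`, `k`, and the normalized `weights`.
#' @examples
#' cct_pvalue(c(0.01, 0.04, 0.3))
#' cct_pvalue(c(0.3, 0.7))  # pair summing to one: exactly 0.5
#' @references Liu, Y. and Xie, J. (2020) Cauchy combination test: a powerful
#'   test with analytic p-value calculation under arbitrary dependency
#'   structures. JASA 115, 393-402.
#' @seealso [minp_pvalue()], [mcm_pvalue()], [cmc_pvalue()]
#' @export
cct_pvalue <- function(p, weights = NULL) {
  v <- validate_pvalues(p, weights)
  stat <- sum(v$weights * .ct(.clip_for_cct(v$p)))
  pval <- stats::pcauchy(stat, lower.tail = FALSE)
  .combined_result("CCT", stat, pval, length(v$p), weights = v$weights)
}

#' Minimum-p (MinP) global test
#'
#' Combines p-values through their minimum, calibrated either by the Sidak
#' formula \eqn{1 - (1 - p_{min})^k} (exact under independence) or by the
#' Bonferroni bound \eqn{\min(1, k\, p_{min})} (valid under arbitrary
#' dependence). Weights are not used; the reported statistic is the minimum
#' p-value, and the combined p-value is never below it.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param mode `"sidak"` (default) or `"bonferroni"`.
#' @return an object of class `"combined_pvalue"`.
#' @examples
#' minp_pvalue(c(0.02, 0.8, 0.4))
#' minp_pvalue(c(0.02, 0.8, 0.4), mode = "bonferroni")
#' @export
minp_pvalue <- function(p, mode = c("sidak", "bonferroni")) {
  mode <- match.arg(mode)
  v <- validate_pvalues(p)
  k <- length(v$p)
  pmin_ <- min(v$p)
  pval <- switch(mode,
    sidak = 1 - (1 - pmin_)^k,
    bonferroni = min(1, k * pmin_)
  )
  .combined_result("MinP", pmin_, pval, k, minp_mode = mode)
}

#' MinP-CCT-MinP (MCM) two-stage test
#'
#' Applies both CCT and MinP to the same p-values and combines the two
#' resulting (dependent) p-values with a second Bonferroni/MinP stage:
#' \eqn{p_{MCM} = 2 \min\{p_{CCT}, p_{MinP}, 0.5\}}. The test inherits
#' CCT's power when the small p-values reinforce each other and MinP's
#' robustness when they do not, and controls the type-I error rate at small
#' significance levels under arbitrary dependence.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param minp_mode calibration for the inner MinP stage; Bonferroni by
#'   default (the robust choice for the dependent two-stage construction).
#' @param weights optional weights passed to the inner CCT stage.
#' @return an object of class `"combined_pvalue"`; the `statistic` is `NA`
#'   (MCM is defined by its p-value only).
#' @examples
#' mcm_pvalue(c(0.99, 0.001, 0.6))
#' @export
mcm_pvalue <- function(p, minp_mode = c("bonferroni", "sidak"),
                       weights = NULL) {
  minp_mode <- match.arg(minp_mode)
  p_cct <- cct_pvalue(p, weights)$pvalue
  p_minp <- minp_pvalue(p, mode = minp_mode)$pvalue
  pval <- 2 * min(p_cct, p_minp, 0.5)
  .combined_result("MCM", NA_real_, pval, length(p), minp_mode = minp_mode)
}

#' CCT-MinP-CCT (CMC) two-stage test
#'
#' Applies both CCT and MinP to the same p-values, then combines the pair
#' \eqn{\{p_{CCT}, p_{MinP}\}} with an equal-weight second CCT stage. Like
#' MCM it blends the strengths of the two first-stage tests while keeping
#' type-I error control at small significance levels under arbitrary
#' dependence; its power tends to track CCT more closely than MCM does.
#'
#' A first-stage MinP p-value of exactly 1 is handled by the CCT clipping
#' convention (clip to `1 - 1e-15` before the second-stage transform).
#'
#' @inheritParams mcm_pvalue
#' @return an object of class `"combined_pvalue"`; the `statistic` is the
#'   second-stage CCT statistic.
#' @examples
#' cmc_pvalue(c(0.99, 0.001, 0.6))
#' @export
cmc_pvalue <- function(p, minp_mode = c("bonferroni", "sidak"),
                       weights = NULL) {
  minp_mode <- match.arg(minp_mode)
  p_cct <- cct_pvalue(p, weights)$pvalue
  p_minp <- minp_pvalue(p, mode = minp_mode)$pvalue
  second <- cct_pvalue(c(p_cct, p_minp))
  .combined_result("CMC", second$statistic, second$pvalue, length(p),
                   minp_mode = minp_mode)
}

#' Fisher's chi-square combination of independent p-values
#'
#' Combines independent p-values with the statistic
#' \eqn{X^2 = -2 \sum_i \ln P_i}, referred to a chi-square distribution with
#' `2k` degrees of freedom. Unlike the CCT-family tests it can produce a
#' combined p-value far below the smallest input, which makes it the better
#' choice when independence holds.
#'
#' @param p numeric vector of p-values in (0, 1]; zeros are rejected since
#'   they make the statistic infinite.
#' @return an object of class `"combined_pvalue"`.
#' @examples
#' fisher_pvalue(c(0.1, 0.05, 0.3))
#' @export
fisher_pvalue <- function(p) {
  v <- validate_pvalues(p)
  stat <- -2 * sum(log(v$p))
  pval <- stats::pchisq(stat, df = 2 * length(v$p), lower.tail = FALSE)
  .combined_result("Fisher", stat, pval, length(v$p))
}

#' Stouffer's z combination of independent p-values
#'
#' Combines independent p-values with
#' \eqn{Z = \sum_i \Phi^{-1}(1 - P_i) / \sqrt{k}}, referred to the standard
#' normal upper tail. Combining a set of p-values and their complements
#' yields combined p-values that sum to one.
#'
#' @param p numeric vector of p-values strictly inside (0, 1); values of 0
#'   or 1 are rejected since the normal quantile is infinite there.
#' @return an object of class `"combined_pvalue"`.
#' @examples
#' stouffer_pvalue(c(0.1, 0.05, 0.3))
#' @export
stouffer_pvalue <- function(p) {
  v <- validate_pvalues(p)
  if (any(v$p >= 1)) {
    stop("Stouffer's z requires p-values strictly inside (0,1)",
         call. = FALSE)
  }
  stat <- sum(stats::qnorm(v$p, lower.tail = FALSE)) / sqrt(length(v$p))
  pval <- stats::pnorm(stat, lower.tail = FALSE)
  .combined_result("StoufferZ", stat, pval, length(v$p))
}

#' Apply several combination tests to one p-value vector
#'
#' Convenience wrapper running any subset of the implemented combiners on
#' the same input and collecting the results in a data frame.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param methods character vector among `"cct"`, `"minp"`, `"mcm"`,
#'   `"cmc"`, `"fisher"`, `"stouffer"`, or `"all"`.
#' @param weights optional weights for the CCT-based tests.
#' @param minp_mode MinP calibration, `"sidak"` or `"bonferroni"`. When
#'   `NULL` (default) each test keeps its own convention: Sidak for the
#'   plain MinP test (exact under independence), Bonferroni inside the
#'   two-stage MCM/CMC tests (robust under dependence). Supplying a mode
#'   applies it everywhere.
#' @return a data frame with columns `method`, `statistic`, `pvalue`, `k`,
#'   `minp_mode`.
#' @examples
#' combine_pvalues(c(0.01, 0.2, 0.9))
#' @export
combine_pvalues <- function(p, methods = "all", weights = NULL,
                            minp_mode = NULL) {
  if (!is.null(minp_mode)) {
    minp_mode <- match.arg(minp_mode, c("sidak", "bonferroni"))
  }
  mode_for <- function(default) if (is.null(minp_mode)) default else minp_mode
  all_methods <- c("cct", "minp", "mcm", "cmc", "fisher", "stouffer")
  methods <- tolower(methods)
  if ("all" %in% methods) methods <- all_methods
  unknown <- setdiff(methods, all_methods)
  if (length(unknown) > 0) {
    stop("unknown method(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  res <- lapply(methods, function(m) {
    switch(m,
      cct = cct_pvalue(p, weights),
      minp = minp_pvalue(p, mode = mode_for("sidak")),
      mcm = mcm_pvalue(p, minp_mode = mode_for("bonferroni"),
                       weights = weights),
      cmc = cmc_pvalue(p, minp_mode = mode_for("bonferroni"),
                       weights = weights),
      fisher = fisher_pvalue(p),
      stouffer = stouffer_pvalue(p)
    )
  })
  data.frame(
    method = vapply(res, `[[`, character(1), "method"),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    pvalue = vapply(res, `[[`, numeric(1), "pvalue"),
    k = vapply(res, `[[`, integer(1), "k"),
    minp_mode = vapply(res, `[[`, character(1), "minp_mode"),
    stringsAsFactors = FALSE
  )
}
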