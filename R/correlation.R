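# Structured correlation models for the simulation study and their
# eigendecomposition-based factorization for multivariate normal sampling.

#' Specify a structured correlation model
#'
#' Bundles and validates the parameters of one of the three correlation
#' models used in the simulation machinery:
#' \describe{
#'   \item{`expo`}{AR(1) exponential decay, \eqn{\sigma_{ij} = \rho^{|i-j|}}
#'     with \eqn{\rho \in [0, 1)}.}
#'   \item{`poly`}{polynomial decay, \eqn{\sigma_{ij} = 1/(0.7 + |i-j|^r)}
#'     off the diagonal, with \eqn{r > 0}.}
#'   \item{`sig`}{a singular (rank k/5) correlation matrix built by
#'     normalizing \eqn{A^T A} for a short wide matrix
#'     \eqn{A_{(k/5) \times k}} with entries \eqn{d^{|i-j|}},
#'     \eqn{d \in (0, 1)}; requires `k` divisible by 5.}
#' }
#'
#' @param model one of `"expo"`, `"poly"`, `"sig"`.
#' @param k number of variables (p-values per replicate).
#' @param parameter the model parameter: rho, r, or d respectively.
#' @return an object of class `"correlation_spec"`.
#' @examples
#' correlation_spec("expo", k = 5, parameter = 0.5)
#' @export
correlation_spec <- function(model = c("expo", "poly", "sig"), k, parameter) {
  model <- match.arg(model)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  if (!is.numeric(parameter) || length(parameter) != 1L ||
      !is.finite(parameter)) {
    stop("parameter must be a single finite number", call. = FALSE)
  }
  switch(model,
    expo = if (parameter < 0 || parameter >= 1) {
      stop("expo model requires rho in [0, 1)", call. = FALSE)
    },
    poly = if (parameter <= 0) {
      stop("poly model requires r > 0", call. = FALSE)
    },
    sig = {
      if (k %% 5L != 0L) {
        stop("sig model builds A as a (k/5) x k matrix; ",
             "k must be divisible by 5 (got k = ", k, ")", call. = FALSE)
      }
      if (parameter <= 0 || parameter >= 1) {
        stop("sig model requires d in (0, 1)", call. = FALSE)
      }
    }
  )
  structure(list(model = model, k = k, parameter = parameter),
            class = "correlation_spec")
}

#' @export
print.correlation_spec <- function(x, ...) {
  pname <- switch(x$model, expo = "rho", poly = "r", sig = "d")
  cat(sprintf("correlation_spec: model = %s, k = %d, %s = %g\n",
              x$model, x$k, pname, x$parameter))
  invisible(x)
}

#' AR(1) exponential-decay correlation matrix
#'
#' @param k matrix dimension.
#' @param rho correlation decay parameter, in \[0, 1).
#' @return a `k x k` correlation matrix with entries `rho^|i-j|`; positive
#'   definite for `rho < 1`.
#' @examples
#' expo_sigma(3, 0.5)
#' @export
expo_sigma <- function(k, rho) {
  spec <- correlation_spec("expo", k, rho)
  d <- abs(outer(seq_len(spec$k), seq_len(spec$k), "-"))
  rho^d
}

#' Polynomial-decay correlation matrix
#'
#' Unit diagonal with off-diagonal entries `1 / (0.7 + |i-j|^r)`, strictly
#' decreasing in the index distance. Positive definiteness is not
#' guaranteed by the formula for all `(k, r)`; [validate_sigma()] (called
#' by the sampling path) fails loudly if the spectrum is negative.
#'
#' @param k matrix dimension.
#' @param r decay exponent, > 0.
#' @return a `k x k` correlation matrix.
#' @examples
#' poly_sigma(4, 1.5)
#' @export
poly_sigma <- function(k, r) {
  spec <- correlation_spec("poly", k, r)
  d <- abs(outer(seq_len(spec$k), seq_len(spec$k), "-"))
  s <- 1 / (0.7 + d^r)
  diag(s) <- 1
  s
}

#' Singular rank-deficient correlation matrix
#'
#' Builds the rank `k/5` correlation matrix \eqn{\Sigma = D^T A^T A D},
#' where `A` is the `(k/5) x k` matrix with entries `d^|i-j|` and `D` the
#' diagonal normalizer \eqn{d_{ii} = (\tilde a_{ii})^{-1/2}} from the
#' diagonal of \eqn{A^T A}, so the result has unit diagonal. The induced
#' z-scores are perfectly linearly dependent in groups. For `k = 5` the
#' construction collapses to the all-ones matrix (A has a single row).
#'
#' @param k matrix dimension, divisible by 5.
#' @param d decay parameter of A, in (0, 1).
#' @return a `k x k` positive semidefinite correlation matrix of rank `k/5`.
#' @examples
#' sig_sigma(10, 0.5)
#' @export
sig_sigma <- function(k, d) {
  spec <- correlation_spec("sig", k, d)
  k <- spec$k
  m <- k %/% 5L
  a <- d^abs(outer(seq_len(m), seq_len(k), "-"))
  ata <- crossprod(a)
  dn <- 1 / sqrt(diag(ata))
  s <- ata * tcrossprod(dn)
  # exact symmetry and unit diagonal despite rounding in the products
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

#' Build the correlation matrix for a spec
#'
#' @param spec a [correlation_spec()].
#' @return the corresponding correlation matrix.
#' @export
build_sigma <- function(spec) {
  stopifnot(inherits(spec, "correlation_spec"))
  switch(spec$model,
    expo = expo_sigma(spec$k, spec$parameter),
    poly = poly_sigma(spec$k, spec$parameter),
    sig = sig_sigma(spec$k, spec$parameter)
  )
}

#' Validate a correlation matrix
#'
#' Checks symmetry and unit diagonal to 1e-12 and that the smallest
#' eigenvalue is no smaller than `-1e-8` times the largest (so only
#' numerically positive semidefinite matrices pass).
#'
#' @param sigma a square numeric matrix.
#' @return invisibly, the eigenvalues of `sigma` (decreasing).
#' @export
validate_sigma <- function(sigma) {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma) ||
      !is.numeric(sigma)) {
    stop("sigma must be a square numeric matrix", call. = FALSE)
  }
  if (max(abs(sigma - t(sigma))) > 1e-12) {
    stop("sigma is not symmetric (tolerance 1e-12)", call. = FALSE)
  }
  if (max(abs(diag(sigma) - 1)) > 1e-12) {
    stop("sigma does not have a unit diagonal (tolerance 1e-12)",
         call. = FALSE)
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) {
    stop(sprintf(
      "sigma is not positive semidefinite (min eigenvalue %.3g)", min(ev)),
      call. = FALSE)
  }
  invisible(ev)
}

#' Factorize a correlation matrix for multivariate normal sampling
#'
#' Returns a factor `B` (rank x k) with `t(B) %*% B == sigma` up to 1e-8,
#' computed from the symmetric eigendecomposition. Eigenvalues within
#' `1e-8 * lambda_max` of zero (of either sign) are treated as zero and
#' dropped, so singular models such as `sig` yield a factor with exactly
#' `rank(sigma)` rows; an eigenvalue below `-1e-8 * lambda_max` is an
#' error. A single eigendecomposition path handles both the full-rank and
#' the singular models (Cholesky would fail on the latter).
#'
#' @param sigma a correlation matrix passing [validate_sigma()].
#' @return a numeric matrix `B` with `ncol(sigma)` columns and `rank(sigma)`
#'   rows; `crossprod(B)` reconstructs `sigma`.
#' @examples
#' B <- factorize_for_sampling(expo_sigma(3, 0.5))
#' max(abs(crossprod(B) - expo_sigma(3, 0.5)))
#' @export
factorize_for_sampling <- function(sigma) {
  validate_sigma(sigma)
  es <- eigen(sigma, symmetric = TRUE)
  lam <- es$values
  tol <- 1e-8 * max(lam)
  if (min(lam) < -tol) {
    stop("sigma is not positive semidefinite", call. = FALSE)
  }
  keep <- lam > tol
  b <- sqrt(lam[keep]) * t(es$vectors[, keep, drop = FALSE])
  err <- max(abs(crossprod(b) - sigma))
  if (err >= 1e-8) {
    stop(sprintf("factorization failed to reconstruct sigma (error %.3g)",
                 err), call. = FALSE)
  }
  b
}

#' Numerical rank of a correlation matrix
#'
#' Counts eigenvalues above `1e-8` times the largest, matching the
#' factorization's notion of rank.
#'
#' @param sigma a square symmetric matrix.
#' @return integer rank.
#' @export
sigma_rank <- function(sigma) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  sum(ev > 1e-8 * max(ev))
}
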