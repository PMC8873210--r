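# Meta-analysis workflow: per-study odds ratios with 95% CIs are converted
# to z-scores and directional p-values; independent studies are combined
# per direction (MinP / Fisher / Stouffer), and the dependent (left, right)
# pair is combined with the robust tests (CCT / MinP / MCM / CMC).

#' Convert an odds ratio with 95% CI to a z-score
#'
#' The 95% CI of a log odds ratio has half-width `1.96 * SE(log OR)`, so
#' `SE = ln(U/L) / 3.92` and the default conversion is
#' `z = ln(OR) / (ln(U/L) / 3.92)`, asymptotically standard normal under
#' the per-study null OR = 1. The `midpoint` variant replaces `ln(OR)` by
#' the CI midpoint on the log scale, `ln(U * L) / 2`; the two agree when
#' the reported CI is symmetric around the reported OR on the log scale,
#' and differ only through rounding of the published numbers.
#'
#' @param odds_ratio,ci_lower,ci_upper positive reals with
#'   `ci_lower < ci_upper`.
#' @param formula `"log_or"` (default) or `"midpoint"`.
#' @return the z-score (vectorized over the inputs).
#' @examples
#' or_ci_to_z(2.95, 1.54, 5.63)
#' @export
or_ci_to_z <- function(odds_ratio, ci_lower, ci_upper,
                       formula = c("log_or", "midpoint")) {
  formula <- match.arg(formula)
  if (any(odds_ratio <= 0 | ci_lower <= 0 | ci_upper <= 0)) {
    stop("odds ratio and CI bounds must be positive", call. = FALSE)
  }
  if (any(ci_lower >= ci_upper)) {
    stop("ci_lower must be below ci_upper", call. = FALSE)
  }
  se <- log(ci_upper / ci_lower) / 3.92
  num <- switch(formula,
    log_or = log(odds_ratio),
    midpoint = log(ci_upper * ci_lower) / 2
  )
  num / se
}

#' Derive per-study z-scores and directional p-values
#'
#' Fills in, for each study row, the z-score from [or_ci_to_z()] and the
#' three p-values `p_left = pnorm(z)`, `p_right = 1 - pnorm(z)` and
#' `p_two = 2 * pnorm(-|z|)`, matching the three per-study alternatives
#' OR < 1, OR > 1 and OR != 1. Rows where the reported OR falls outside
#' its own CI (possible through rounding of published values) trigger a
#' warning, not an error.
#'
#' @param studies a data frame with columns `study`, `or`, `ci_lower`,
#'   `ci_upper`.
#' @param formula passed to [or_ci_to_z()].
#' @return `studies` with columns `z`, `p_left`, `p_right`, `p_two` added.
#' @examples
#' study_pvalues(data.frame(study = 1, or = 2.95,
#'                          ci_lower = 1.54, ci_upper = 5.63))
#' @export
study_pvalues <- function(studies, formula = c("log_or", "midpoint")) {
  formula <- match.arg(formula)
  req <- c("study", "or", "ci_lower", "ci_upper")
  missing_cols <- setdiff(req, names(studies))
  if (length(missing_cols) > 0) {
    stop("study table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(studies$or < studies$ci_lower | studies$or > studies$ci_upper)
  if (length(bad) > 0) {
    warning("reported OR outside its own CI in row(s) ",
            paste(bad, collapse = ", "),
            " (often a rounding artifact of published tables)",
            call. = FALSE)
  }
  z <- or_ci_to_z(studies$or, studies$ci_lower, studies$ci_upper, formula)
  left <- stats::pnorm(z)
  studies$z <- z
  studies$p_left <- left
  studies$p_right <- 1 - left
  studies$p_two <- 2 * pmin(left, 1 - left)
  studies
}

#' Read a study table from CSV
#'
#' Expects a header with columns `study`, `or`, `ci_lower`, `ci_upper`;
#' rows with non-positive OR or CI bounds are rejected with their row
#' numbers.
#'
#' @param path CSV file path.
#' @return a data frame of study records.
#' @export
read_study_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("study", "or", "ci_lower", "ci_upper")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    stop("study table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(tab$or <= 0 | tab$ci_lower <= 0 | tab$ci_upper <= 0 |
                 !is.finite(tab$or) | !is.finite(tab$ci_lower) |
                 !is.finite(tab$ci_upper))
  if (length(bad) > 0) {
    stop("non-positive or missing OR/CI values in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tab
}

#' The packaged 12-study geriatric rehabilitation table
#'
#' Odds ratios and 95% confidence intervals from 12 independent trials of
#' inpatient rehabilitation programs for geriatric patients (functional
#' outcome improvement versus usual care), as published in meta-analyses
#' of those trials. An OR above 1 favors the rehabilitation program.
#'
#' @return a data frame with columns `study`, `or`, `ci_lower`, `ci_upper`
#'   (12 rows).
#' @examples
#' geriatric_rehab()
#' @export
geriatric_rehab <- function() {
  read_study_table(system.file("extdata", "geriatric_rehab_12.csv",
                               package = "robcomb", mustWork = TRUE))
}

#' Two-stage combination of directional meta-analysis p-values
#'
#' Stage 1 combines the independent per-study p-values separately for each
#' direction (all left-sided, all right-sided, all two-sided) with the
#' MinP (Sidak), Fisher and Stouffer-z methods. Stage 2 takes, for each
#' stage-1 method, the dependent pair of combined left- and right-sided
#' p-values and combines it with the robust tests: CCT, MinP (Bonferroni),
#' MCM and CMC. Stage 2 always consumes the full-precision stage-1
#' numbers; rounding happens only in printing.
#'
#' The left and right p-values of each study sum to one, so a Stouffer
#' stage-1 pair also sums to one and its stage-2 CCT is exactly 0.5 — the
#' configuration in which CCT is powerless and the MinP-based stage-2
#' tests are not.
#'
#' @param studies a study data frame (see [read_study_table()]), or one
#'   already processed by [study_pvalues()].
#' @param formula z-score conversion, see [or_ci_to_z()].
#' @param stage1_minp_mode MinP calibration for the independent stage
#'   (Sidak default, exact under independence).
#' @param stage2_minp_mode MinP calibration for the dependent pair
#'   (Bonferroni default, valid under dependence).
#' @return an object of class `"meta_combination"`: a list with
#'   `studies` (the per-study table with z and p-values), `stage1` (rows
#'   MinP/Fisher/StoufferZ, columns left/right/two), and `stage2` (same
#'   rows, columns CCT/MinP/MCM/CMC).
#' @examples
#' run_meta_pipeline(geriatric_rehab())
#' @export
run_meta_pipeline <- function(studies,
                              formula = c("log_or", "midpoint"),
                              stage1_minp_mode = "sidak",
                              stage2_minp_mode = "bonferroni") {
  formula <- match.arg(formula)
  if (nrow(studies) < 1) stop("need at least one study", call. = FALSE)
  if (!all(c("p_left", "p_right", "p_two") %in% names(studies))) {
    studies <- study_pvalues(studies, formula)
  }
  stage1_combiners <- list(
    MinP = function(p) minp_pvalue(p, mode = stage1_minp_mode)$pvalue,
    Fisher = function(p) fisher_pvalue(p)$pvalue,
    StoufferZ = function(p) stouffer_pvalue(p)$pvalue
  )
  stage1 <- do.call(rbind, lapply(names(stage1_combiners), function(m) {
    f <- stage1_combiners[[m]]
    data.frame(method = m,
               left = f(studies$p_left),
               right = f(studies$p_right),
               two = f(studies$p_two),
               stringsAsFactors = FALSE)
  }))
  stage2 <- do.call(rbind, lapply(seq_len(nrow(stage1)), function(i) {
    pair <- c(stage1$left[i], stage1$right[i])
    data.frame(method = stage1$method[i],
               CCT = cct_pvalue(pair)$pvalue,
               MinP = minp_pvalue(pair, mode = stage2_minp_mode)$pvalue,
               MCM = mcm_pvalue(pair, minp_mode = stage2_minp_mode)$pvalue,
               CMC = cmc_pvalue(pair, minp_mode = stage2_minp_mode)$pvalue,
               stringsAsFactors = FALSE)
  }))
  structure(list(studies = studies, stage1 = stage1, stage2 = stage2,
                 formula = formula,
                 stage1_minp_mode = stage1_minp_mode,
                 stage2_minp_mode = stage2_minp_mode),
            class = "meta_combination")
}

#' @export
print.meta_combination <- function(x, digits = 4L, ...) {
  cat(sprintf(
    "Two-stage combination of %d studies (z from %s; MinP %s/%s)\n\n",
    nrow(x$studies), x$formula, x$stage1_minp_mode, x$stage2_minp_mode))
  cat("Per-study p-values:\n")
  show <- x$studies
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], signif, digits)
  print(show, row.names = FALSE)
  cat("\nStage 1 (independent p-values, per direction):\n")
  s1 <- x$stage1
  s1[-1] <- lapply(s1[-1], signif, digits)
  print(s1, row.names = FALSE)
  cat("\nStage 2 (dependent left/right pair):\n")
  s2 <- x$stage2
  s2[-1] <- lapply(s2[-1], signif, digits)
  print(s2, row.names = FALSE)
  invisible(x)
}

#' Write the meta-analysis results as CSV files
#'
#' Emits two CSVs: the per-study table (`<prefix>_studies.csv`) and the
#' combined stage-1/stage-2 table (`<prefix>_combined.csv`), at full
#' precision.
#'
#' @param result a `"meta_combination"` object.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_meta_tables <- function(result, prefix) {
  stopifnot(inherits(result, "meta_combination"))
  f1 <- paste0(prefix, "_studies.csv")
  f2 <- paste0(prefix, "_combined.csv")
  utils::write.csv(result$studies, f1, row.names = FALSE)
  utils::write.csv(merge(result$stage1, result$stage2, by = "method",
                         sort = FALSE),
                   f2, row.names = FALSE)
  invisible(c(f1, f2))
}
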