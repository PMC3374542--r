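#' Pearson chi-square test of homogeneity across conditions
#'
#' Tests whether a binary characteristic is distributed homogeneously
#' across trial arms (the randomization-check applied to baseline
#' characteristics). No continuity correction, matching the large-sample
#' setting.
#'
#' @param counts a 2 x k matrix of counts (rows: characteristic
#'   present/absent; columns: conditions), k >= 2.
#' @param alpha significance threshold (default 0.01; a stricter threshold
#'   than .05 is used to limit type I error in very large samples).
#' @return a list of class `"association_result"`: `statistic`, `df`,
#'   `p_value`, `significant`.
#' @export
#' @examples
#' males <- rbind(c(2168, 2150, 2165, 2155),
#'                c(4102, 4080, 4088, 4079) - c(2168, 2150, 2165, 2155))
#' chi_square_homogeneity(males)$p_value # ~1
chi_square_homogeneity <- function(counts, alpha = 0.01) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    cb_abort("counts must be at least a 2 x 2 table.", "input_error")
  }
  check_count(c(counts), "counts")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    cb_abort("degenerate table: a row or column marginal is zero.",
             "degenerate_table")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  res <- list(statistic = unname(ht$statistic), df = unname(ht$parameter),
              p_value = unname(ht$p.value),
              effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              significant = unname(ht$p.value) < alpha)
  structure(res, class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("chi-square = %.3f, df = %d, p = %.4g%s\n", x$statistic, x$df,
              x$p_value, if (x$significant) " *" else ""))
  if (!is.na(x$effect)) {
    cat(sprintf("  OR = %.3f, 95%% CI %.3f-%.3f\n", x$effect, x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Crude odds ratio for a 2 x 2 table
#'
#' Cross-product odds ratio `(a d)/(b c)` with a Wald 95% confidence
#' interval on the log scale. Any zero cell triggers the Haldane-Anscombe
#' continuity correction (0.5 added to every cell), flagged in the result —
#' never applied silently.
#'
#' @param a,b exposed quit / exposed not-quit counts.
#' @param c,d unexposed quit / unexposed not-quit counts.
#' @param conf_level confidence level for the Wald interval.
#' @param alpha significance threshold for the Wald test (default 0.01).
#' @return a list of class `"association_result"` with `effect` (the OR),
#'   `ci_low`, `ci_high`, `statistic` (Wald chi-square, 1 df), `p_value`,
#'   and `continuity_corrected`.
#' @export
#' @examples
#' crude_odds_ratio(46, 50, 714, 612)$effect # 0.789
crude_odds_ratio <- function(a, b, c, d, conf_level = 0.95, alpha = 0.01) {
  check_count(c(a, b, c, d), "cell counts")
  cells <- c(a, b, c, d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  log_or <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  wald <- (log_or / se)^2
  res <- list(statistic = wald, df = 1L,
              p_value = stats::pchisq(wald, df = 1, lower.tail = FALSE),
              effect = exp(log_or),
              ci_low = exp(log_or - z * se), ci_high = exp(log_or + z * se),
              significant = stats::pchisq(wald, df = 1, lower.tail = FALSE) < alpha,
              continuity_corrected = corrected)
  structure(res, class = "association_result")
}

#' Binomial logistic regression with Wald inference
#'
#' Maximum-likelihood logit fit (iteratively reweighted least squares via
#' `stats::glm`, convergence when successive deviances change by less than
#' 1e-8, at most 100 iterations) with per-coefficient Wald chi-square
#' statistics, p values and confidence intervals. Used for condition
#' contrasts and cohort-comparability checks; with a single binary
#' covariate the exponentiated slope equals the crude odds ratio.
#'
#' @param outcome 0/1 (or logical) response vector.
#' @param design numeric covariate matrix (no intercept column; one is
#'   added). Column names become coefficient labels.
#' @param alpha significance threshold (default 0.01).
#' @param conf_level confidence level for Wald intervals.
#' @return a tibble with one row per coefficient: `term`, `estimate`,
#'   `se`, `or`, `ci_low`, `ci_high`, `wald_chisq`, `df`, `p_value`,
#'   `significant`.
#' @export
fit_binomial_logit <- function(outcome, design = NULL, alpha = 0.01,
                               conf_level = 0.95) {
  outcome <- as.numeric(outcome)
  if (any(is.na(outcome)) || any(!outcome %in% c(0, 1))) {
    cb_abort("outcome must be binary 0/1 with no missing values.", "input_error")
  }
  if (is.null(design)) {
    X <- matrix(numeric(0), nrow = length(outcome), ncol = 0)
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (nrow(X) != length(outcome)) {
      cb_abort("design and outcome have different lengths.", "input_error")
    }
    if (qr(cbind(1, X))$rank < ncol(X) + 1) {
      cb_abort("design matrix is rank deficient (collinear covariates).",
               "design_error")
    }
  }
  dat <- data.frame(.y = outcome, X, check.names = FALSE)
  form <- if (ncol(X) == 0) .y ~ 1 else
    stats::reformulate(sprintf("`%s`", colnames(X)), response = ".y")
  fit <- suppressWarnings(stats::glm(
    form, family = stats::binomial(), data = dat,
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  est <- stats::coef(fit)
  diverged <- names(est)[abs(est) > 15]
  if (length(diverged)) {
    cb_abort(sprintf("complete or quasi-complete separation: coefficient '%s' diverged (|estimate| > 15 on the logit scale).",
                     diverged[1]), "separation_error")
  }
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  wald <- (est / se)^2
  p <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  tibble::tibble(
    term = names(est), estimate = unname(est), se = unname(se),
    or = exp(unname(est)),
    ci_low = exp(unname(est) - z * unname(se)),
    ci_high = exp(unname(est) + z * unname(se)),
    wald_chisq = unname(wald), df = 1L, p_value = unname(p),
    significant = unname(p) < alpha)
}
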