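#' Two-sided Mann-Whitney U test
#'
#' The workhorse comparison for numeric covariates and label distributions
#' between the SL and NSL classes. The exact null distribution is used when
#' `n1 * n2 <= 400` and the pooled data have no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used. The
#' reported `U` statistic counts pairs won by `x`.
#'
#' The branch that ran is recorded in the `method` tag (`"mw_exact"`,
#' `"mw_normal"` or `"mw_normal_ties"`), so results can be compared against
#' either convention. When every pooled value is identical the test is
#' degenerate and `p = 1` is returned with a warning tag.
#'
#' @param x,y numeric vectors, both nonempty; `NA`s are dropped.
#' @return A list of class `test_result`: `statistic` (U for `x`), `p_value`,
#'   `method`, `n` (per-group counts), `warnings`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be nonempty", class = "somnaudit_argument_error")
  }
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  has_ties <- anyDuplicated(pooled) > 0
  warnings <- character()
  if (length(unique(pooled)) == 1L) {
    # all observations identical: U is exactly its null mean, no evidence
    return(.test_result(n1 * n2 / 2, 1, "mw_degenerate", c(n1 = n1, n2 = n2),
                        "all pooled values identical"))
  }
  exact <- (n1 * n2 <= 400) && !has_ties
  if (exact) {
    res <- suppressWarnings(wilcox.test(x, y, exact = TRUE, correct = FALSE))
    method <- "mw_exact"
  } else {
    res <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    method <- if (has_ties) "mw_normal_ties" else "mw_normal"
  }
  .test_result(unname(res$statistic), min(1, res$p.value), method,
               c(n1 = n1, n2 = n2), warnings)
}

#' Chi-squared test of independence on a 2x2 table
#'
#' Yates' continuity correction is applied by default: the statistic is
#' `sum(max(|O - E| - 0.5, 0)^2 / E)` referred to a chi-squared distribution
#' with one degree of freedom. The correction term is floored at zero, so a
#' table in exact independence yields statistic 0 and `p = 1`. A warning is
#' attached when any expected count falls below 5.
#'
#' @param table 2x2 matrix (or coercible) of nonnegative integer counts.
#' @param yates apply the continuity correction (default `TRUE`).
#' @return A `test_result` list; `method` is `"chi2_yates"` or `"chi2"`.
#' @export
#' @examples
#' # sex-by-class sample counts of a clinical latency-test corpus
#' chi_squared_2x2(matrix(c(100, 110, 115, 205), 2))
chi_squared_2x2 <- function(table, yates = TRUE) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) {
    abort("table must be 2x2", class = "somnaudit_argument_error")
  }
  if (any(m < 0) || sum(m) <= 0) {
    abort("counts must be nonnegative with a positive total",
          class = "somnaudit_argument_error")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("degenerate table: a row or column margin is zero",
          class = "somnaudit_degenerate_error")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  warnings <- character()
  if (any(expected < 5)) {
    warnings <- c(warnings, "expected count below 5; approximation may be poor")
  }
  res <- suppressWarnings(chisq.test(m, correct = yates))
  .test_result(unname(res$statistic), unname(res$p.value),
               if (yates) "chi2_yates" else "chi2",
               c(n = sum(m)), warnings)
}

#' Spearman rank correlation
#'
#' Midranks are assigned to ties, `rho` is the Pearson correlation of the two
#' rank vectors, and the p-value comes from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Only complete pairs are used.
#'
#' @param x,y numeric vectors of equal length with at least 3 complete pairs.
#' @return A list of class `correlation_result`: `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "somnaudit_argument_error")
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    abort("need at least 3 complete pairs", class = "somnaudit_insufficient_data_error")
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    abort("correlation undefined for a constant vector",
          class = "somnaudit_degenerate_error")
  }
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n), class = "correlation_result")
}

.test_result <- function(statistic, p_value, method, n, warnings = character()) {
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         n = n, warnings = warnings),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4g, p = %.4g (n: %s)\n",
              x$method, x$statistic, x$p_value,
              paste(x$n, collapse = ", ")))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rho = %.4f, p = %.4g, n = %d\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}
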