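# Nonparametric and descriptive statistics used by the screening framework.
# All tests are two-sided; ties get mid-ranks with the standard corrections
# (the defaults of the field's usual statistical software).

#' @noRd
test_result <- function(statistic_name, statistic, p_value, n_total,
                        df = NA_real_, extra = list()) {
  structure(c(list(statistic_name = statistic_name,
                   statistic = unname(statistic),
                   df = unname(df), p_value = unname(p_value),
                   n_total = n_total), extra),
            class = "envelope_test")
}

#' @export
print.envelope_test <- function(x, ...) {
  cat(sprintf("%s = %.6g%s, p = %.4g (n = %d, two-sided)\n",
              x$statistic_name, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %g", x$df),
              x$p_value, x$n_total))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Valid for sample sizes 3 to 5000 (the range of the standard
#' approximation); constant samples are rejected as an error.
#'
#' @param values numeric sample.
#' @return an `envelope_test` with statistic `W`.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got n = ", n, call. = FALSE)
  }
  if (stats::sd(values) == 0) stop("zero variance: all values identical", call. = FALSE)
  ht <- stats::shapiro.test(values)
  test_result("W", ht$statistic, ht$p.value, n)
}

#' Kruskal-Wallis rank test
#'
#' `H = [12 / (N (N + 1)) * sum R_j^2 / n_j - 3 (N + 1)]` divided by the
#' tie-correction factor; `df = k - 1`; p-value from the chi-squared upper
#' tail.
#'
#' @param groups list of numeric samples (>= 2 non-empty groups).
#' @return an `envelope_test` with statistic `H`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) == 0L)) {
    stop("empty group", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  if (stats::sd(x) == 0) stop("all values identical across groups", call. = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ht <- stats::kruskal.test(x, g)
  test_result("H", ht$statistic, ht$p.value, length(x),
              df = ht$parameter)
}

#' Mann-Whitney U test
#'
#' Two-sided Wilcoxon rank-sum. The p-value is exact (by enumeration of the
#' rank-sum distribution) when both samples have at most 50 observations
#' and there are no ties; otherwise the normal approximation with
#' tie-corrected variance and continuity correction is used. The statistic
#' reported is `U` for the first sample, so `U_x + U_y = n_x * n_y`.
#'
#' A fully tied pooled sample (every value identical) is a perfectly
#' symmetric configuration: `U = n_x n_y / 2`, `p = 1`.
#'
#' @param x,y numeric samples (non-empty).
#' @return an `envelope_test` with statistic `U`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample", call. = FALSE)
  nx <- length(x)
  ny <- length(y)
  if (stats::sd(c(x, y)) == 0) {
    # tie-corrected normal sd is zero; by symmetry the test carries no
    # evidence either way
    return(test_result("U", nx * ny / 2, 1, nx + ny))
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  test_result("U", ht$statistic, ht$p.value, nx + ny,
              extra = list(exact = is.null(ht$parameter) &&
                             !grepl("continuity", ht$method)))
}

#' Linear-interpolation quantile
#'
#' The quantile at position `h = (n - 1) q` on the sorted sample
#' (`stats::quantile` type 7), the rule whose interpolation precision
#' matches sub-unit thresholds such as 0.925 degrees C. Alternative rules
#' can be selected for comparison.
#'
#' @param values non-empty numeric sample.
#' @param q probability in `[0, 1]` (vectorised).
#' @param type quantile rule passed to [stats::quantile] (default 7).
#' @return quantile value(s) in sample units.
#' @export
climate_quantile <- function(values, q, type = 7) {
  if (length(values) == 0L) stop("empty sample", call. = FALSE)
  if (any(!is.finite(q)) || any(q < 0 | q > 1)) {
    stop("q must lie in [0, 1]", call. = FALSE)
  }
  stats::quantile(values, probs = q, names = FALSE, type = type)
}

#' Ordinary least-squares fit and coefficient of determination
#'
#' @param x,y matching numeric samples, `n >= 3`, `x` non-constant.
#' @return an `envelope_test` with statistic `R2` and extra fields
#'   `slope` and `intercept`; the p-value is the F-test p of the slope.
#' @export
linear_fit_r2 <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) {
    stop("need matching samples with n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("constant x: fit undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # an exact linear relation (R^2 = 1) is a legitimate input here
  sm <- suppressWarnings(summary(fit))
  p <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                 lower.tail = FALSE)
  test_result("R2", sm$r.squared, unname(p), n,
              extra = list(slope = unname(stats::coef(fit)[2]),
                           intercept = unname(stats::coef(fit)[1])))
}
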