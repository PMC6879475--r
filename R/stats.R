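check_paired <- function(x, y, min_n = 3L) {
  if (length(x) != length(y))
    stop_validation("x and y must be paired (equal length)",
                    "vasctrack_validation_error")
  if (length(x) < min_n)
    stop_validation(sprintf("need at least %d pairs, got %d", min_n, length(x)),
                    "vasctrack_sample_size_error")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_validation("non-finite values in input", "vasctrack_validation_error")
  invisible(TRUE)
}

#' Bland-Altman agreement analysis
#'
#' Method-agreement analysis of paired measurements: differences
#' `d = x - y` are summarized by their mean (the bias), sample SD
#' (`n - 1`), and 95% limits of agreement `mean +/- 1.96 * SD`. The
#' conventional 1.96 multiplier is used (not a t quantile), matching
#' standard limits-of-agreement practice; the 95% CI of the bias does use
#' the t distribution with `n - 1` df. Per-pair `(average, difference)`
#' values are kept for plotting.
#'
#' @param x,y Paired numeric vectors (length >= 3), e.g. the same growth
#'   densities measured by two imaging modalities.
#' @return A `bland_altman` object; see [tidy.bland_altman()] and
#'   [autoplot.bland_altman()].
#' @export
bland_altman <- function(x, y) {
  check_paired(x, y, 3L)
  d <- x - y
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(0.975, n - 1)
  structure(list(
    n = n, mean_diff = m, sd_diff = s,
    loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
    ci_mean = c(m - tq * s / sqrt(n), m + tq * s / sqrt(n)),
    pairs = tibble::tibble(average = (x + y) / 2, difference = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: n=%d, mean diff=%.3f (95%% CI %.3f to %.3f), LOA [%.3f, %.3f]\n",
    x$n, x$mean_diff, x$ci_mean[1], x$ci_mean[2], x$loa_low, x$loa_high))
  invisible(x)
}

#' Tidy a Bland-Altman result
#'
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return The per-pair `(average, difference)` tibble.
#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' One-row summary of a Bland-Altman result
#'
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `ci_mean_low`, `ci_mean_high`.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 ci_mean_low = x$ci_mean[1], ci_mean_high = x$ci_mean[2])
}

#' Bland-Altman plot
#'
#' Differences against pair averages, with the bias and the 95% limits of
#' agreement drawn as horizontal lines.
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$average, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff, color = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", color = "red") +
    ggplot2::labs(x = "Average of the two methods (%)",
                  y = "Difference between methods (%)") +
    ggplot2::theme_minimal()
}

test_tibble <- function(method, statistic, p, n) {
  tibble::tibble(method = method, statistic = unname(statistic),
                 p_value = unname(p), n = n)
}

#' Pearson correlation with t-transform p-value
#'
#' @param x,y Paired numeric vectors (length >= 3, both with nonzero
#'   variance).
#' @return One-row tibble: `method`, `statistic` (r), `p_value`
#'   (two-sided, t with `n - 2` df), `n`.
#' @export
pearson_correlation <- function(x, y) {
  check_paired(x, y, 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_validation("correlation undefined for zero-variance input",
                    "vasctrack_validation_error")
  ct <- stats::cor.test(x, y, method = "pearson")
  test_tibble("pearson", ct$estimate, ct$p.value, length(x))
}

#' Paired two-sample t-test
#'
#' @param x,y Paired numeric vectors.
#' @return One-row tibble with the t statistic and two-sided p-value
#'   (`n - 1` df). All-zero differences give `t = 0, p = 1`; zero-SD
#'   differences with nonzero mean are reported as `p = 0` (an infinite
#'   t), the documented edge convention.
#' @export
paired_t_test <- function(x, y) {
  check_paired(x, y, 2L)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(test_tibble("paired t", 0, 1, length(d)))
    return(test_tibble("paired t", sign(mean(d)) * Inf, 0, length(d)))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  test_tibble("paired t", tt$statistic, tt$p.value, length(d))
}

#' Welch unpaired t-test
#'
#' Welch's form (unequal variances) is the default: simulated and real
#' arms have small, unequal sizes and no variance-homogeneity claim is
#' made.
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @return One-row tibble with the Welch t statistic and two-sided
#'   p-value. Two zero-variance samples with equal means give
#'   `t = 0, p = 1`.
#' @export
unpaired_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop_validation("each group needs at least 2 values",
                    "vasctrack_sample_size_error")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(test_tibble("welch t", 0, 1, length(x) + length(y)))
    return(test_tibble("welch t", sign(mean(x) - mean(y)) * Inf, 0,
                       length(x) + length(y)))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  test_tibble("welch t", tt$statistic, tt$p.value, length(x) + length(y))
}

#' Wilcoxon signed-rank test (paired, two-sided)
#'
#' The standard paired nonparametric test: exact p-values from the full
#' signed-rank distribution for up to 25 nonzero differences without ties,
#' the normal approximation with tie correction otherwise. Zero
#' differences are dropped first.
#'
#' @param x,y Paired numeric vectors (>= 5 nonzero differences).
#' @return One-row tibble with the V statistic and two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  check_paired(x, y, 2L)
  d <- (x - y)[x != y]
  if (length(d) == 0)
    stop_validation("all paired differences are zero: no information",
                    "vasctrack_validation_error")
  if (length(d) < 5)
    stop_validation("need at least 5 nonzero differences",
                    "vasctrack_sample_size_error")
  has_ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= 25 && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = !exact))
  test_tibble("wilcoxon signed-rank", wt$statistic, wt$p.value, length(d))
}

#' Mann-Whitney U test (unpaired, two-sided)
#'
#' Provided alongside the signed-rank test because paired designs are
#' sometimes (incorrectly) analyzed with the unpaired form.
#'
#' @param x,y Numeric vectors.
#' @return One-row tibble with the W statistic and two-sided p-value.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop_validation("each group needs at least 2 values",
                    "vasctrack_sample_size_error")
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  test_tibble("mann-whitney u", wt$statistic, wt$p.value,
              length(x) + length(y))
}

#' Group summary: mean, SD, median, IQR
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), the convention pinned for IQR
#' reproducibility.
#'
#' @param values Numeric vector (length >= 1).
#' @return One-row tibble: `n`, `mean`, `sd` (0 when `n = 1`, with
#'   `single_value = TRUE`), `median`, `q1`, `q3`.
#' @export
group_summary <- function(values) {
  if (length(values) == 0)
    stop_validation("empty input", "vasctrack_validation_error")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(n = length(values), mean = mean(values),
                 sd = if (length(values) == 1) 0 else stats::sd(values),
                 single_value = length(values) == 1,
                 median = q[2], q1 = q[1], q3 = q[3])
}
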