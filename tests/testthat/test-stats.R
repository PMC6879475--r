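# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments (no ties assumed), following the convention
# p = min(1, 2 * min(P(V <= v), P(V >= v))).
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

test_that("bland_altman reproduces hand-computed summaries", {
  same <- bland_altman(c(3, 7, 2, 9), c(3, 7, 2, 9))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  ba <- bland_altman(c(1, 2, 3), c(2, 2, 4))
  expect_equal(ba$mean_diff, -2 / 3, tolerance = 1e-4)
  expect_equal(ba$sd_diff, stats::sd(c(-1, 0, -1)), tolerance = 1e-10)
  expect_equal(ba$loa_low, -2 / 3 - 1.96 * stats::sd(c(-1, 0, -1)), tolerance = 1e-10)
  expect_equal(ba$loa_high, -2 / 3 + 1.96 * stats::sd(c(-1, 0, -1)), tolerance = 1e-10)
  expect_equal(ba$loa_low, -1.798, tolerance = 1e-3)
  expect_equal(ba$loa_high, 0.465, tolerance = 1e-3)
  expect_true(ba$ci_mean[1] < ba$mean_diff && ba$mean_diff < ba$ci_mean[2])
  expect_equal(tidy(ba)$difference, c(-1, 0, -1))
  expect_equal(nrow(glance(ba)), 1)
})

test_that("bland_altman converges on simulated normal differences", {
  set.seed(101)
  n <- 20000
  y <- rnorm(n, 0, 1)
  x <- y + rnorm(n, 0.5, 1)
  ba <- bland_altman(x, y)
  expect_equal(ba$mean_diff, 0.5, tolerance = 0.03)
  expect_equal(ba$loa_high - ba$loa_low, 3.92, tolerance = 0.05)
  # LOA coverage approaches 95%
  d <- x - y
  cover <- mean(abs(d - ba$mean_diff) <= 1.96 * ba$sd_diff)
  expect_equal(cover, 0.95, tolerance = 0.02)
})

test_that("bland_altman rejects invalid input", {
  expect_error(bland_altman(1:2, 1:2), class = "vasctrack_sample_size_error")
  expect_error(bland_altman(c(1, 2, NA), c(1, 2, 3)),
               class = "vasctrack_validation_error")
})

test_that("pearson correlation matches the direct formula", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1)$statistic, 1)
  expect_equal(pearson_correlation(1:10, -(1:10))$statistic, -1)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pearson_correlation(x, y)
  expect_equal(got$statistic, r_direct, tolerance = 1e-12)
  tstat <- r_direct * sqrt(2 / (1 - r_direct^2))
  expect_equal(got$p_value, 2 * stats::pt(-abs(tstat), 2), tolerance = 1e-12)
  expect_error(pearson_correlation(c(1, 1, 1), 1:3),
               class = "vasctrack_validation_error")
})

test_that("paired t-test matches its closed form and edge conventions", {
  expect_equal(paired_t_test(1:5, 1:5)$p_value, 1)
  expect_equal(paired_t_test(1:5, 1:5)$statistic, 0)
  sym <- paired_t_test(c(1, -1, 1, -1), c(0, 0, 0, 0))
  expect_equal(sym$statistic, 0)
  d <- c(1, 2, 3)
  got <- paired_t_test(d + 5, rep(5, 3))
  t_direct <- mean(d) / (stats::sd(d) / sqrt(3))
  expect_equal(got$statistic, t_direct, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_direct), 2), tolerance = 1e-12)
  shifted <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(shifted$p_value, 0)
})

test_that("Welch test matches its closed form and is symmetric under swap", {
  same <- unpaired_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  got <- unpaired_t_test(x, y)
  se <- sqrt(stats::var(x) / 3 + stats::var(y) / 3)
  expect_equal(got$statistic, (mean(x) - mean(y)) / se, tolerance = 1e-12)
  swapped <- unpaired_t_test(y, x)
  expect_equal(swapped$statistic, -got$statistic, tolerance = 1e-12)
  expect_equal(swapped$p_value, got$p_value, tolerance = 1e-12)
})

test_that("wilcoxon signed-rank: exact small-n p-values match enumeration", {
  expect_error(wilcoxon_signed_rank(1:6, 1:6), class = "vasctrack_validation_error")
  all_pos <- wilcoxon_signed_rank(c(11, 12, 13, 14, 15, 16), c(10, 10, 10, 10, 10, 10))
  expect_equal(all_pos$p_value, 1 / 32, tolerance = 1e-12)

  set.seed(37)
  for (k in 1:6) {
    n <- sample(6:11, 1)
    d <- round(rnorm(n, 0.3, 1), 3)
    d <- d[d != 0]
    if (anyDuplicated(abs(d)) || length(d) < 5) next
    got <- wilcoxon_signed_rank(d, rep(0, length(d)))
    expect_equal(got$p_value, enum_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("symmetric paired differences are far from significance", {
  x <- c(1, -1, 2, -2, 3, -3) + 10
  y <- rep(10, 6)
  got <- wilcoxon_signed_rank(x, y)
  expect_gte(got$p_value, 0.9)
})

test_that("mann-whitney U agrees with the base implementation", {
  set.seed(41)
  x <- rnorm(8); y <- rnorm(9, 0.5)
  got <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
})

test_that("group summaries pin the interpolation quantile convention", {
  gs <- group_summary(c(1, 2, 3, 4))
  expect_equal(gs$median, 2.5)
  expect_equal(gs$q1, 1.75)
  expect_equal(gs$q3, 3.25)
  one <- group_summary(5)
  expect_equal(one$mean, 5)
  expect_equal(one$sd, 0)
  expect_true(one$single_value)
  const <- group_summary(rep(2, 7))
  expect_equal(const$sd, 0)
  expect_equal(c(const$q1, const$q3), c(2, 2))
  expect_error(group_summary(numeric(0)), class = "vasctrack_validation_error")
})

test_that("tests are invariant where mathematically expected", {
  set.seed(43)
  x <- rnorm(12); y <- rnorm(12, 0.3)
  # correlation invariant under positive affine maps of each variable
  r0 <- pearson_correlation(x, y)$statistic
  r1 <- pearson_correlation(2 * x + 3, 0.5 * y - 1)$statistic
  expect_equal(r0, r1, tolerance = 1e-12)
  # shifting both samples equally leaves the unpaired test unchanged
  t0 <- unpaired_t_test(x, y)
  t1 <- unpaired_t_test(x + 7, y + 7)
  expect_equal(t0$statistic, t1$statistic, tolerance = 1e-10)
  expect_equal(t0$p_value, t1$p_value, tolerance = 1e-10)
})
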