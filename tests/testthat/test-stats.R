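test_that("one-way ANOVA reproduces hand-computed decompositions", {
  a0 <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3),
                           g3 = c(1, 2, 3)))
  expect_equal(a0$statistic, 0)
  expect_equal(a0$p_value, 1)
  a <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(a$statistic, 3)
  expect_identical(unname(a$df), c(2L, 6L))
  expect_equal(a$p_value, stats::pf(3, 2, 6, lower.tail = FALSE))
  expect_error(one_way_anova(list(1:3)), ">= 2 groups")
  expect_error(one_way_anova(list(1:3, 5)), "n >= 2")
})

test_that("with two groups F equals the squared pooled t statistic", {
  set.seed(4)
  x <- rnorm(8); y <- rnorm(11, 0.5)
  a <- one_way_anova(list(x, y), tukey = FALSE)
  t2 <- two_sample_t(x, y)$statistic^2
  expect_equal(a$statistic, t2)
  expect_equal(a$p_value, two_sample_t(x, y)$p_value)
})

test_that("ANOVA F is invariant to adding a constant", {
  set.seed(9)
  gs <- list(rnorm(6), rnorm(7, 1), rnorm(5, 2))
  a1 <- one_way_anova(gs, tukey = FALSE)
  a2 <- one_way_anova(lapply(gs, `+`, 42), tukey = FALSE)
  expect_equal(a1$statistic, a2$statistic)
})

test_that("studentized-range CDF matches reference values", {
  # independent oracle: base R's ptukey
  for (k in c(2, 3, 5)) for (df in c(5, 10, 40)) for (q in c(1, 2.5, 4)) {
    expect_equal(ptukey_range(q, k, df), stats::ptukey(q, k, df),
                 tolerance = 1e-5)
  }
  # published q-table entry: q_{0.05}(k = 3, df = 10) = 3.88
  expect_equal(1 - ptukey_range(3.877, 3, 10), 0.05, tolerance = 2e-3)
  expect_equal(ptukey_range(0, 3, 10), 0)
  expect_equal(ptukey_range(Inf, 3, 10), 1)
})

test_that("Tukey HSD agrees with base R and dominates unadjusted p", {
  set.seed(15)
  vals <- c(rnorm(8), rnorm(9, 1), rnorm(7, 0.5))
  grp <- rep(c("a", "b", "c"), c(8, 9, 7))
  a <- one_way_anova(split(vals, grp))
  ref <- stats::TukeyHSD(stats::aov(vals ~ grp))$grp
  expect_equal(sort(a$tukey$p_adj), sort(unname(ref[, "p adj"])),
               tolerance = 1e-4)
  expect_equal(sort(abs(a$tukey$difference)),
               sort(abs(unname(ref[, "diff"]))), tolerance = 1e-10)
  expect_true(all(a$tukey$p_adj >= a$tukey$p_unadj - 1e-10))
  expect_identical(nrow(a$tukey), 3L)   # k (k - 1) / 2 pairs
})

test_that("variance-ratio test matches hand values and var.test", {
  av <- variance_ratio_test(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_equal(av$statistic, 4)           # variances 2.5 and 10
  expect_identical(unname(av$df), c(4L, 4L))
  expect_equal(av$p_value,
               stats::var.test(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))$p.value)
  same <- variance_ratio_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 1)
  expect_equal(same$p_value, 1)
  expect_error(variance_ratio_test(c(1, 1), c(2, 2)), "zero variance")
  expect_error(variance_ratio_test(1, 1:3), "n >= 2")
})

test_that("variance-ratio p matches a Monte-Carlo tail probability", {
  # with equal group sizes the null tail of the larger/smaller variance
  # ratio is exactly twice the one-tailed F probability, i.e. the
  # two-tailed p reported by the test
  set.seed(33)
  x <- rnorm(8, sd = 1.8); y <- rnorm(8)
  obs <- variance_ratio_test(x, y)
  nsim <- 2e5
  v1 <- matrix(rnorm(8 * nsim), 8)
  v2 <- matrix(rnorm(8 * nsim), 8)
  va <- matrixStats_colVars(v1)
  vb <- matrixStats_colVars(v2)
  f_null <- pmax(va, vb) / pmin(va, vb)
  p_mc <- mean(f_null >= obs$statistic)
  se <- sqrt(p_mc * (1 - p_mc) / nsim)
  expect_lt(abs(p_mc - obs$p_value), 3 * se + 1e-3)
})

test_that("two-sample t matches base R and a permutation oracle", {
  set.seed(12)
  x <- rnorm(9, 1); y <- rnorm(12)
  for (welch in c(FALSE, TRUE)) {
    mine <- two_sample_t(x, y, welch = welch)
    ref <- stats::t.test(x, y, var.equal = !welch)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
  }
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # sign symmetry
  m1 <- two_sample_t(x, y)
  m2 <- two_sample_t(-x, -y)
  expect_equal(m2$statistic, -m1$statistic)
  expect_equal(m2$p_value, m1$p_value)
  # permutation oracle on a small example
  set.seed(77)
  xs <- c(2.1, 3.4, 1.9, 2.8, 3.0)
  ys <- c(1.2, 1.9, 1.5, 2.2, 1.1, 1.7)
  t_obs <- abs(two_sample_t(xs, ys)$statistic)
  pool <- c(xs, ys)
  nperm <- 4000
  exceed <- vapply(seq_len(nperm), function(i) {
    idx <- sample(11, 5)
    abs(two_sample_t(pool[idx], pool[-idx])$statistic) >= t_obs - 1e-12
  }, logical(1))
  p_perm <- mean(exceed)
  p_mine <- two_sample_t(xs, ys)$p_value
  se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(p_mine - p_perm), 3 * se + 0.01)
})

test_that("describe returns the standard summaries", {
  d <- describe(c(2, 4))
  expect_equal(d$mean, 3)
  expect_equal(d$sd, sqrt(2))
  expect_equal(d$median, 3)
  d1 <- describe(5)
  expect_equal(d1$sd, 0)
  expect_false(d1$sd_defined)
  set.seed(1)
  v <- rnorm(37)
  dv <- describe(v)
  expect_equal(dv$mean, sum(v) / 37)
  expect_equal(dv$sd, sqrt(sum((v - mean(v))^2) / 36))
  sv <- sort(v)
  expect_equal(dv$median, sv[19])
  expect_error(describe(numeric(0)), "n >= 1")
})
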