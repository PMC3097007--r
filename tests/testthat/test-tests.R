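# Hypothesis tests: published worked examples, algebraic identities,
# cross-checks against independent implementations, degenerate rules.

std <- expand_counts(c(19, 10, 7, 3, 6))    # standard programme, n = 45
int <- expand_counts(c(39, 8, 8, 0, 0))     # intensive programme, n = 55

test_that("the asthma example reproduces the published p-values", {
  expect_equal(round(t_test_pooled(std, int)$p_value, 4), 0.0003)
  expect_equal(round(welch_u_test(std, int)$p_value, 4), 0.0007)
  expect_equal(round(wmw_test(std, int)$p_value, 3), 0.001)
  expect_equal(round(welch_u_test(std, int)$mean_difference, 2), 0.83)
})

test_that("pooled T and Welch agree with stats::t.test and coincide for
           balanced groups with equal variances", {
  set.seed(31)
  for (i in 1:25) {
    x <- sample(0:4, sample(5:40, 1), replace = TRUE)
    y <- sample(0:4, sample(5:40, 1), replace = TRUE)
    if (var(x) == 0 && var(y) == 0) next
    rt <- t_test_pooled(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(rt$statistic, unname(ref$statistic))
    expect_equal(rt$p_value, ref$p.value)
    rw <- welch_u_test(x, y)
    refw <- t.test(x, y)
    expect_equal(rw$statistic, unname(refw$statistic))
    expect_equal(rw$df, unname(refw$parameter))
    expect_equal(rw$p_value, refw$p.value)
  }
  # same m = n and equal sample variances: identical statistics
  x <- c(0, 1, 2, 3, 4, 0)
  y <- c(1, 2, 3, 4, 5, 1)
  expect_equal(var(x), var(y))
  expect_equal(t_test_pooled(x, y)$statistic,
               welch_u_test(x, y)$statistic)
})

test_that("WMW matches the tie-corrected normal approximation of
           stats::wilcox.test without continuity correction", {
  set.seed(32)
  for (i in 1:25) {
    x <- sample(0:3, sample(8:30, 1), replace = TRUE)
    y <- sample(0:3, sample(8:30, 1), replace = TRUE)
    if (length(unique(c(x, y))) == 1) next
    ref <- suppressWarnings(wilcox.test(x, y, correct = FALSE))
    expect_equal(wmw_test(x, y)$p_value, ref$p.value)
  }
})

test_that("Brunner-Munzel matches an independent step-by-step computation
           of the rank formulas", {
  # mixed-tie m = n = 5 case with frozen, independently confirmed values
  x <- c(0, 1, 1, 2, 3)
  y <- c(1, 2, 2, 3, 3)
  r <- brunner_munzel_test(x, y)
  expect_equal(r$statistic, 1.27442578, tolerance = 1e-7)
  expect_equal(r$df, 6.72095663, tolerance = 1e-7)
  expect_equal(r$p_value, 0.24480351, tolerance = 1e-7)
  expect_equal(r$relative_effect, 0.72)

  set.seed(33)
  for (i in 1:20) {
    x <- sample(0:4, sample(4:15, 1), replace = TRUE)
    y <- sample(0:4, sample(4:15, 1), replace = TRUE)
    o <- oracle_bm(x, y)
    if (!is.finite(o$W)) next
    r <- brunner_munzel_test(x, y)
    expect_equal(r$statistic, o$W)
    expect_equal(r$df, o$df)
    expect_equal(r$p_value, o$p)
    expect_equal(r$relative_effect, o$phat)
  }
})

test_that("identical groups give null results and complete separation a
           relative effect of one", {
  x <- c(0, 1, 2, 2, 3)
  for (f in list(t_test_pooled, welch_u_test, wmw_test,
                 brunner_munzel_test)) {
    r <- f(x, x)
    expect_equal(r$statistic, 0)
    expect_equal(r$p_value, 1)
    expect_equal(r$mean_difference, 0)
  }
  expect_equal(wmw_test(x, x)$relative_effect, 0.5)
  expect_equal(brunner_munzel_test(x, x)$relative_effect, 0.5)
  # every group-1 value below every group-2 value: Pr(X < Y) = 1
  expect_equal(brunner_munzel_test(c(0, 0, 1), c(2, 3, 3))$relative_effect,
               1)
})

test_that("swapping group order flips signs, complements the relative
           effect and preserves p-values", {
  set.seed(34)
  for (i in 1:15) {
    x <- sample(0:3, 12, replace = TRUE)
    y <- sample(0:3, 9, replace = TRUE)
    for (f in list(t_test_pooled, welch_u_test, wmw_test,
                   brunner_munzel_test)) {
      a <- f(x, y)
      b <- f(y, x)
      expect_equal(a$statistic, -b$statistic)
      expect_equal(a$mean_difference, -b$mean_difference)
      expect_equal(a$p_value, b$p_value)
      if (!is.na(a$relative_effect)) {
        expect_equal(a$relative_effect, 1 - b$relative_effect)
      }
    }
  }
})

test_that("rank statistics are shift-invariant and mean differences
           shift-equivariant", {
  x <- c(0, 1, 1, 2)
  y <- c(1, 2, 3, 3)
  for (f in list(wmw_test, brunner_munzel_test)) {
    expect_equal(f(x, y)$p_value, f(x + 1, y + 1)$p_value)
    expect_equal(f(x, y)$statistic, f(x + 1, y + 1)$statistic)
  }
  expect_equal(welch_u_test(x, y)$mean_difference,
               welch_u_test(x + 1, y + 1)$mean_difference)
})

test_that("degenerate data follow the zero-variance rules", {
  a <- rep(2L, 5)
  b <- rep(2L, 6)
  c3 <- rep(3L, 5)
  for (f in list(t_test_pooled, welch_u_test)) {
    r <- f(a, b)
    expect_equal(r$p_value, 1)
    expect_true(r$degenerate)
    r2 <- f(a, c3)
    expect_equal(r2$p_value, 0)
    expect_true(r2$degenerate)
  }
  expect_equal(wmw_test(a, b)$p_value, 1)
  r <- brunner_munzel_test(a, b)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  r2 <- brunner_munzel_test(a, c3)
  expect_equal(r2$p_value, 0)
  expect_true(r2$degenerate)
  # constant identical groups under permutation: p = 1
  expect_equal(bm_permutation_test(a, b, 200)$p_value, 1)
})

test_that("without ties WMW and Brunner-Munzel p-values converge", {
  set.seed(35)
  x <- rnorm(150)
  y <- rnorm(150, 0.15)
  p1 <- wmw_test(x, y)$p_value
  p2 <- brunner_munzel_test(x, y)$p_value
  expect_lt(abs(p1 - p2) / p1, 0.10)
})

test_that("the data-frame interface matches the vector interface and
           respects group order", {
  df <- data.frame(
    visits = c(std, int),
    arm = factor(rep(c("standard", "intensive"), c(45, 55)),
                 levels = c("standard", "intensive"))
  )
  r <- compare_groups(df, visits, arm, test = "welch")
  expect_equal(r$mean_difference, welch_u_test(std, int)$mean_difference)
  expect_equal(tidy(r), tidy(welch_u_test(std, int)))
  expect_error(compare_groups(data.frame(v = 1:3, g = c("a", "b", "c")),
                              v, g), "exactly two groups")
})
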