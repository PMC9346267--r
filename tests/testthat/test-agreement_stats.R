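test_that("CCC equals 1 for identical vectors and -1 for mirrored ones", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  fit <- concordance_correlation(x, x)
  expect_equal(fit$ccc, 1.0)
  expect_equal(fit$category, "strong")

  z <- x - mean(x)
  expect_equal(concordance_correlation(z, -z)$ccc, -1.0)
})

test_that("CCC matches the independently coded textbook formula", {
  fit <- concordance_correlation(c(1, 2, 3, 4), c(1, 2, 3, 6))
  expect_equal(fit$ccc, oracle_ccc(c(1, 2, 3, 4), c(1, 2, 3, 6)))
  expect_equal(fit$ccc, 0.8) # frozen from the oracle

  set.seed(123)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- 0.5 * x + rnorm(n, mean = runif(1, -1, 1))
    expect_equal(concordance_correlation(x, y)$ccc, oracle_ccc(x, y),
      tolerance = 1e-12
    )
  }
})

test_that("CCC respects Lin's inequality, symmetry and affine invariance", {
  set.seed(99)
  for (i in 1:50) {
    x <- rnorm(20)
    y <- rnorm(20) + 0.3 * x
    cc <- concordance_correlation(x, y)
    expect_lte(abs(cc$ccc), abs(cc$pearson) + 1e-12)
    expect_equal(cc$ccc, concordance_correlation(y, x)$ccc)
    # same positive affine map applied to both leaves agreement unchanged
    expect_equal(
      concordance_correlation(2 * x + 3, 2 * y + 3)$ccc, cc$ccc,
      tolerance = 1e-12
    )
  }
})

test_that("CCC confidence interval brackets the estimate and respects level", {
  set.seed(7)
  x <- rnorm(50, 10, 3)
  y <- x + rnorm(50, 0, 1)
  fit <- concordance_correlation(x, y)
  expect_lt(fit$ci_low, fit$ccc)
  expect_gt(fit$ci_high, fit$ccc)
  wider <- concordance_correlation(x, y, conf_level = 0.99)
  expect_lt(wider$ci_low, fit$ci_low)
  # bias-corrected variant shifts moments but stays close at n = 50
  bc <- concordance_correlation(x, y, bias_correction = TRUE)
  expect_equal(bc$ccc, fit$ccc, tolerance = 0.01)
  expect_false(bc$ccc == fit$ccc)
})

test_that("CCC agreement categories switch exactly at 0.800 and 0.950", {
  expect_equal(
    ccc_category(c(0.799, 0.800, 0.949, 0.950, 0.999)),
    c("none", "acceptable", "acceptable", "strong", "strong")
  )
})

test_that("CCC rejects degenerate input", {
  expect_error(concordance_correlation(1:3, 1:4), "equal length")
  expect_error(concordance_correlation(1:2, 1:2), "at least 3")
  expect_error(concordance_correlation(c(1, 2, NA), c(1, 2, 3)), "finite")
  expect_error(concordance_correlation(rep(1, 5), rep(2, 5)), "constant")
})

test_that("tidy and glance summarise a CCC fit", {
  fit <- concordance_correlation(1:10, 1:10 + c(rep(0, 9), 1))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("estimate", "ci_low", "ci_high", "category"))
  expect_named(
    glance(fit),
    c("ccc", "ci_low", "ci_high", "category", "pearson", "n")
  )
})

test_that("Spearman correlation is rank-based with mid-rank ties", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(spearman_correlation(x, exp(x))$rho, 1.0)
  expect_equal(spearman_correlation(x, -x)$rho, -1.0)
  set.seed(5)
  for (i in 1:20) {
    a <- sample(1:5, 15, replace = TRUE) # heavy ties
    b <- sample(1:5, 15, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(spearman_correlation(a, b)$rho, oracle_spearman(a, b),
      tolerance = 1e-12
    )
  }
  expect_error(spearman_correlation(1:3, 1:4), "equal length")
})

test_that("group location tests detect separation and respect the null", {
  same <- replicate(4, c(1.1, 2.2, 3.3, 4.4), simplify = FALSE)
  kw <- group_location_test(same, "kruskal")
  expect_lt(kw$statistic, 1e-9)
  expect_gt(kw$p_value, 0.99)

  sep <- list(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  expect_lt(group_location_test(sep, "kruskal")$p_value, 0.001)
  expect_lt(group_location_test(sep, "anova")$p_value, 0.001)

  # data-frame interface
  df <- data.frame(value = unlist(sep), group = rep(c("a", "b"), each = 10))
  expect_equal(
    group_location_test(df, "kruskal")$statistic,
    group_location_test(sep, "kruskal")$statistic
  )

  expect_error(group_location_test(list(1:5)), "at least 2 groups")
  expect_error(group_location_test(list(1:5, 2)), "at least 2 observations")
})

test_that("well-separated two-group rank test agrees with exact enumeration", {
  # all of A below all of B: the rank-sum attains its extreme; the exact
  # two-sided enumeration p is 2 / choose(20, 10)
  a <- 1:10
  b <- 21:30
  exact_p <- 2 / choose(20, 10)
  got <- stats::wilcox.test(a, b, exact = TRUE)$p.value
  expect_equal(got, exact_p)
  expect_lt(group_location_test(list(a, b), "kruskal")$p_value, 0.001)
})
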