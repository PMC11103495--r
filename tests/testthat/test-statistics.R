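test_that("relative values divide by the cohort maximum", {
  expect_equal(relative_values(c(2, 4, 8)), c(0.25, 0.5, 1.0))
  expect_equal(relative_values(5), 1.0)
  expect_error(relative_values(c(0, 0)), "zero")
  expect_error(relative_values(c(-1, 2)), "nonnegative")
})

test_that("Pearson correlation hits the exact linear limits", {
  x <- c(1, 2, 3, 4, 5)
  up <- pearson_cor(x, 2 * x + 1)
  expect_equal(up$statistic, 1)
  down <- pearson_cor(x, -x)
  expect_equal(down$statistic, -1)
  expect_error(pearson_cor(x, rep(3, 5)), "constant")
  expect_error(pearson_cor(x, 1:4), "mismatch")
})

test_that("Pearson r and p match the closed-form oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  res <- pearson_cor(x, y)
  # independent closed form: covariance over the product of SDs, and the
  # t-distribution transform for the two-sided p-value
  r_cf <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_cf <- r_cf * sqrt(3 / (1 - r_cf^2))
  p_cf <- 2 * pt(-abs(t_cf), df = 3)
  expect_equal(res$statistic, r_cf, tolerance = 1e-12)
  expect_equal(res$p_value, p_cf, tolerance = 1e-12)
  expect_equal(res$df, 3)
})

test_that("Pearson r is invariant under positive affine rescaling", {
  set.seed(14)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30, 0, 0.3)
  r0 <- pearson_cor(x, y)$statistic
  expect_equal(pearson_cor(3 * x + 7, 0.2 * y - 4)$statistic, r0,
               tolerance = 1e-12)
})

test_that("identical groups give F = 0", {
  res <- anova_lsd(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(res$statistic, 0)
})

test_that("two balanced groups reproduce the pooled t-test (F = t^2)", {
  set.seed(8)
  a <- rnorm(10, 0, 1); b <- rnorm(10, 0.8, 1)
  res <- anova_lsd(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(res$pairwise$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA and LSD match a from-scratch sums-of-squares oracle", {
  groups <- list(A = c(1, 2, 3), B = c(2, 3, 4), C = c(10, 11, 12))
  res <- anova_lsd(groups)

  # brute-force decomposition
  all_v <- unlist(groups); grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  msw <- ssw / (length(all_v) - 3)
  f_oracle <- (ssb / 2) / msw
  expect_equal(res$statistic, f_oracle, tolerance = 1e-12)
  expect_equal(unname(res$ss[["between"]]), ssb, tolerance = 1e-12)

  # cross-check against stats::aov as an independent route
  df <- data.frame(v = all_v, g = rep(names(groups), lengths(groups)))
  av <- summary(aov(v ~ g, df))[[1]]
  expect_equal(res$statistic, av$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_value, av$`Pr(>F)`[1], tolerance = 1e-10)

  # LSD pairwise p from the pooled-variance t formula
  d_ab <- mean(groups$A) - mean(groups$B)
  se <- sqrt(msw * (1 / 3 + 1 / 3))
  p_ab <- 2 * pt(-abs(d_ab / se), df = 6)
  row_ab <- res$pairwise[res$pairwise$group1 == "A" &
                         res$pairwise$group2 == "B", ]
  expect_equal(row_ab$p, p_ab, tolerance = 1e-12)
  expect_equal(nrow(res$pairwise), 3L)  # all pairs covered
})

test_that("the sums of squares always decompose exactly", {
  set.seed(42)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:12, 1),
                                                   mean = rnorm(1, 0, 2)))
    res <- anova_lsd(groups)
    expect_lt(abs(res$ss[["total"]] -
                  (res$ss[["between"]] + res$ss[["within"]])), 1e-9)
  }
})

test_that("significance stars follow the plotting convention", {
  expect_equal(significance_stars(c(0.2, 0.03, 0.005, 5e-4, 5e-5)),
               c("ns", "*", "**", "***", "****"))
})

test_that("protected LSD skips pairwise tests when the omnibus is null", {
  set.seed(2)
  g <- lapply(1:3, function(i) rnorm(5))
  res <- anova_lsd(g, protected = TRUE)
  if (res$p_value >= 0.05) expect_true(all(is.na(res$pairwise$p)))
})

test_that("anova_lsd validates its inputs", {
  expect_error(anova_lsd(list(a = c(1, 2))), "2 groups")
  expect_error(anova_lsd(list(a = c(1, 2), b = 3)), "at least 2 values")
})

test_that("cohort summaries report quartiles and Tukey whiskers", {
  v <- c(1, 2, 3, 4, 100)
  s <- cohort_summary(v, "g")
  expect_equal(s$median, 3)
  expect_equal(s$q25, 2)
  expect_equal(s$q75, 4)
  expect_equal(s$whisker_high, 4)  # 100 lies beyond 1.5 IQR
  expect_equal(s$whisker_low, 1)
})
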