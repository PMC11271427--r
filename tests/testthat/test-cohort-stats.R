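# Cohort statistics: reporting arithmetic, correlations, PCA composite,
# multiplicity correction, and the normality-gated comparison.

test_that("percent increase rounds half away from zero, as printed results do", {
  expect_equal(percent_increase(1.78, 1.26)$percent, 41)
  expect_equal(percent_increase(1.95, 0.68)$percent, 187)
  expect_equal(percent_increase(1.175, 1)$percent, 18)  # 17.5 -> 18, not 17
  expect_equal(percent_increase(0.9, 1)$percent, -10)
  expect_error(percent_increase(1, 0), "b = 0")
})

test_that("restoration ratio is the value as a percent of the intact reference", {
  expect_equal(restoration_ratio(1.95, 3.0)$percent, 65)
  expect_equal(restoration_ratio(10.5, 60)$percent, 18)
  expect_equal(restoration_ratio(10.5, 60)$percent_raw, 17.5)
  expect_error(restoration_ratio(1, -2), "positive")
})

test_that("round_half_away differs from banker's rounding exactly at halves", {
  expect_equal(round_half_away(c(0.5, 1.5, 2.5, -0.5, -2.5)),
               c(1, 2, 3, -1, -3))
  expect_equal(round_half_away(c(1.4, -1.4)), c(1, -1))
})

test_that("correlation matches cor.test and the slope matches least squares", {
  set.seed(20)
  d <- data.frame(x = rnorm(30))
  d$y <- 2 * d$x + rnorm(30, 0, 0.5)
  res <- pearson_with_ci(d, x, y)
  ct <- cor.test(d$x, d$y)
  fit <- lm(y ~ x, data = d)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(c(res$ci_lo, res$ci_hi), as.numeric(ct$conf.int))
  expect_equal(res$p_value, ct$p.value)
  expect_equal(res$slope, unname(coef(fit)[2]))
  expect_equal(tidy(res)$estimate[1], res$r)
  expect_equal(glance(res)$nobs, 30)
})

test_that("correlation refuses degenerate inputs with named errors", {
  expect_error(pearson_with_ci(data.frame(x = 1:2, y = 1:2), x, y),
               "at least 3")
  expect_error(pearson_with_ci(data.frame(x = rep(1, 5), y = 1:5), x, y),
               "zero variance")
})

test_that("PCA composite recovers a single shared factor with oriented loadings", {
  set.seed(30)
  f <- rnorm(40)
  d <- tibble::tibble(group = rep(c("a", "b"), 20),
                      m1 = 2 * f + rnorm(40, 0, 0.05),
                      m2 = -3 * f + rnorm(40, 0, 0.05),
                      m3 = f + rnorm(40, 0, 0.05))
  pca <- pca_composite(d, flip = "m2")
  expect_gt(pca$variance_explained, 0.98)
  expect_true(all(pca$loadings$loading > 0))  # flip made all signs agree
  expect_equal(nrow(pca$scores), 40)
  expect_true("group" %in% names(pca$scores))
  # orientation: score increases with the first metric
  expect_gt(cor(pca$scores$pc1, d$m1), 0.99)
  expect_equal(glance(pca)$n_metrics, 3)
})

test_that("PCA composite refuses missing cells, constants, and unknown columns", {
  d <- tibble::tibble(m1 = c(1, 2, NA), m2 = c(3, 1, 2))
  expect_error(pca_composite(d), "missing cells")
  d2 <- tibble::tibble(m1 = c(1, 1, 1), m2 = c(3, 1, 2))
  expect_error(pca_composite(d2), "constant")
  d3 <- tibble::tibble(m1 = 1:5 + 0.1, m2 = c(3, 1, 2, 5, 4))
  expect_error(pca_composite(d3, flip = "nope"), "nope")
})

test_that("Holm-Sidak adjustment matches the step-down formula and is monotone", {
  p <- c(0.01, 0.04, 0.03)
  adj <- holm_sidak(p)
  # by hand: sorted p (0.01, 0.03, 0.04), multiplicities 3, 2, 1
  expect_equal(adj[1], 1 - (1 - 0.01)^3)
  expect_equal(adj[3], max(1 - (1 - 0.01)^3, 1 - (1 - 0.03)^2))
  expect_equal(adj[2], max(adj[3], 1 - (1 - 0.04)^1))
  expect_true(all(adj >= p))
  expect_equal(holm_sidak(0.2), 0.2)  # family of one is unadjusted
  expect_error(holm_sidak(c(0.5, 1.2)))
})

test_that("normally distributed groups take the t-test branch", {
  set.seed(40)
  x <- rnorm(12, 1); y <- rnorm(12, 0)
  cmp <- group_compare(x, y)
  expect_equal(cmp$test, "unpaired t-test")
  expect_true(cmp$normal)
  expect_equal(cmp$p_value, t.test(x, y)$p.value)
})

test_that("heavily skewed groups take the Mann-Whitney branch", {
  set.seed(41)
  x <- rexp(20)^3
  y <- rexp(20)^3 + 0.5
  cmp <- group_compare(x, y)
  expect_equal(cmp$test, "Mann-Whitney U")
  expect_false(cmp$normal)
  expect_equal(cmp$p_value,
               suppressWarnings(wilcox.test(x, y, exact = FALSE))$p.value)
})

test_that("paired comparisons gate on the differences and require equal sizes", {
  set.seed(42)
  x <- rnorm(10); y <- x + rnorm(10, 0.3, 0.2)
  cmp <- group_compare(x, y, paired = TRUE)
  expect_equal(cmp$test, "paired t-test")
  expect_equal(cmp$p_value, t.test(x, y, paired = TRUE)$p.value)
  expect_error(group_compare(x, y[1:5], paired = TRUE), "equal")
})

test_that("a zero-variance group is treated as non-normal, not an error", {
  cmp <- group_compare(rep(1, 6), c(1, 2, 1, 3, 2, 2))
  expect_false(cmp$normal)
  expect_match(cmp$test, "Mann-Whitney")
})
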