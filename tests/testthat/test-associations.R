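test_that("3-SD outlier masks follow the exclusion rule", {
  expect_warning(m <- exclude_outliers(rep(2, 10)), "zero SD")
  expect_true(all(m))
  set.seed(2)
  x <- rnorm(100)
  x[101] <- mean(x) + 10 * sd(x)
  m <- exclude_outliers(x)
  expect_identical(which(!m), 101L)
  # surviving values satisfy the bound under the full-sample statistics
  mu <- mean(x); s <- sd(x)
  expect_true(all(abs(x[m] - mu) <= 3 * s))
  # missing values are excluded
  x[5] <- NA
  expect_false(exclude_outliers(x)[5])
  expect_error(exclude_outliers(1), "n >= 2")
})

test_that("Holm correction reproduces the step-down rule", {
  expect_equal(holm_correct(0.03), 0.03)
  expect_equal(holm_correct(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_correct(c(0.03, 0.03)), c(0.06, 0.06))
  # permutation equivariance, monotone dominance, cap at 1
  set.seed(4)
  p <- runif(7)
  perm <- sample(7)
  expect_equal(holm_correct(p)[perm], holm_correct(p[perm]))
  expect_true(all(holm_correct(p) >= p))
  expect_true(all(holm_correct(rep(0.9, 5)) <= 1))
  expect_error(holm_correct(c(0.5, 1.2)), "0, 1")
  # brute-force oracle: sort, multiply by m - i + 1, cummax, unsort
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    o <- order(p)
    adj <- pmin(1, cummax(p[o] * (length(p) - seq_along(p) + 1)))
    expect_equal(holm_correct(p), adj[order(o)], tolerance = 1e-12)
  }
})

test_that("correlation layer masks outliers and corrects across two DVs", {
  set.seed(9)
  n <- 300
  x <- rnorm(n)
  vars <- data.frame(lnk_delay = x + rnorm(n, 0, 2),
                     lnk_date = x + rnorm(n, 0, 2))
  scales <- data.frame(s1 = x + rnorm(n, 0, 3), s2 = rnorm(n))
  tab <- pearson_with_holm(vars, scales)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$p_c >= tab$p))
  for (sc in c("s1", "s2")) {
    sub <- tab[tab$scale == sc, ]
    expect_equal(sub$p_c, holm_correct(sub$p))
  }
  # identity pair gives r = 1
  t1 <- pearson_with_holm(data.frame(v = x), data.frame(s = x))
  expect_equal(t1$r, 1)
  # an extreme outlier shrinks n through the pairwise mask intersection
  vars$lnk_delay[1] <- 100
  t2 <- pearson_with_holm(vars, scales)
  for (sc in c("s1", "s2")) {
    expected_n <- sum(exclude_outliers(vars$lnk_delay) &
                        exclude_outliers(scales[[sc]]))
    expect_equal(t2$n[t2$td_variable == "lnk_delay" & t2$scale == sc],
                 expected_n)
    expect_false(1 %in% which(exclude_outliers(vars$lnk_delay)))
  }
})

test_that("bivariate-normal sampling keeps r near the design effect size", {
  set.seed(731)
  n <- 731
  x <- rnorm(n); y <- 0.1 * x + sqrt(1 - 0.01) * rnorm(n)
  r <- cor(x, y)
  expect_gt(r, 0.03)
  expect_lt(r, 0.17)
})

test_that("robust regression returns standardized, sandwich-based betas", {
  set.seed(12)
  n <- 500
  x <- rnorm(n)
  y <- 0.4 * x + rnorm(n)
  # single standardized regressor: beta equals the Pearson r exactly
  r <- robust_ols(y, data.frame(x = x), z_threshold = Inf)
  expect_equal(r$table$beta[2], cor(y, x), tolerance = 1e-10)
  # intercept-only without standardization: coefficient is mean(y)
  r0 <- robust_ols(y, data.frame(row = rep(1, n))[, 0, drop = FALSE],
                   standardize = FALSE, z_threshold = Inf)
  expect_equal(r0$table$beta[1], mean(y), tolerance = 1e-10)
  # robust and classical SEs agree asymptotically under homoskedasticity
  n2 <- 5000
  X2 <- data.frame(a = rnorm(n2), b = rnorm(n2))
  y2 <- 0.3 * X2$a - 0.2 * X2$b + rnorm(n2)
  rr <- robust_ols(y2, X2, z_threshold = Inf)
  cls <- summary(rr$fit)$coefficients[, 2]
  expect_true(all(abs(rr$table$se_robust / cls - 1) < 0.05))
  # CI construction and BP attachment
  expect_equal(rr$table$ci_low,
               rr$table$beta - qnorm(0.975) * rr$table$se_robust)
  expect_true(is.finite(rr$breusch_pagan$statistic))
  # collinear designs are rejected with the offending column named
  X3 <- data.frame(a = x, b = 2 * x)
  expect_error(robust_ols(y, X3, z_threshold = Inf), "collinear.*b|b.*collinear")
})

test_that("Breusch-Pagan responds to real heteroskedasticity only", {
  set.seed(21)
  n <- 1000
  # error SD proportional to the regressor itself
  x <- runif(n, 0.5, 3)
  het <- robust_ols(0.2 * x + rnorm(n, 0, 0.5 * x), data.frame(x = x),
                    z_threshold = Inf)
  expect_lt(het$breusch_pagan$p, 0.01)
  # constant residuals: statistic exactly zero
  fit0 <- lm(c(1, 2, 3, 4) ~ c(0, 1, 2, 3))
  expect_equal(breusch_pagan(fit0)$statistic, 0)
})

test_that("exact correlation power is calibrated and monotone", {
  # matches Monte Carlo at moderate n
  set.seed(5)
  B <- 4000; n <- 120
  rej <- mean(replicate(B, {
    x <- rnorm(n); y <- 0.2 * x + sqrt(1 - 0.04) * rnorm(n)
    cor.test(x, y)$p.value < 0.05
  }))
  expect_lt(abs(power_correlation(n, 0.2) - rej), 0.025)
  # near-null effect: power collapses to the test size
  expect_lt(abs(power_correlation(400, 1e-8) - 0.05), 0.002)
  # required n decreases in the effect size
  ns <- vapply(c(0.1, 0.2, 0.3), function(r) power_n_correlation(r), 0)
  expect_true(all(diff(ns) < 0))
  # the returned n is minimal
  n1 <- power_n_correlation(0.3)
  expect_gte(power_correlation(n1, 0.3), 0.80)
  expect_lt(power_correlation(n1 - 1, 0.3), 0.80)
  expect_error(power_n_correlation(0.0005, n_cap = 1000), "cap")
})
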