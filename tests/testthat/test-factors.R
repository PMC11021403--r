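test_that("bivariate-normal rectangle probabilities match quadrature", {
  for (rho in c(-0.85, -0.3, 0, 0.4, 0.9)) {
    p_pkg <- tdisc:::.bvn_cells(c(-Inf, -0.5, 0.7, Inf),
                                c(-Inf, 0.2, Inf), rho)
    p_ora <- matrix(0, 3, 2)
    aa <- c(-8, -0.5, 0.7, 8); bb <- c(-8, 0.2, 8)
    for (i in 1:3) for (j in 1:2)
      p_ora[i, j] <- bvn_rect_oracle(aa[i], aa[i + 1], bb[j], bb[j + 1], rho)
    expect_equal(unclass(p_pkg), p_ora, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("polychoric estimation matches independence and perfection", {
  # independent equal cells
  x <- rep(c(0, 0, 1, 1), 25); y <- rep(c(0, 1, 0, 1), 25)
  expect_lt(abs(polychoric_ml(x, y)), 0.02)
  # perfectly concordant dichotomies approach the cap
  x2 <- rep(0:1, each = 40); y2 <- x2
  expect_gt(polychoric_ml(x2, y2), 0.98)
  expect_error(polychoric_ml(rep(1, 40), rep(0:1, 20)), "category")
  expect_error(polychoric_ml(1:3, 1:3), "n >= 20")
})

test_that("polychoric matches a brute-force likelihood grid search", {
  set.seed(42)
  for (kk in list(c(2, 2), c(3, 4), c(5, 5))) {
    z <- MASS::mvrnorm(400, c(0, 0),
                       matrix(c(1, 0.45, 0.45, 1), 2))
    x <- findInterval(z[, 1], qnorm(seq_len(kk[1] - 1) / kk[1] + 0.05))
    y <- findInterval(z[, 2], qnorm(seq_len(kk[2] - 1) / kk[2] - 0.05))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    r_pkg <- polychoric_ml(x, y)
    r_grid <- polychoric_grid_oracle(table(factor(x), factor(y)))
    expect_equal(r_pkg, r_grid, tolerance = 0.01)
  }
})

test_that("polyserial recovers latent mixed-type correlations", {
  set.seed(7)
  z <- MASS::mvrnorm(1500, c(0, 0), matrix(c(1, 0.6, 0.6, 1), 2))
  y <- findInterval(z[, 2], c(-0.6, 0.4, 1.1))
  expect_equal(polyserial_ml(z[, 1], y), 0.6, tolerance = 0.06)
  expect_error(polyserial_ml(z[, 1], rep(2, 1500)), "single category")
})

test_that("hetcor dispatches by type and is invariant to recoding", {
  set.seed(19)
  n <- 300
  z <- MASS::mvrnorm(n, rep(0, 3),
                     matrix(c(1, .5, .3, .5, 1, .4, .3, .4, 1), 3))
  cont <- as.data.frame(z)
  hc <- hetcor_matrix(cont, rep("continuous", 3))
  expect_equal(hc$matrix, cor(z), ignore_attr = TRUE, tolerance = 1e-12)
  expect_false(hc$smoothing_applied)
  # ordinal pair types recorded and order invariances hold
  X <- data.frame(a = findInterval(z[, 1], c(-0.5, 0.5)),
                  b = findInterval(z[, 2], c(-1, 0, 1)),
                  c = z[, 3])
  h1 <- hetcor_matrix(X, c("ordinal", "ordinal", "continuous"))
  expect_identical(h1$pair_type[1, 2], "polychoric")
  expect_identical(h1$pair_type[1, 3], "polyserial")
  # strictly increasing relabeling of categories
  X2 <- X; X2$a <- c(0, 5, 9)[X$a + 1]; X2$b <- X$b * 3 + 1
  h2 <- hetcor_matrix(X2, c("ordinal", "ordinal", "continuous"))
  expect_equal(h1$matrix, h2$matrix, ignore_attr = TRUE, tolerance = 1e-10)
  # participant order
  h3 <- hetcor_matrix(X[sample(n), ], c("ordinal", "ordinal", "continuous"))
  expect_equal(h1$matrix, h3$matrix, ignore_attr = TRUE, tolerance = 1e-10)
  # pairwise-complete handling tolerates scattered missingness
  Xna <- X; Xna$a[1:10] <- NA
  expect_silent(hetcor_matrix(Xna, c("ordinal", "ordinal", "continuous")))
  Xall <- X; Xall$a[] <- NA
  expect_error(hetcor_matrix(Xall, c("ordinal", "ordinal", "continuous")),
               "all-missing")
})

test_that("indefinite correlation inputs are smoothed to PSD", {
  # tiny sample of short ordinal items can produce an indefinite matrix;
  # craft one deterministically: pairwise correlations from inconsistent
  # subsamples of three alternating dichotomies
  set.seed(101)
  X <- data.frame(a = rep(0:1, 30),
                  b = c(rep(0:1, 15), rep(1:0, 15)),
                  c = c(rep(1:0, 10), rep(0:1, 20)))
  h <- hetcor_matrix(X, rep("ordinal", 3))
  expect_gte(min(eigen(h$matrix, symmetric = TRUE)$values), -1e-12)
  expect_equal(unname(diag(h$matrix)), rep(1, 3))
})

test_that("CNG picks the elbow and matches brute force exactly", {
  expect_equal(cng_factor_count(c(10, 6, 3, 1, 0.9, 0.8, 0.7, 0.6)), 3)
  # perfectly linear decay: constant index, tie to the smallest count
  expect_equal(cng_factor_count(seq(10, 1, length.out = 10)), 3)
  expect_error(cng_factor_count(c(3, 2, 1, 0.5, 0.2)), "6")
  # brute-force oracle via lm() on random decreasing sequences
  set.seed(33)
  for (i in 1:25) {
    e <- sort(rexp(sample(8:20, 1), 0.5), decreasing = TRUE)
    ts <- 3:(length(e) - 3)
    cng <- vapply(ts, function(t) {
      s2 <- coef(lm(e[(t + 1):(t + 3)] ~ I(1:3)))[2]
      s1 <- coef(lm(e[(t - 2):t] ~ I(1:3)))[2]
      unname(s2 - s1)
    }, 0)
    expect_identical(cng_factor_count(e), ts[which.max(cng)])
  }
})

test_that("ML-EFA with oblimin recovers generating structures", {
  set.seed(55)
  # orthogonal two-factor structure, continuous indicators
  L <- matrix(0, 12, 2); L[1:6, 1] <- 0.7; L[7:12, 2] <- 0.7
  F2 <- MASS::mvrnorm(2000, c(0, 0), diag(2))
  X <- F2 %*% t(L) + matrix(rnorm(2000 * 12, 0, sqrt(1 - 0.49)), 2000, 12)
  hc <- hetcor_matrix(as.data.frame(X), rep("continuous", 12))
  sol <- fit_ml_efa(hc, 2, n_obs = 2000)
  # congruence with the generating loadings after column matching
  cg <- abs(outer(1:2, 1:2, Vectorize(function(i, j)
    tdisc:::tucker_congruence(L[, i], sol$loadings[, j]))))
  expect_gt(max(cg[1, ]), 0.95)
  expect_gt(max(cg[2, ]), 0.95)
  # orthogonal truth: near-identity factor correlations
  expect_lt(abs(sol$factor_corr[1, 2]), 0.1)
  expect_true(all(sol$communalities <= 1 + 1e-8))
  expect_error(fit_ml_efa(hc, 0), "n_factors")
  expect_error(fit_ml_efa(hc, 6), "items / 2")
})

test_that("regression factor scores behave like weighted sum scores", {
  set.seed(66)
  L <- matrix(0.6, 8, 1)
  F1 <- matrix(rnorm(1500), ncol = 1)
  X <- F1 %*% t(L) + matrix(rnorm(1500 * 8, 0, sqrt(1 - 0.36)), 1500, 8)
  colnames(X) <- paste0("v", 1:8)
  hc <- hetcor_matrix(as.data.frame(X), rep("continuous", 8))
  sol <- fit_ml_efa(hc, 1, n_obs = 1500)
  sc <- factor_scores(sol, as.data.frame(X))
  expect_gt(abs(cor(sc[, 1], rowSums(X))), 0.99)
  expect_gt(abs(cor(sc[, 1], F1[, 1])), 0.8)
  expect_equal(mean(sc), 0, tolerance = 1e-10)
  expect_equal(sd(sc), 1, tolerance = 1e-10)
  # missing responses: scored with a warning, no NA output
  Xm <- as.data.frame(X); Xm$v1[1:5] <- NA
  expect_warning(scm <- factor_scores(sol, Xm), "available items")
  expect_false(anyNA(scm))
})

test_that("bootstrap loading CIs are aligned and consistent", {
  set.seed(77)
  L <- matrix(0, 8, 2); L[1:4, 1] <- 0.75; L[5:8, 2] <- 0.75
  mk <- function(n) {
    F2 <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, .3, .3, 1), 2))
    d <- F2 %*% t(L) + matrix(rnorm(n * 8, 0, sqrt(1 - 0.57)), n, 8)
    as.data.frame(d)
  }
  # degenerate resampling: identical replicates give zero-width intervals
  X <- mk(400)
  ci0 <- bootstrap_loading_cis(X, 2, n_boot = 100, seed = 1,
                               var_types = rep("continuous", 8),
                               indices_fn = function(b, n) seq_len(n))
  # identical replicates differ only by rotation convergence noise
  expect_lt(max(ci0$upper - ci0$lower), 1e-4)
  expect_equal(ci0$n_dropped, 0)
  # width shrinks roughly like 1/sqrt(n)
  w <- vapply(c(250, 1000, 4000), function(n) {
    ci <- bootstrap_loading_cis(mk(n), 2, n_boot = 120, seed = n,
                                var_types = rep("continuous", 8))
    median(ci$upper - ci$lower)
  }, 0)
  expect_equal(w[1] / w[2], 2, tolerance = 0.8)
  expect_equal(w[2] / w[3], 2, tolerance = 0.8)
  expect_true(all(diff(w) < 0))
  expect_error(bootstrap_loading_cis(X, 2, n_boot = 50), "100")
})
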