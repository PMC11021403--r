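# Correlation/regression layer linking discounting quantities to symptom
# and factor scores: 3-SD outlier masks, Pearson correlations with
# Bonferroni-Holm correction across the two dependent variables,
# heteroskedasticity-robust standardized regressions with Breusch-Pagan
# tests, and the exact a priori power computation for correlation designs.

#' Outlier inclusion mask (3-SD rule)
#'
#' Marks values more than `z_threshold` SDs from the mean for exclusion;
#' mean and SD are computed once on the full non-missing sample. Missing
#' values are excluded.
#'
#' @param x numeric vector.
#' @param z_threshold default 3.
#' @return logical inclusion mask of `length(x)`.
#' @export
exclude_outliers <- function(x, z_threshold = 3) {
  if (length(x) < 2) stop("need n >= 2")
  ok <- is.finite(x)
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s == 0) {
    warning("zero SD: no outlier exclusions possible")
    return(ok)
  }
  m <- mean(x[ok])
  ok & abs(x - m) <= z_threshold * s
}

#' Bonferroni-Holm step-down correction
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order (monotone, capped at 1).
#' @export
holm_correct <- function(pvals) {
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "holm")
}

#' Pearson correlations of TD variables with symptom scales, Holm-corrected
#'
#' Computes `r`, its 95% CI and two-sided p for every TD-variable x scale
#' pair on the pairwise intersection of 3-SD outlier masks, then applies
#' Holm correction across the TD variables (the study's two dependent
#' variables) within each scale.
#'
#' @param vars data.frame of TD variables (e.g. `lnk_delay`, `lnk_date`).
#' @param scales data.frame of symptom/factor scores (same rows).
#' @param z_threshold outlier threshold, default 3.
#' @return data.frame: `td_variable`, `scale`, `n`, `r`, `ci_low`,
#'   `ci_high`, `p`, `p_c`.
#' @export
pearson_with_holm <- function(vars, scales, z_threshold = 3) {
  vars <- as.data.frame(vars); scales <- as.data.frame(scales)
  stopifnot(nrow(vars) == nrow(scales))
  mask_v <- lapply(vars, exclude_outliers, z_threshold = z_threshold)
  mask_s <- lapply(scales, exclude_outliers, z_threshold = z_threshold)
  out <- list()
  for (sc in names(scales)) {
    rows <- list()
    for (v in names(vars)) {
      ok <- mask_v[[v]] & mask_s[[sc]]
      n <- sum(ok)
      if (n < 4) {
        warning("pair ", v, " x ", sc, " skipped: n < 4 after masking")
        next
      }
      ct <- stats::cor.test(vars[[v]][ok], scales[[sc]][ok])
      rows[[v]] <- data.frame(
        td_variable = v, scale = sc, n = n,
        r = unname(ct$estimate), ci_low = ct$conf.int[1],
        ci_high = ct$conf.int[2], p = ct$p.value,
        stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    tab <- do.call(rbind, rows)
    tab$p_c <- holm_correct(tab$p)
    out[[sc]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' OLS with heteroskedasticity-robust standard errors
#'
#' Regresses a z-standardized outcome on z-standardized regressors (binary
#' dummies are left on their own scale unless `standardize_dummies`), with
#' sandwich covariance of the selected HC type, Wald 95% CIs and p-values,
#' and a studentized (Koenker) Breusch-Pagan test attached. Rows failing
#' 3-SD outlier masks on outcome or continuous regressors are dropped
#' listwise.
#'
#' @param y numeric outcome.
#' @param X data.frame of regressors (constant added automatically).
#' @param hc_type `"HC3"` (default), `"HC0"`, `"HC1"` or `"HC2"`.
#' @param z_threshold outlier threshold (set `Inf` to keep all rows).
#' @param standardize logical, z-standardize y and continuous columns
#'   (default TRUE, so coefficients are standardized betas).
#' @return object of class `RegressionResult`: `table` (term, beta,
#'   robust SE, CI, p), `breusch_pagan`, `n`, `hc_type`, `fit` (the lm).
#' @export
robust_ols <- function(y, X, hc_type = "HC3", z_threshold = 3,
                       standardize = TRUE) {
  X <- as.data.frame(X)
  stopifnot(length(y) == nrow(X))
  num <- vapply(X, is.numeric, TRUE)
  if (!all(num)) stop("all regressors must be numeric (code dummies first)")
  is_dummy <- vapply(X, function(v) all(stats::na.omit(v) %in% 0:1), TRUE)
  ok <- exclude_outliers(y, z_threshold)
  for (j in which(!is_dummy)) ok <- ok & exclude_outliers(X[[j]], z_threshold)
  for (j in which(is_dummy)) ok <- ok & !is.na(X[[j]])
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  if (standardize) {
    y <- as.numeric(scale(y))
    for (j in which(!is_dummy)) X[[j]] <- as.numeric(scale(X[[j]]))
  }
  dat <- cbind(.y = y, X)
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  V <- sandwich::vcovHC(fit, type = hc_type)
  ct <- lmtest::coeftest(fit, vcov. = V)
  est <- ct[, 1]; se <- ct[, 2]
  zc <- stats::qnorm(0.975)
  res_scale <- max(1e-8, stats::sd(y))
  bp <- if (ncol(X) == 0)
    list(statistic = NA_real_, parameter = 0, p.value = NA_real_)
  else if (stats::sd(stats::residuals(fit)) <= 1e-10 * res_scale)
    list(statistic = 0, parameter = ncol(X), p.value = 1)
  else lmtest::bptest(fit)    # Koenker studentized variant (default)
  tab <- data.frame(term = rownames(ct), beta = est, se_robust = se,
                    ci_low = est - zc * se, ci_high = est + zc * se,
                    p = ct[, 4], stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 breusch_pagan = list(statistic = unname(bp$statistic),
                                      df = unname(bp$parameter),
                                      p = bp$p.value),
                 n = length(y), hc_type = hc_type, fit = fit),
            class = "RegressionResult")
}

#' Studentized Breusch-Pagan test
#'
#' Koenker's studentized variant: `n R^2` from regressing squared
#' residuals on the design, chi-square with df = number of regressors.
#'
#' @param fit an `lm` object, or a `RegressionResult`.
#' @return list with `statistic`, `df`, `p`.
#' @export
breusch_pagan <- function(fit) {
  if (inherits(fit, "RegressionResult")) return(fit$breusch_pagan)
  r <- stats::residuals(fit)
  if (stats::sd(r) <= 1e-10 * max(1e-8, stats::sd(stats::fitted(fit)))) {
    # constant residuals carry no heteroskedasticity signal
    k <- length(stats::coef(fit)) - 1
    return(list(statistic = 0, df = k, p = 1))
  }
  bp <- lmtest::bptest(fit)
  list(statistic = unname(bp$statistic), df = unname(bp$parameter),
       p = bp$p.value)
}

# exact density of the sample correlation r for n bivariate-normal
# observations with population correlation rho (Hotelling's form with a
# Gauss-hypergeometric series)
.hyp2f1 <- function(a, b, cc, x, tol = 1e-12, maxit = 2000) {
  term <- 1; s <- 1
  for (j in 0:(maxit - 1)) {
    term <- term * (a + j) * (b + j) / ((cc + j) * (j + 1)) * x
    s <- s + term
    if (abs(term) < tol * abs(s)) break
  }
  s
}

#' Exact density of the sample Pearson correlation
#'
#' @param r value(s) in (-1, 1).
#' @param n sample size (>= 4).
#' @param rho population correlation.
#' @return density value(s).
#' @export
dcorr <- function(r, n, rho) {
  lg <- lgamma(n - 1) - lgamma(n - 0.5) - 0.5 * log(2 * pi)
  vapply(r, function(ri) {
    if (abs(ri) >= 1) return(0)
    h <- .hyp2f1(0.5, 0.5, n - 0.5, (1 + rho * ri) / 2)
    exp(log(n - 2) + lg + (n - 1) / 2 * log1p(-rho^2) +
          (n - 4) / 2 * log1p(-ri^2) - (n - 1.5) * log1p(-rho * ri)) * h
  }, 0)
}

#' Exact power of the two-sided test of zero correlation
#'
#' @param n sample size.
#' @param rho true correlation.
#' @param alpha two-sided level.
#' @return power in `[0, 1]`.
#' @export
power_correlation <- function(n, rho, alpha = 0.05) {
  tc <- stats::qt(1 - alpha / 2, n - 2)
  rc <- tc / sqrt(n - 2 + tc^2)
  up <- stats::integrate(dcorr, rc, 1, n = n, rho = rho,
                         rel.tol = 1e-9)$value
  lo <- stats::integrate(dcorr, -1, -rc, n = n, rho = rho,
                         rel.tol = 1e-9)$value
  up + lo
}

#' Required sample size for the exact correlation test
#'
#' Smallest n at which the exact two-sided test of `rho = 0` attains the
#' target power when the true correlation is `rho`, using the exact
#' sampling distribution of r under bivariate normality (not the Fisher-z
#' approximation); bisection over n followed by a linear scan.
#'
#' @param rho true correlation (0 < rho < 1).
#' @param alpha two-sided level, default 0.05.
#' @param power target power, default 0.80.
#' @param n_cap search cap, default 1e6.
#' @return required sample size (integer).
#' @export
power_n_correlation <- function(rho = 0.10, alpha = 0.05, power = 0.80,
                                n_cap = 1e6) {
  stopifnot(rho > 0, rho < 1, alpha > 0, alpha < 1, power > 0, power < 1)
  lo <- 5
  hi <- 10
  while (power_correlation(hi, rho, alpha) < power) {
    lo <- hi
    hi <- hi * 2
    if (hi > n_cap) stop("required n exceeds cap (", n_cap, ")")
  }
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (power_correlation(mid, rho, alpha) >= power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}
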