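# Predictive-accuracy machinery: PSIS-LOO elpd, pairwise comparison with
# the two-SE rule, and per-participant WAIC.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Zhang-Stephens (2009) posterior-mean estimator for the generalized Pareto
# shape, with the weak prior regularisation used by standard PSIS
# implementations. `x` are positive exceedances. Returns shape xi (the
# "Pareto k") and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30 + floor(sqrt(n))
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  jj <- seq_len(m)
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  prof <- vapply(b, function(bb) {
    k <- -mean(log1p(-bb * x))
    if (!is.finite(k) || k <= 0) return(-Inf)
    n * (log(bb / k) + k - 1)
  }, 0)
  if (all(!is.finite(prof))) return(list(xi = Inf, sigma = NA_real_))
  w <- exp(prof - logsumexp(prof))
  bhat <- sum(b * w)
  k <- -mean(log1p(-bhat * x))      # Zhang-Stephens k = -xi
  sigma <- k / bhat
  xi <- -k
  # weakly informative prior pulling xi toward 0.5 (10 pseudo-observations)
  xi <- (n * xi + 10 * 0.5) / (n + 10)
  list(xi = xi, sigma = sigma)
}

qgpd <- function(p, u, sigma, xi) {
  if (abs(xi) < 1e-12) u + sigma * (-log1p(-p))
  else u + sigma / xi * ((1 - p)^(-xi) - 1)
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' Pareto-smoothed importance-sampling estimate of leave-one-out
#' cross-validated elpd from a posterior pointwise log-likelihood matrix.
#' For each observation the largest `ceiling(min(0.2 S, 3 sqrt(S)))`
#' importance ratios are replaced by the expected order statistics of a
#' generalized Pareto distribution fitted to the tail; observations with
#' tail-shape `pareto_k > 0.7` are flagged (not refit).
#'
#' @param loglik draws x observations matrix of log-likelihood values.
#' @return object of class `ElpdResult`: `elpd_estimate` (sum of pointwise
#'   elpd), `se` (`sqrt(N var(pointwise))`), `pointwise`, `pareto_k`
#'   (`-Inf` for degenerate zero-variance tails), `n_obs`, `n_draws`,
#'   `flagged` (indices with k > 0.7).
#' @export
psis_loo <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (any(!is.finite(loglik)))
    stop("log-likelihood matrix contains non-finite entries")
  S <- nrow(loglik); N <- ncol(loglik)
  if (S < 100)
    warning("fewer than 100 draws; PSIS tail fit is unreliable")
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  pointwise <- numeric(N)
  pareto_k <- numeric(N)
  for (j in seq_len(N)) {
    ll <- loglik[, j]
    lr <- -ll                      # log importance ratios (up to a constant)
    lr <- lr - max(lr)
    if (stats::sd(lr) < 1e-12 || M < 5) {
      pareto_k[j] <- -Inf
      lw <- lr
    } else {
      ord <- order(lr)
      tail_ix <- ord[(S - M + 1):S]
      u <- exp(lr[ord[S - M]])
      exc <- exp(lr[tail_ix]) - u
      if (max(exc) <= 0 || stats::sd(exc) < 1e-12) {
        pareto_k[j] <- -Inf
        lw <- lr
      } else {
        fit <- gpd_fit(exc)
        pareto_k[j] <- fit$xi
        lw <- lr
        if (is.finite(fit$xi)) {
          sm <- qgpd((seq_len(M) - 0.5) / M, u, fit$sigma, fit$xi)
          sm <- pmin(sm, exp(max(lr)))   # never exceed the raw maximum
          lw[tail_ix[order(exc)]] <- log(sm)
        }
      }
    }
    pointwise[j] <- logsumexp(lw + ll) - logsumexp(lw)
  }
  structure(list(elpd_estimate = sum(pointwise),
                 se = sqrt(N * stats::var(pointwise)),
                 pointwise = pointwise,
                 pareto_k = pareto_k,
                 n_obs = N, n_draws = S,
                 flagged = which(pareto_k > 0.7)),
            class = "ElpdResult")
}

#' @export
print.ElpdResult <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd = %.1f (SE = %.1f), N = %d, draws = %d\n",
              x$elpd_estimate, x$se, x$n_obs, x$n_draws))
  if (length(x$flagged))
    cat(length(x$flagged), "observation(s) with pareto_k > 0.7\n")
  invisible(x)
}

#' Compare two PSIS-LOO results with the two-SE rule
#'
#' The elpd difference `a - b` with its paired standard error from the
#' pointwise differences; model fits are deemed `"distinguishable"` iff
#' `|elpd_diff| >= 2 * se_diff`, else `"indistinguishable"`.
#'
#' @param a,b `ElpdResult` objects computed on the same observations in the
#'   same order.
#' @return list with `elpd_diff`, `se_diff`, `decision`.
#' @export
compare_elpd <- function(a, b) {
  stopifnot(inherits(a, "ElpdResult"), inherits(b, "ElpdResult"))
  if (a$n_obs != b$n_obs)
    stop("mismatched observation sets: ", a$n_obs, " vs ", b$n_obs)
  d <- a$pointwise - b$pointwise
  elpd_diff <- sum(d)
  se_diff <- sqrt(length(d) * stats::var(d))
  list(elpd_diff = elpd_diff, se_diff = se_diff,
       decision = if (abs(elpd_diff) > 0 && abs(elpd_diff) >= 2 * se_diff)
         "distinguishable" else "indistinguishable")
}

#' Per-participant WAIC
#'
#' `WAIC_i = -2 * sum_{j in i} (log mean_s p_sj - var_s log p_sj)` over the
#' participant's observations, with the variance over draws using the S-1
#' denominator. Lower values indicate better pointwise predictive fit.
#'
#' @param loglik draws x observations log-likelihood matrix.
#' @param participant_index length-N vector mapping observations to
#'   participants (factor, character or integer).
#' @return data.frame with `participant`, `waic`, `p_waic`, `elpd_waic`,
#'   `n_obs`; total WAIC is `sum(waic)`.
#' @export
participant_waic <- function(loglik, participant_index) {
  loglik <- as.matrix(loglik)
  if (any(!is.finite(loglik)))
    stop("log-likelihood matrix contains non-finite entries")
  f <- if (is.factor(participant_index)) participant_index
       else factor(participant_index, levels = unique(participant_index))
  if (length(f) != ncol(loglik))
    stop("participant_index length must equal the number of observations")
  if (any(table(f) == 0))
    stop("participant with zero observations: ",
         paste(levels(f)[table(f) == 0], collapse = ", "))
  ii <- as.integer(f)
  lpd <- apply(loglik, 2, logsumexp) - log(nrow(loglik))
  p_waic <- apply(loglik, 2, stats::var)     # S-1 denominator
  elpd_j <- lpd - p_waic
  out <- data.frame(
    participant = levels(f),
    waic = as.numeric(rowsum(-2 * elpd_j, ii)),
    p_waic = as.numeric(rowsum(p_waic, ii)),
    elpd_waic = as.numeric(rowsum(elpd_j, ii)),
    n_obs = as.integer(table(ii)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
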