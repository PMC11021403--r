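#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("tdisc_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed on chains split in half,
#' after rank-normalisation is *not* applied (classic split-R-hat).
#'
#' @param draws numeric matrix, iterations x chains.
#' @return scalar R-hat estimate.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  sp <- cbind(draws[seq_len(half), , drop = FALSE],
              draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  B <- nn * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size (bulk, autocorrelation-based)
#'
#' Standard combined-chain ESS using Geyer initial monotone positive
#' sequence truncation of FFT autocorrelations.
#'
#' @param draws numeric matrix, iterations x chains.
#' @return scalar ESS estimate.
#' @export
ess_bulk <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  if (n < 4) return(NA_real_)
  acov <- apply(draws, 2, function(x) {
    x <- x - mean(x)
    nf <- stats::nextn(2 * length(x))
    ft <- stats::fft(c(x, rep(0, nf - length(x))))
    ac <- Re(stats::fft(ft * Conj(ft), inverse = TRUE))[seq_along(x)]
    ac / length(x)
  })
  var_w <- mean(acov[1, ]) * n / (n - 1)
  var_b <- if (m > 1) stats::var(colMeans(draws)) else 0
  var_plus <- var_w * (n - 1) / n + var_b
  if (var_plus <= 0) return(n * m)
  rho <- 1 - (var_w - rowMeans(acov)) / var_plus
  # Geyer: sum of adjacent pairs while positive and monotone
  t_max <- 1
  s_prev <- Inf
  tau <- rho[1]
  k <- 2
  while (k + 1 <= min(n - 2, length(rho))) {
    s <- rho[k] + rho[k + 1]
    if (s < 0) break
    s <- min(s, s_prev)
    tau <- tau + 2 * s
    s_prev <- s
    k <- k + 2
  }
  max(1, min(n * m, n * m / (2 * tau - 1)))
}

#' Highest-density interval from posterior draws
#'
#' @param x numeric vector of draws.
#' @param prob interval mass, default 0.95.
#' @return length-2 vector (lower, upper).
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  k <- max(1, floor(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Adjusted Fisher-Pearson skewness
#'
#' The sample-size-corrected skewness `g1 * sqrt(n(n-1))/(n-2)`.
#'
#' @param x numeric vector (NA dropped).
#' @return scalar skewness.
#' @export
skewness_adj <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch via symmetric
# tridiagonal eigen decomposition).
gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (b - a) / 2 * x[ord] + (a + b) / 2,
       weights = (b - a) / 2 * w[ord])
}

# derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, k) {
  (as.integer(seed) %% 100000L) * 10000L + as.integer(k) %% 10000L
}
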