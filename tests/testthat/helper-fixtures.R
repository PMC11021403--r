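# shared fixtures, all generated in code

# small simulated study: hyperbolic agents on the default item set
make_choice_fixture <- function(n = 40, seed = 1, frame_effect = 0.4,
                                sd_frame_effect = 0.6, n_items = 27) {
  set.seed(seed)
  items <- generate_item_set(n_items = n_items, seed = seed)
  agents <- data.frame(
    participant_id = sprintf("p%03d", seq_len(n)),
    ln_k = stats::rnorm(n, -4.8, 1.8),
    tau = exp(stats::rnorm(n, log(0.5), 0.5)),
    frame_effect = stats::rnorm(n, frame_effect, sd_frame_effect),
    stringsAsFactors = FALSE)
  list(items = items, agents = agents,
       choices = simulate_choices(items, agents, seed = seed + 1))
}

# conjugate normal-mean model: analytic posterior and exact LOO predictive,
# used as the independent oracle for PSIS-LOO
normal_model_fixture <- function(n_obs = 20, n_draws = 1000, seed = 3,
                                 prior_sd = 10) {
  set.seed(seed)
  y <- stats::rnorm(n_obs, 1, 1)
  post <- function(yy) {
    v <- 1 / (length(yy) + 1 / prior_sd^2)
    list(mean = v * sum(yy), var = v)
  }
  p_full <- post(y)
  theta <- stats::rnorm(n_draws, p_full$mean, sqrt(p_full$var))
  loglik <- sapply(y, function(yj) stats::dnorm(yj, theta, 1, log = TRUE))
  # brute-force refit LOO: independent posterior draws per left-out point
  refit <- vapply(seq_along(y), function(j) {
    pj <- post(y[-j])
    th_j <- stats::rnorm(n_draws, pj$mean, sqrt(pj$var))
    log(mean(stats::dnorm(y[j], th_j, 1)))
  }, 0)
  # analytic leave-one-out predictive density (closed-form check)
  exact <- vapply(seq_along(y), function(j) {
    pj <- post(y[-j])
    stats::dnorm(y[j], pj$mean, sqrt(1 + pj$var), log = TRUE)
  }, 0)
  list(y = y, loglik = loglik, refit_loo = refit, exact_loo = exact)
}

# independent bivariate-normal rectangle probability by 1-D quadrature
# (oracle for the polychoric machinery; deliberately not pbvnorm)
bvn_rect_oracle <- function(lo1, hi1, lo2, hi2, rho) {
  f <- function(x) {
    stats::dnorm(x) *
      (stats::pnorm((hi2 - rho * x) / sqrt(1 - rho^2)) -
         stats::pnorm((lo2 - rho * x) / sqrt(1 - rho^2)))
  }
  stats::integrate(f, lo1, hi1, rel.tol = 1e-9)$value
}

# brute-force polychoric: grid search of the exact table likelihood using
# the quadrature oracle
polychoric_grid_oracle <- function(tab, step = 0.005) {
  a <- c(-Inf, stats::qnorm(cumsum(rowSums(tab)) / sum(tab))[-nrow(tab)], Inf)
  b <- c(-Inf, stats::qnorm(cumsum(colSums(tab)) / sum(tab))[-ncol(tab)], Inf)
  grid <- seq(-0.95, 0.95, by = step)
  ll <- vapply(grid, function(r) {
    s <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0)
        s <- s + tab[i, j] *
          log(max(bvn_rect_oracle(a[i], a[i + 1], b[j], b[j + 1], r), 1e-12))
    }
    s
  }, 0)
  grid[which.max(ll)]
}
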