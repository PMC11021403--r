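# Hierarchical Bayesian estimation of condition-specific log discount rates.
#
# Model (per discount family):
#   choice_j ~ Bernoulli(logistic(tau_i * (V_LL - V_SS)))
#   ln k_i = (ln k_{i,1}, ..., ln k_{i,C}) ~ MVN(mu, diag(sigma) R diag(sigma))
#   ln tau_i ~ Normal(mu_tau, sigma_tau)
#   mu_c ~ Normal(-4, 3); sigma_c ~ Half-Normal(2); R ~ LKJ(2)
#   mu_tau ~ Normal(0, 1); sigma_tau ~ Half-Normal(1)
#   quasi-hyperbolic adds logit(beta_i) ~ Normal(mu_b, sigma_b),
#   mu_b ~ Normal(1.4, 1), sigma_b ~ Half-Normal(1), and ln k parameterises
#   the delta component via delta = exp(-k).
#
# Sampling is adaptive Metropolis-within-Gibbs: vectorised random-walk
# updates for participant-level parameters (independent across participants
# given the hyperparameters, so all participants are updated in parallel),
# conjugate Gibbs draws for mu and mu_tau, and adaptive random-walk updates
# on unconstrained scales for the remaining hyperparameters.

.cond_levels <- function(condition_var) {
  if (condition_var == "frame") c("delay", "date")
  else c("small", "medium", "large")
}

#' Fit the hierarchical discounting model
#'
#' Estimates group- and participant-level log discount rates jointly across
#' the levels of a condition variable (time frame or magnitude band), with a
#' participant-level softmax inverse temperature shared across conditions.
#' Participant `ln k` vectors across conditions are modelled as correlated
#' multivariate normal, respecting the within-person pairing used by the
#' downstream paired analyses.
#'
#' @param data choice data.frame with columns `participant_id`, `ss_amount`,
#'   `ss_delay_days`, `ll_amount`, `ll_delay_days`, `frame`,
#'   `magnitude_band`, `choice` (0 = smaller-sooner, 1 = larger-later).
#' @param family discount family, see [subjective_value()].
#' @param condition_var `"frame"` (delay/date) or `"magnitude_band"`
#'   (small/medium/large); `"none"` fits a single condition (used for the
#'   separate per-version models).
#' @param mcmc list of sampler options: `chains` (default 4), `warmup`
#'   (1000), `iter` (1000 post-warmup draws per chain),
#'   `keep_participant_draws` (250 per chain, thinned, used for pointwise
#'   log-likelihood and point estimates).
#' @param seed integer seed; each chain derives its own stream.
#' @return object of class `td_fit` with hyperparameter draws, thinned
#'   participant-level draws, sampler diagnostics (split R-hat, bulk ESS),
#'   and a `converged` flag (max R-hat <= 1.05). Divergence count is always
#'   0 for this sampler type and is reported for interface completeness.
#' @export
fit_hierarchical <- function(data,
                             family = c("hyperbolic", "exponential",
                                        "quasi_hyperbolic"),
                             condition_var = c("frame", "magnitude_band",
                                               "none"),
                             mcmc = list(), seed = 1) {
  family <- match.arg(family)
  condition_var <- match.arg(condition_var)
  opts <- utils::modifyList(
    list(chains = 4L, warmup = 1000L, iter = 1000L,
         keep_participant_draws = 250L, rhat_limit = 1.05), mcmc)
  dat <- .check_choices(data)

  pid <- factor(dat$participant_id, levels = unique(dat$participant_id))
  if (condition_var == "none") {
    cond <- factor(rep("all", nrow(dat)))
  } else {
    cond <- factor(as.character(dat[[condition_var]]),
                   levels = .cond_levels(condition_var))
    if (anyNA(cond)) stop("unrecognised ", condition_var, " labels")
  }
  n <- nlevels(pid); C <- nlevels(cond)
  oi <- as.integer(pid); oc <- as.integer(cond)
  tab <- table(oi, oc)
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("participant ", levels(pid)[bad[1]],
         " has no observations in condition ", levels(cond)[bad[2]])
  }
  quasi <- family == "quasi_hyperbolic"
  # per-condition observation blocks, sorted by participant so that a
  # balanced design reduces group sums to a single .colSums call
  dsub <- lapply(seq_len(C), function(cc) {
    ix <- which(oc == cc)
    ix <- ix[order(oi[ix])]
    cnt <- tabulate(oi[ix], n)
    list(ix = ix, oi = oi[ix], d = dat[ix, , drop = FALSE],
         ss_a = dat$ss_amount[ix], ss_d = dat$ss_delay_days[ix],
         ll_a = dat$ll_amount[ix], ll_d = dat$ll_delay_days[ix],
         sgn = 2 * dat$choice[ix] - 1,
         ss_imm = all(dat$ss_delay_days[ix] == 0),
         m = if (all(cnt == cnt[1])) cnt[1] else NA_integer_)
  })

  # crude per-participant grid initialisation (tau fixed at 0.5)
  grid <- seq(-9, -0.2, length.out = 24)
  lnk0 <- matrix(0, n, C)
  for (cc in seq_len(C)) {
    d <- dsub[[cc]]
    ll <- vapply(grid, function(g)
      .gsum(.ll_blk(d, rep(g, length(d$ix)),
                    rep(log(0.5), length(d$ix)), family,
                    rep(2.2, length(d$ix))), d, n),
      numeric(n))
    lnk0[, cc] <- grid[max.col(ll, ties.method = "first")]
  }

  chains <- lapply(seq_len(opts$chains), function(ch)
    .run_chain(dsub, dat, oi, n, C, family, quasi, lnk0, opts,
               child_seed(seed, ch)))

  hyper_names <- colnames(chains[[1]]$hyper)
  hyper_arr <- array(
    unlist(lapply(chains, function(x) x$hyper)),
    dim = c(opts$iter, length(hyper_names), opts$chains),
    dimnames = list(NULL, hyper_names, NULL))
  diag_tab <- data.frame(
    parameter = hyper_names,
    mean = apply(hyper_arr, 2, mean),
    sd = apply(hyper_arr, 2, stats::sd),
    q2.5 = apply(hyper_arr, 2, stats::quantile, 0.025),
    q97.5 = apply(hyper_arr, 2, stats::quantile, 0.975),
    rhat = apply(hyper_arr, 2, function(m) split_rhat(m)),
    ess = apply(hyper_arr, 2, function(m) ess_bulk(m)),
    row.names = NULL)

  lnk_draws <- do.call(abind3, lapply(chains, function(x) x$lnk))
  ltau_draws <- do.call(rbind, lapply(chains, function(x) x$ltau))
  lbeta_draws <- if (quasi)
    do.call(rbind, lapply(chains, function(x) x$lbeta)) else NULL

  structure(list(
    family = family, condition_var = condition_var,
    conditions = levels(cond), participants = levels(pid),
    data = dat, obs_participant = oi, obs_condition = oc,
    hyper_draws = hyper_arr, diagnostics = diag_tab,
    lnk_draws = lnk_draws, ltau_draws = ltau_draws,
    lbeta_draws = lbeta_draws,
    divergences = 0L,
    converged = all(is.na(diag_tab$rhat) | diag_tab$rhat <= opts$rhat_limit),
    seed = seed, mcmc = opts), class = "td_fit")
}

# bind S x n matrices (or S x n x C arrays) along dim 1
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  if (length(d) == 2) return(do.call(rbind, xs))
  out <- array(0, c(sum(vapply(xs, function(x) dim(x)[1], 1L)), d[2], d[3]))
  at <- 0
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}


# fast per-observation log-likelihood on a prepared condition block
.ll_blk <- function(d, lnk_obs, ltau_obs, family, lbeta_obs = NULL) {
  k <- exp(lnk_obs)
  if (family == "hyperbolic") {
    v_ss <- if (d$ss_imm) d$ss_a else d$ss_a / (1 + k * d$ss_d)
    v_ll <- d$ll_a / (1 + k * d$ll_d)
  } else if (family == "exponential") {
    v_ss <- if (d$ss_imm) d$ss_a else d$ss_a * exp(-k * d$ss_d)
    v_ll <- d$ll_a * exp(-k * d$ll_d)
  } else {
    b <- stats::plogis(lbeta_obs)
    v_ss <- if (d$ss_imm) d$ss_a else d$ss_a * b * exp(-k * d$ss_d)
    v_ll <- d$ll_a * b * exp(-k * d$ll_d)
  }
  stats::plogis(d$sgn * exp(ltau_obs) * (v_ll - v_ss), log.p = TRUE)
}

# sum a per-observation vector by participant (fast path for balanced data)
.gsum <- function(x, d, n) {
  if (!is.na(d$m)) .colSums(x, d$m, n) else rowsum(x, d$oi)[, 1]
}

.run_chain <- function(dsub, dat, oi, n, C, family, quasi, lnk0, opts, seed) {
  set.seed(seed)
  warmup <- opts$warmup; iter <- opts$iter
  keep <- min(iter, opts$keep_participant_draws)
  keep_at <- unique(floor(seq(1, iter, length.out = keep)))

  # ---- state ----
  lnk <- lnk0 + matrix(stats::rnorm(n * C, 0, 0.3), n, C)
  ltau <- stats::rnorm(n, log(0.5), 0.2)
  lbeta <- if (quasi) stats::rnorm(n, 2.2, 0.2) else rep(0, n)
  mu <- colMeans(lnk)
  sigma <- pmax(apply(lnk, 2, stats::sd), 0.5)
  Rc <- diag(C) * 0.5 + 0.5  # mild positive correlation start
  if (C == 1) Rc <- matrix(1, 1, 1)
  mu_tau <- 0; sigma_tau <- 0.5
  mu_b <- 1.4; sigma_b <- 0.5

  upd_prec <- function() {
    Sg <- diag(sigma, C) %*% Rc %*% diag(sigma, C)
    Q <- solve(Sg)
    list(Q = Q, logdet = determinant(Sg)$modulus[1])
  }
  pr <- upd_prec()

  mvn_loglik <- function(lnk, mu, pr) {
    X <- sweep(lnk, 2, mu)
    -0.5 * (n * pr$logdet + sum((X %*% pr$Q) * X))
  }

  # cached per-observation log-likelihood per condition subset
  cur_ll <- lapply(seq_len(C), function(cc) {
    d <- dsub[[cc]]
    .ll_blk(d, lnk[d$oi, cc], ltau[d$oi], family, lbeta[d$oi])
  })

  # adaptive RW step sizes
  st <- list(lnk = rep(0.25, C), ltau = 0.25, lbeta = 0.4,
             lsig = rep(0.2, C), zr = rep(0.1, C * (C - 1) / 2),
             lsig_tau = 0.3, lsig_b = 0.3,
             mshift = rep(0.1, C), rescale = rep(0.05, C),
             tau_rescale = 0.05)
  acc <- rapply(st, function(x) x * 0, how = "replace")
  cnt <- 0
  rpairs <- if (C > 1) which(upper.tri(Rc), arr.ind = TRUE) else NULL

  hyper_names <- c(paste0("mu_lnk[", seq_len(C), "]"),
                   paste0("sigma_lnk[", seq_len(C), "]"),
                   if (C > 1) paste0("R[", rpairs[, 1], ",", rpairs[, 2], "]"),
                   "mu_tau", "sigma_tau",
                   if (quasi) c("mu_beta", "sigma_beta"))
  hyper <- matrix(NA_real_, iter, length(hyper_names),
                  dimnames = list(NULL, hyper_names))
  lnk_keep <- array(NA_real_, c(length(keep_at), n, C))
  ltau_keep <- matrix(NA_real_, length(keep_at), n)
  lbeta_keep <- if (quasi) matrix(NA_real_, length(keep_at), n)
  ki <- 0

  total <- warmup + iter
  for (it in seq_len(total)) {
    cnt <- cnt + 1
    ## participant ln k, one condition at a time (parallel across persons)
    for (cc in seq_len(C)) {
      d <- dsub[[cc]]
      step <- st$lnk[cc]
      delta <- stats::rnorm(n, 0, step)
      prop <- lnk[, cc] + delta
      ll_prop <- .ll_blk(d, prop[d$oi], ltau[d$oi], family, lbeta[d$oi])
      dll <- .gsum(ll_prop - cur_ll[[cc]], d, n)
      qx <- (sweep(lnk, 2, mu) %*% pr$Q[, cc])[, 1]
      dprior <- -(delta * qx + 0.5 * delta^2 * pr$Q[cc, cc])
      ok <- log(stats::runif(n)) < dll + dprior
      if (any(ok)) {
        lnk[ok, cc] <- prop[ok]
        sel <- ok[d$oi]
        cur_ll[[cc]][sel] <- ll_prop[sel]
      }
      acc$lnk[cc] <- acc$lnk[cc] + mean(ok)
    }
    ## participant log tau (affects every observation)
    delta <- stats::rnorm(n, 0, st$ltau)
    prop <- ltau + delta
    ll_prop <- lapply(seq_len(C), function(cc) {
      d <- dsub[[cc]]
      .ll_blk(d, lnk[d$oi, cc], prop[d$oi], family, lbeta[d$oi])
    })
    dll <- rep(0, n)
    for (cc in seq_len(C))
      dll <- dll + .gsum(ll_prop[[cc]] - cur_ll[[cc]], dsub[[cc]], n)
    dprior <- stats::dnorm(prop, mu_tau, sigma_tau, log = TRUE) -
      stats::dnorm(ltau, mu_tau, sigma_tau, log = TRUE)
    ok <- log(stats::runif(n)) < dll + dprior
    if (any(ok)) {
      ltau[ok] <- prop[ok]
      for (cc in seq_len(C)) {
        sel <- ok[dsub[[cc]]$oi]
        cur_ll[[cc]][sel] <- ll_prop[[cc]][sel]
      }
    }
    acc$ltau <- acc$ltau + mean(ok)
    ## participant logit beta (quasi-hyperbolic only)
    if (quasi) {
      delta <- stats::rnorm(n, 0, st$lbeta)
      prop <- lbeta + delta
      ll_prop <- lapply(seq_len(C), function(cc) {
        d <- dsub[[cc]]
        .ll_blk(d, lnk[d$oi, cc], ltau[d$oi], family, prop[d$oi])
      })
      dll <- rep(0, n)
      for (cc in seq_len(C))
        dll <- dll + .gsum(ll_prop[[cc]] - cur_ll[[cc]], dsub[[cc]], n)
      dprior <- stats::dnorm(prop, mu_b, sigma_b, log = TRUE) -
        stats::dnorm(lbeta, mu_b, sigma_b, log = TRUE)
      ok <- log(stats::runif(n)) < dll + dprior
      if (any(ok)) {
        lbeta[ok] <- prop[ok]
        for (cc in seq_len(C)) {
          sel <- ok[dsub[[cc]]$oi]
          cur_ll[[cc]][sel] <- ll_prop[[cc]][sel]
        }
      }
      acc$lbeta <- acc$lbeta + mean(ok)
    }
    ## group mean: conjugate Gibbs (prior Normal(-4, 3) per component)
    P <- n * pr$Q + diag(1 / 9, C)
    b <- pr$Q %*% colSums(lnk) + rep(-4 / 9, C)
    ch <- chol(P)
    mu <- drop(backsolve(ch, backsolve(ch, b, transpose = TRUE)) +
                 backsolve(ch, stats::rnorm(C)))
    ## joint translation move: shift mu_c and all lnk[, c] together
    ## (prior on deviations unchanged; acceptance from likelihood + mu prior)
    for (cc in seq_len(C)) {
      d <- dsub[[cc]]
      sh <- stats::rnorm(1, 0, st$mshift[cc])
      prop <- lnk[, cc] + sh
      ll_prop <- .ll_blk(d, prop[d$oi], ltau[d$oi], family, lbeta[d$oi])
      lr <- sum(ll_prop - cur_ll[[cc]]) +
        stats::dnorm(mu[cc] + sh, -4, 3, log = TRUE) -
        stats::dnorm(mu[cc], -4, 3, log = TRUE)
      if (log(stats::runif(1)) < lr) {
        lnk[, cc] <- prop
        mu[cc] <- mu[cc] + sh
        cur_ll[[cc]] <- ll_prop
        acc$mshift[cc] <- acc$mshift[cc] + 1
      }
    }
    ## joint rescale move: scale sigma_c and the lnk deviations together;
    ## the MVN log-determinant and the transformation Jacobian cancel, so
    ## acceptance uses only the likelihood and the sigma prior (log scale).
    ## Repeated per sweep: this is the only move that traverses the
    ## location-scale funnel, and its steps are necessarily small.
    for (rep_ in seq_len(3)) for (cc in seq_len(C)) {
      d <- dsub[[cc]]
      g <- exp(stats::rnorm(1, 0, st$rescale[cc]))
      prop <- mu[cc] + g * (lnk[, cc] - mu[cc])
      prop_sig <- sigma
      prop_sig[cc] <- g * sigma[cc]
      ll_prop <- .ll_blk(d, prop[d$oi], ltau[d$oi], family, lbeta[d$oi])
      lr <- sum(ll_prop - cur_ll[[cc]]) +
        stats::dnorm(prop_sig[cc], 0, 2, log = TRUE) -
        stats::dnorm(sigma[cc], 0, 2, log = TRUE) +
        log(prop_sig[cc]) - log(sigma[cc])
      if (log(stats::runif(1)) < lr) {
        lnk[, cc] <- prop
        sigma <- prop_sig
        pr <- upd_prec()
        cur_ll[[cc]] <- ll_prop
        acc$rescale[cc] <- acc$rescale[cc] + 1/3
      }
    }
    ## group SDs (half-normal(2) prior, RW on log scale)
    base <- mvn_loglik(lnk, mu, pr)
    for (cc in seq_len(C)) {
      prop_sig <- sigma
      prop_sig[cc] <- sigma[cc] * exp(stats::rnorm(1, 0, st$lsig[cc]))
      Sg <- diag(prop_sig, C) %*% Rc %*% diag(prop_sig, C)
      pr2 <- list(Q = solve(Sg), logdet = determinant(Sg)$modulus[1])
      lr <- mvn_loglik(lnk, mu, pr2) - base +
        stats::dnorm(prop_sig[cc], 0, 2, log = TRUE) -
        stats::dnorm(sigma[cc], 0, 2, log = TRUE) +
        log(prop_sig[cc]) - log(sigma[cc])
      if (log(stats::runif(1)) < lr) {
        sigma <- prop_sig; pr <- pr2; base <- mvn_loglik(lnk, mu, pr)
        acc$lsig[cc] <- acc$lsig[cc] + 1
      }
    }
    ## correlations (LKJ(2) prior, RW on atanh scale)
    if (C > 1) {
      for (p in seq_len(nrow(rpairs))) {
        i <- rpairs[p, 1]; j <- rpairs[p, 2]
        z <- atanh(Rc[i, j]) + stats::rnorm(1, 0, st$zr[p])
        R2 <- Rc; R2[i, j] <- R2[j, i] <- tanh(z)
        ev_ok <- min(eigen(R2, symmetric = TRUE, only.values = TRUE)$values) > 1e-8
        if (ev_ok) {
          Sg <- diag(sigma, C) %*% R2 %*% diag(sigma, C)
          pr2 <- list(Q = solve(Sg), logdet = determinant(Sg)$modulus[1])
          # LKJ(2) density plus Jacobian of atanh reparameterisation
          lr <- mvn_loglik(lnk, mu, pr2) - base +
            determinant(R2)$modulus[1] - determinant(Rc)$modulus[1] +
            log(1 - R2[i, j]^2) - log(1 - Rc[i, j]^2)
          if (log(stats::runif(1)) < lr) {
            Rc <- R2; pr <- pr2; base <- mvn_loglik(lnk, mu, pr)
            acc$zr[p] <- acc$zr[p] + 1
          }
        }
      }
    }
    ## joint rescale of sigma_tau with the ltau deviations
    {
      g <- exp(stats::rnorm(1, 0, st$tau_rescale))
      prop <- mu_tau + g * (ltau - mu_tau)
      ll_prop <- lapply(seq_len(C), function(cc) {
        d <- dsub[[cc]]
        .ll_blk(d, lnk[d$oi, cc], prop[d$oi], family, lbeta[d$oi])
      })
      lr <- sum(unlist(ll_prop)) - sum(unlist(cur_ll)) +
        stats::dnorm(g * sigma_tau, 0, 1, log = TRUE) -
        stats::dnorm(sigma_tau, 0, 1, log = TRUE) + log(g)
      if (log(stats::runif(1)) < lr) {
        ltau <- prop
        sigma_tau <- g * sigma_tau
        cur_ll <- ll_prop
        acc$tau_rescale <- acc$tau_rescale + 1
      }
    }
    ## tau hyperparameters
    v_post <- 1 / (n / sigma_tau^2 + 1)
    mu_tau <- stats::rnorm(1, v_post * sum(ltau) / sigma_tau^2, sqrt(v_post))
    prop_s <- sigma_tau * exp(stats::rnorm(1, 0, st$lsig_tau))
    lr <- sum(stats::dnorm(ltau, mu_tau, prop_s, log = TRUE)) -
      sum(stats::dnorm(ltau, mu_tau, sigma_tau, log = TRUE)) +
      stats::dnorm(prop_s, 0, 1, log = TRUE) -
      stats::dnorm(sigma_tau, 0, 1, log = TRUE) +
      log(prop_s) - log(sigma_tau)
    if (log(stats::runif(1)) < lr) {
      sigma_tau <- prop_s; acc$lsig_tau <- acc$lsig_tau + 1
    }
    if (quasi) {
      v_post <- 1 / (n / sigma_b^2 + 1)
      mu_b <- stats::rnorm(1, v_post * (sum(lbeta) / sigma_b^2 + 1.4),
                           sqrt(v_post))
      prop_s <- sigma_b * exp(stats::rnorm(1, 0, st$lsig_b))
      lr <- sum(stats::dnorm(lbeta, mu_b, prop_s, log = TRUE)) -
        sum(stats::dnorm(lbeta, mu_b, sigma_b, log = TRUE)) +
        stats::dnorm(prop_s, 0, 1, log = TRUE) -
        stats::dnorm(sigma_b, 0, 1, log = TRUE) +
        log(prop_s) - log(sigma_b)
      if (log(stats::runif(1)) < lr) {
        sigma_b <- prop_s; acc$lsig_b <- acc$lsig_b + 1
      }
    }
    ## adaptation during warmup
    if (it <= warmup && cnt == 25) {
      tune <- function(step, rate, target = 0.35)
        pmin(5, pmax(1e-3, step * exp((rate - target))))
      st$lnk <- tune(st$lnk, acc$lnk / cnt, 0.44)
      st$ltau <- tune(st$ltau, acc$ltau / cnt, 0.44)
      if (quasi) st$lbeta <- tune(st$lbeta, acc$lbeta / cnt, 0.44)
      st$lsig <- tune(st$lsig, acc$lsig / cnt)
      if (C > 1) st$zr <- tune(st$zr, acc$zr / cnt)
      st$lsig_tau <- tune(st$lsig_tau, acc$lsig_tau / cnt)
      st$mshift <- tune(st$mshift, acc$mshift / cnt)
      st$rescale <- tune(st$rescale, acc$rescale / cnt)
      st$tau_rescale <- tune(st$tau_rescale, acc$tau_rescale / cnt)
      if (quasi) st$lsig_b <- tune(st$lsig_b, acc$lsig_b / cnt)
      acc <- rapply(acc, function(x) x * 0, how = "replace")
      cnt <- 0
    }
    ## record
    if (it > warmup) {
      s <- it - warmup
      hyper[s, ] <- c(mu, sigma,
                      if (C > 1) Rc[rpairs],
                      mu_tau, sigma_tau,
                      if (quasi) c(mu_b, sigma_b))
      if (ki < length(keep_at) && s == keep_at[ki + 1]) {
        ki <- ki + 1
        lnk_keep[ki, , ] <- lnk
        ltau_keep[ki, ] <- ltau
        if (quasi) lbeta_keep[ki, ] <- lbeta
      }
    }
  }
  list(hyper = hyper, lnk = lnk_keep, ltau = ltau_keep,
       lbeta = if (quasi) lbeta_keep)
}

#' Pointwise log-likelihood matrix of a fitted model
#'
#' Computes the draws x observations matrix of Bernoulli log-likelihoods
#' from the stored (thinned) participant-level draws, the input expected by
#' [psis_loo()] and [participant_waic()].
#'
#' @param fit a `td_fit` object.
#' @return matrix, kept draws x observations; attribute
#'   `participant_index` maps observations to participants.
#' @export
pointwise_loglik <- function(fit) {
  stopifnot(inherits(fit, "td_fit"))
  S <- dim(fit$lnk_draws)[1]
  N <- nrow(fit$data)
  oi <- fit$obs_participant; oc <- fit$obs_condition
  out <- matrix(NA_real_, S, N)
  for (s in seq_len(S)) {
    lnk_obs <- fit$lnk_draws[s, , ][cbind(oi, oc)]
    lb <- if (!is.null(fit$lbeta_draws)) fit$lbeta_draws[s, oi] else NULL
    out[s, ] <- .obs_loglik(fit$data, lnk_obs, fit$ltau_draws[s, oi],
                            fit$family, lb)
  }
  attr(out, "participant_index") <- oi
  attr(out, "participant_id") <- fit$participants[oi]
  out
}

#' Participant-level point estimates and derived effects
#'
#' Point estimates are posterior means of participant-level `ln k` per
#' condition. For frame models the date/delay effect is
#' `dde = ln k(delay) - ln k(date)`; for magnitude models the magnitude
#' effect is `me = ln k(small) - ln k(large)`. Per-participant WAIC is
#' attached as a model-fit index (lower is better).
#'
#' @param fit a `td_fit` object.
#' @return data.frame with one row per participant: `participant_id`,
#'   `lnk_<condition>` columns, `tau`, `waic`, and `dde` or `me`.
#' @export
point_estimates <- function(fit) {
  stopifnot(inherits(fit, "td_fit"))
  est <- apply(fit$lnk_draws, c(2, 3), mean)
  colnames(est) <- paste0("lnk_", fit$conditions)
  out <- data.frame(participant_id = fit$participants, est,
                    tau = exp(colMeans(fit$ltau_draws)),
                    stringsAsFactors = FALSE)
  ll <- pointwise_loglik(fit)
  out$waic <- participant_waic(ll, attr(ll, "participant_index"))$waic
  if (all(c("lnk_delay", "lnk_date") %in% names(out)))
    out$dde <- out$lnk_delay - out$lnk_date
  if (all(c("lnk_small", "lnk_large") %in% names(out)))
    out$me <- out$lnk_small - out$lnk_large
  rownames(out) <- NULL
  out
}

#' @export
print.td_fit <- function(x, ...) {
  cat("Hierarchical discounting fit (", x$family, ", conditions: ",
      paste(x$conditions, collapse = "/"), ")\n", sep = "")
  cat(length(x$participants), "participants,", nrow(x$data), "observations;",
      x$mcmc$chains, "chains x", x$mcmc$iter, "draws\n")
  cat("converged:", x$converged,
      "(max split R-hat =", round(max(x$diagnostics$rhat, na.rm = TRUE), 3),
      ")\n\n")
  print(x$diagnostics, digits = 3)
  invisible(x)
}
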