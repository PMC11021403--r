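#' Subjective value of a delayed reward
#'
#' Discounted value of `amount` received after `delay_days` under one of
#' three discount families:
#' \itemize{
#'   \item hyperbolic: `V = A / (1 + k D)`
#'   \item exponential: `V = A exp(-k D)`
#'   \item quasi-hyperbolic (beta-delta): `V = A` at `D = 0`, else
#'     `V = A * beta * delta^D`
#' }
#'
#' @param amount reward amount (> 0), USD.
#' @param delay_days delay in days (>= 0).
#' @param params list with `k` (per day, >= 0) for hyperbolic/exponential;
#'   `beta` in (0, 1] and `delta` in (0, 1] for quasi-hyperbolic.
#' @param family one of `"hyperbolic"`, `"exponential"`, `"quasi_hyperbolic"`.
#' @return subjective value, same units as `amount`.
#' @examples
#' subjective_value(25, 19, list(k = 1 / 19), "hyperbolic")  # 12.5
#' @export
subjective_value <- function(amount, delay_days, params,
                             family = c("hyperbolic", "exponential",
                                        "quasi_hyperbolic")) {
  family <- match.arg(family)
  if (any(amount <= 0)) stop("amount must be positive")
  if (any(delay_days < 0)) stop("delay_days must be non-negative")
  switch(family,
    hyperbolic = {
      if (any(params$k < 0)) stop("k must be non-negative")
      amount / (1 + params$k * delay_days)
    },
    exponential = {
      if (any(params$k < 0)) stop("k must be non-negative")
      amount * exp(-params$k * delay_days)
    },
    quasi_hyperbolic = {
      beta <- params$beta; delta <- params$delta
      if (any(beta <= 0 | beta > 1) || any(delta <= 0 | delta > 1))
        stop("quasi-hyperbolic needs beta, delta in (0, 1]")
      # discrete convention: the present bias beta applies only to delayed
      # outcomes, so V = A exactly at D = 0
      ifelse(delay_days == 0, amount, amount * beta * delta^delay_days)
    })
}

#' Probability of choosing the larger-later option
#'
#' Softmax (logistic) choice rule in the subjective-value difference:
#' `P(LL) = logistic(tau * (V_LL - V_SS))` with inverse temperature
#' `tau > 0`.
#'
#' @param item data.frame/list with `ss_amount`, `ss_delay_days`,
#'   `ll_amount`, `ll_delay_days` (vectorised).
#' @param params list with `tau` plus the family parameters of
#'   [subjective_value()].
#' @param family discount family, see [subjective_value()].
#' @return probability in (0, 1) of choosing the larger-later reward.
#' @export
choice_probability <- function(item, params, family = "hyperbolic") {
  if (any(params$tau <= 0)) stop("tau must be positive")
  v_ss <- subjective_value(item$ss_amount, item$ss_delay_days, params, family)
  v_ll <- subjective_value(item$ll_amount, item$ll_delay_days, params, family)
  stats::plogis(params$tau * (v_ll - v_ss))
}

# Vectorised Bernoulli log-likelihood of observed choices.
# lnk, ltau (and for quasi, lbeta = logit beta) are per-observation vectors.
# For the quasi family lnk parameterises delta via delta = exp(-exp(lnk)),
# i.e. exp(lnk) is the daily exponential rate of the delta component.
.obs_loglik <- function(dat, lnk, ltau, family, lbeta = NULL) {
  k <- exp(lnk)
  v_ss <- switch(family,
    hyperbolic = dat$ss_amount / (1 + k * dat$ss_delay_days),
    exponential = dat$ss_amount * exp(-k * dat$ss_delay_days),
    quasi_hyperbolic = {
      b <- stats::plogis(lbeta)
      ifelse(dat$ss_delay_days == 0, dat$ss_amount,
             dat$ss_amount * b * exp(-k * dat$ss_delay_days))
    })
  v_ll <- switch(family,
    hyperbolic = dat$ll_amount / (1 + k * dat$ll_delay_days),
    exponential = dat$ll_amount * exp(-k * dat$ll_delay_days),
    quasi_hyperbolic =
      dat$ll_amount * stats::plogis(lbeta) * exp(-k * dat$ll_delay_days))
  eta <- exp(ltau) * (v_ll - v_ss)
  # log P(choice): plogis on log scale for numerical stability
  ifelse(dat$choice == 1, stats::plogis(eta, log.p = TRUE),
         stats::plogis(-eta, log.p = TRUE))
}
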