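test_that("subjective value matches the three discount families", {
  # zero delay returns the full amount in every family
  expect_equal(subjective_value(25, 0, list(k = 0.3), "hyperbolic"), 25)
  expect_equal(subjective_value(25, 0, list(k = 0.3), "exponential"), 25)
  expect_equal(subjective_value(25, 0, list(beta = 0.5, delta = 0.9),
                                "quasi_hyperbolic"), 25)
  # kD = 1 halves the hyperbolic value
  expect_equal(subjective_value(25, 19, list(k = 1 / 19), "hyperbolic"), 12.5)
  # beta-delta by hand: 10 * 0.8 * 1^5
  expect_equal(subjective_value(10, 5, list(beta = 0.8, delta = 1),
                                "quasi_hyperbolic"), 8)
  expect_equal(subjective_value(10, 3, list(k = 0.1), "exponential"),
               10 * exp(-0.3))
  expect_error(subjective_value(10, 3, list(k = -0.1), "hyperbolic"), "k")
  expect_error(subjective_value(10, -3, list(k = 0.1), "hyperbolic"), "delay")
  expect_error(subjective_value(10, 3, list(beta = 1.2, delta = 0.9),
                                "quasi_hyperbolic"), "beta")
})

test_that("softmax choice rule is calibrated and monotone", {
  # indifference: the $14-now vs $25-in-19-days item at its k*
  item <- list(ss_amount = 14, ss_delay_days = 0, ll_amount = 25,
               ll_delay_days = 19)
  kstar <- item_indifference_k(item)
  expect_equal(choice_probability(item, list(k = kstar, tau = 1)), 0.5)
  # logistic algebra: tau = 1, value difference ln 3 -> 0.75
  it2 <- list(ss_amount = 5, ss_delay_days = 0, ll_amount = 5 + log(3),
              ll_delay_days = 0)
  expect_equal(choice_probability(it2, list(k = 0.1, tau = 1)), 0.75)
  # deterministic limit for a patient agent
  expect_gt(choice_probability(item, list(k = kstar / 100, tau = 1e4)),
            1 - 1e-6)
  # strictly increasing in the value difference
  ll_amts <- seq(15, 40, by = 1)
  ps <- vapply(ll_amts, function(a)
    choice_probability(list(ss_amount = 14, ss_delay_days = 0,
                            ll_amount = a, ll_delay_days = 19),
                       list(k = 0.04, tau = 0.5)), 0)
  expect_true(all(diff(ps) > 0))
  expect_error(choice_probability(item, list(k = 0.1, tau = 0)), "tau")
})

test_that("likelihood is symmetric under option relabeling", {
  # choosing LL in an item equals choosing SS after swapping the options
  set.seed(5)
  for (i in 1:20) {
    item <- list(ss_amount = runif(1, 5, 20), ss_delay_days = 0,
                 ll_amount = runif(1, 25, 85), ll_delay_days = sample(5:180, 1))
    swapped <- list(ss_amount = item$ll_amount,
                    ss_delay_days = item$ll_delay_days,
                    ll_amount = item$ss_amount, ll_delay_days = 0)
    pars <- list(k = exp(rnorm(1, -4.8, 1.8)), tau = exp(rnorm(1, 0, 0.5)))
    p_ll <- choice_probability(item, pars)
    p_swapped <- choice_probability(swapped, pars)
    expect_equal(log(p_ll), log(1 - p_swapped), tolerance = 1e-6)
  }
})

test_that("hierarchical fit recovers individuals and handles degenerates", {
  fx <- make_choice_fixture(n = 40, seed = 21)
  # force one participant to always take the larger-later option
  all_ll <- fx$choices$participant_id == "p001"
  fx$choices$choice[all_ll] <- 1L
  fit <- fit_hierarchical(fx$choices, "hyperbolic", "frame",
                          mcmc = list(chains = 2, warmup = 400, iter = 400),
                          seed = 2)
  est <- point_estimates(fit)
  # derived effects are exact differences of point estimates
  expect_equal(est$dde, est$lnk_delay - est$lnk_date)
  expect_true(all(is.finite(est$waic)))
  # the all-LL participant shrinks to the patient end without an error
  expect_lt(est$lnk_delay[est$participant_id == "p001"],
            mean(est$lnk_delay))
  # individual estimates track the generating parameters
  others <- est$participant_id != "p001"
  expect_gt(cor(est$lnk_delay[others], fx$agents$ln_k[others]), 0.8)
  # pointwise log-likelihood contract
  ll <- pointwise_loglik(fit)
  expect_true(all(ll <= 0))
  expect_equal(ncol(ll), nrow(fx$choices))
  # grid maximum-likelihood oracle: deviations from the group mean agree in
  # sign for clearly separated participants (fixed tau grid ML per person)
  one <- fx$choices[fx$choices$frame == "delay", ]
  grid <- seq(-9, -0.5, length.out = 60)
  ml <- vapply(split(one, one$participant_id)[unique(one$participant_id)],
               function(d) {
    lls <- vapply(grid, function(g) {
      p <- choice_probability(d, list(k = exp(g), tau = 0.5))
      sum(ifelse(d$choice == 1, log(p), log(1 - p)))
    }, 0)
    grid[which.max(lls)]
  }, 0)
  dev_ml <- ml - mean(ml)
  dev_post <- est$lnk_delay - mean(est$lnk_delay)
  sel <- abs(dev_ml) > 1
  expect_true(mean(sign(dev_ml[sel]) == sign(dev_post[sel])) > 0.95)
})

test_that("fit validates conditions and labels missing cells", {
  fx <- make_choice_fixture(n = 6, seed = 31, n_items = 9)
  broken <- fx$choices[!(fx$choices$participant_id == "p002" &
                           fx$choices$frame == "date"), ]
  expect_error(
    fit_hierarchical(broken, "hyperbolic", "frame",
                     mcmc = list(chains = 1, warmup = 10, iter = 10)),
    "p002.*date")
})

test_that("prior predictive choices are non-degenerate", {
  set.seed(77)
  items <- generate_item_set(seed = 8)
  p_ll <- replicate(20, {
    mu <- rnorm(1, -4, 3); sg <- abs(rnorm(1, 0, 2))
    mu_t <- rnorm(1, 0, 1); sg_t <- abs(rnorm(1, 0, 1))
    n <- 25
    agents <- data.frame(participant_id = sprintf("a%02d", 1:n),
                         ln_k = rnorm(n, mu, sg),
                         tau = exp(rnorm(n, mu_t, sg_t)))
    mean(simulate_choices(items, agents, seed = sample.int(1e6, 1))$choice)
  })
  expect_gt(mean(p_ll), 0.05)
  expect_lt(mean(p_ll), 0.95)
})
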