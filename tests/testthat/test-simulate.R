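test_that("choices are exchangeable across frames under a null frame effect", {
  items <- generate_item_set(seed = 14)
  rejections <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 60
    agents <- data.frame(participant_id = sprintf("a%03d", 1:n),
                         ln_k = rnorm(n, -4.8, 1.8),
                         tau = exp(rnorm(n, log(0.5), 0.5)))
    ch <- simulate_choices(items, agents, frame_effect = 0, seed = s + 50)
    tab <- table(ch$frame, ch$choice)
    stats::chisq.test(tab)$p.value < 0.01
  }, TRUE)
  expect_lte(sum(rejections), 1)
})

test_that("a positive frame effect raises patience in the date frame", {
  items <- generate_item_set(seed = 14)
  set.seed(9)
  n <- 150
  agents <- data.frame(participant_id = sprintf("a%03d", 1:n),
                       ln_k = rnorm(n, -4.8, 1.5),
                       tau = exp(rnorm(n, log(0.5), 0.3)))
  ch <- simulate_choices(items, agents, frame_effect = 1.0, seed = 10)
  p_date <- mean(ch$choice[ch$frame == "date"])
  p_delay <- mean(ch$choice[ch$frame == "delay"])
  expect_gt(p_date, p_delay + 0.02)  # lower ln k under dates -> more LL
  # deterministic preference limit
  pat <- data.frame(participant_id = "z", ln_k = -12, tau = 1e4)
  ch2 <- simulate_choices(items, pat, seed = 3)
  expect_true(all(ch2$choice == 1))
  # reproducibility and validation
  expect_identical(simulate_choices(items, agents, seed = 4)$choice,
                   simulate_choices(items, agents, seed = 4)$choice)
  bad <- agents; bad$tau[2] <- -1
  expect_error(simulate_choices(items, bad, seed = 1), "a002")
})

test_that("questionnaire generator respects the factor model", {
  # null loadings: responses independent of the factors
  L0 <- matrix(0, 6, 2)
  th <- replicate(6, qnorm(c(0.3, 0.6, 0.85)), simplify = FALSE)
  q <- simulate_questionnaires(2000, L0, diag(2), th, seed = 5)
  rs <- abs(cor(q$responses, q$factor_scores))
  expect_true(all(rs < 0.06))
  # perfect indicator: response is the discretized factor score
  L1 <- matrix(1, 1, 1)
  q1 <- simulate_questionnaires(500, L1, diag(1), th[1], seed = 6)
  expect_identical(as.integer(q1$responses),
                   findInterval(as.numeric(q1$factor_scores), th[[1]]))
  # Heywood input rejected
  expect_error(
    simulate_questionnaires(50, matrix(c(0.9, 0.9), 1, 2),
                            matrix(c(1, 0.5, 0.5, 1), 2), th[1], seed = 1),
    "Heywood|communality")
  expect_error(
    simulate_questionnaires(50, L0, diag(2),
                            replicate(6, c(1, 0.5, 2), simplify = FALSE)),
    "increasing")
})

test_that("oblique factor structure is recovered at generation scale", {
  spec <- default_questionnaire_spec()
  phi <- matrix(0.4, 3, 3); diag(phi) <- 1
  q <- simulate_questionnaires(2000, spec$loadings, phi, spec$thresholds,
                               seed = 12)
  expect_equal(unname(cor(q$factor_scores)[upper.tri(phi)]),
               rep(0.4, 3), tolerance = 0.05)
  # polychoric round-trip on a handful of strong AD items
  ad <- which(spec$codebook$scale == "DASS")[1:6]
  implied <- (spec$loadings %*% phi %*% t(spec$loadings))[ad, ad]
  for (pair in list(c(1, 2), c(3, 5), c(2, 6))) {
    r_hat <- polychoric_ml(q$responses[, ad[pair[1]]],
                           q$responses[, ad[pair[2]]])
    expect_lt(abs(r_hat - implied[pair[1], pair[2]]), 0.06)
  }
})

test_that("generate_cohort bundles a coherent synthetic study", {
  cfg <- list(n = 400L)
  syn <- generate_cohort(cfg, seed = 30)
  expect_equal(nrow(syn$choices), 400 * 54)
  expect_equal(nrow(syn$cohort), 400)
  expect_equal(sum(grepl("_", names(syn$cohort))) >= 176, TRUE)
  # attention-check flag near the configured rate (binomial 99% interval)
  rate <- mean(syn$cohort$attention_check_fail)
  expect_lt(abs(rate - 68 / 800), 3 * sqrt(0.085 * 0.915 / 400))
  # ln k correlates with the factors at the configured effect size
  r_obs <- cor(syn$truth$agents$ln_k, syn$truth$factor_scores)
  expect_true(all(abs(r_obs - 0.10) < 0.14))  # Fisher-z 95% at n=400
  # null effect size kills the association
  syn0 <- generate_cohort(list(n = 400L,
                               factor_lnk_r = c(AD = 0, IIO = 0, CIT = 0)),
                          seed = 31)
  r0 <- cor(syn0$truth$agents$ln_k, syn0$truth$factor_scores)
  expect_true(all(abs(r0) < 0.13))
  # determinism and config validation
  syn_b <- generate_cohort(cfg, seed = 30)
  expect_identical(syn$choices$choice, syn_b$choices$choice)
  expect_error(generate_cohort(list(frac_fail = 0.1)), "frac_fail")
  expect_error(generate_cohort(list(fraction_fail = 1.2)), "fraction_fail")
})
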