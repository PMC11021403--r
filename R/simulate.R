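# Synthetic-cohort generator: hyperbolic (or other family) softmax agents
# completing an MCQ-style task in two time frames, plus ordinal questionnaire
# responses from an oblique 3-factor measurement model and basic covariates.

#' Simulate binary intertemporal choices for a set of agents
#'
#' Each agent chooses between the smaller-immediate and larger-later option
#' of every item with probability from [choice_probability()]. Date-frame
#' items use `ln k(date) = ln k(delay) - frame_effect`; magnitude bands
#' shift `ln k` by `+magnitude_effect/2` (small), `0` (medium),
#' `-magnitude_effect/2` (large), so the small-minus-large contrast equals
#' the configured magnitude effect.
#'
#' @param items item set from [generate_item_set()] (both frames).
#' @param agents data.frame with `participant_id`, `ln_k` (delay-frame log
#'   discount rate), `tau` (> 0); optional per-agent `frame_effect` and
#'   `magnitude_effect` columns override the global arguments; for the
#'   quasi-hyperbolic family, `beta` and `delta`.
#' @param frame_effect group reduction in `ln k` under date framing.
#' @param magnitude_effect group small-minus-large difference in `ln k`.
#' @param family discount family of the generating agents.
#' @param seed integer seed.
#' @return long data.frame: one row per participant x item x frame with the
#'   item columns plus `participant_id` and `choice` (1 = larger-later).
#' @export
simulate_choices <- function(items, agents, frame_effect = 0,
                             magnitude_effect = 0, family = "hyperbolic",
                             seed = 1) {
  need <- c("participant_id", "ln_k", "tau")
  miss <- setdiff(need, names(agents))
  if (length(miss))
    stop("agents table lacks column(s): ", paste(miss, collapse = ", "))
  for (v in c("ln_k", "tau")) {
    bad <- which(!is.finite(agents[[v]]) | (v == "tau" & agents[[v]] <= 0))
    if (length(bad))
      stop("participant ", agents$participant_id[bad[1]],
           ": invalid ", v, " for condition-level simulation")
  }
  n <- nrow(agents)
  ni <- nrow(items)
  set.seed(seed)
  d <- items[rep(seq_len(ni), times = n), , drop = FALSE]
  ai <- rep(seq_len(n), each = ni)
  d$participant_id <- agents$participant_id[ai]

  fe <- if ("frame_effect" %in% names(agents))
    agents$frame_effect[ai] else rep(frame_effect, nrow(d))
  me <- if ("magnitude_effect" %in% names(agents))
    agents$magnitude_effect[ai] else rep(magnitude_effect, nrow(d))
  band_shift <- c(small = 0.5, medium = 0, large = -0.5)[d$magnitude_band] * me
  lnk <- agents$ln_k[ai] - fe * (d$frame == "date") + band_shift

  params <- list(k = exp(lnk), tau = agents$tau[ai])
  if (family == "quasi_hyperbolic") {
    if (!all(c("beta", "delta") %in% names(agents)))
      stop("quasi-hyperbolic agents need beta and delta columns")
    params$beta <- agents$beta[ai]
    # magnitude/frame shifts act on the delta rate: delta = exp(-k)
    params$delta <- exp(-exp(lnk))
  }
  p <- choice_probability(d, params, family)
  d$choice <- stats::rbinom(nrow(d), 1, p)
  rownames(d) <- NULL
  d[, c("participant_id", setdiff(names(d), "participant_id"))]
}

#' Simulate ordinal questionnaire responses from an oblique factor model
#'
#' Latent item values are `loadings %*% factor + e`, with unique normal
#' noise of variance `1 - communality` (communality from the oblique model,
#' `diag(L Phi L')`), discretised by per-item increasing thresholds into
#' ordinal categories `0 .. K`.
#'
#' @param n number of respondents (ignored when `factor_scores` given).
#' @param loadings items x factors loading matrix.
#' @param factor_corr factor correlation matrix (symmetric PD).
#' @param thresholds list (length = items) of strictly increasing numeric
#'   cutpoints on the latent scale.
#' @param seed integer seed.
#' @param factor_scores optional n x factors matrix of latent scores to
#'   condition on (used to link questionnaires to other agent parameters).
#' @return list with `responses` (n x items integer matrix) and
#'   `factor_scores` (the latent scores used).
#' @export
simulate_questionnaires <- function(n, loadings, factor_corr, thresholds,
                                    seed = 1, factor_scores = NULL) {
  loadings <- as.matrix(loadings)
  p <- nrow(loadings); m <- ncol(loadings)
  if (!isSymmetric(unname(factor_corr)) ||
      min(eigen(factor_corr, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop_config("factor_corr must be symmetric positive definite")
  if (length(thresholds) != p)
    stop_config("need one threshold vector per item")
  if (any(!vapply(thresholds, function(t) all(diff(t) > 0), TRUE)))
    stop_config("thresholds must be strictly increasing per item")
  comm <- rowSums((loadings %*% factor_corr) * loadings)
  if (any(comm > 1 + 1e-12))
    stop("communality > 1 (Heywood input) for item(s) ",
         paste(which(comm > 1 + 1e-12), collapse = ", "))
  set.seed(seed)
  if (is.null(factor_scores))
    factor_scores <- MASS::mvrnorm(n, rep(0, m), factor_corr)
  factor_scores <- as.matrix(factor_scores)
  n <- nrow(factor_scores)
  latent <- factor_scores %*% t(loadings) +
    matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(pmax(0, 1 - comm)), p)
  resp <- vapply(seq_len(p),
                 function(j) findInterval(latent[, j], thresholds[[j]]),
                 integer(n))
  colnames(resp) <- rownames(loadings) %||% paste0("item", seq_len(p))
  list(responses = resp, factor_scores = factor_scores)
}

#' Default questionnaire measurement spec (176 items, 3 oblique factors)
#'
#' A synthetic codebook emulating the structure (not the content) of a
#' transdiagnostic battery: eight scales totalling 176 four-point (0-3)
#' items, each with a dominant loading on one of three oblique factors
#' (AD, IIO, CIT), small cross-loadings, and positively skewed thresholds.
#'
#' @param seed seed for loading/threshold jitter.
#' @return list with `loadings` (176 x 3), `thresholds` (list of cutpoints),
#'   `codebook` (data.frame: item, scale, factor, n_categories),
#'   `factor_corr` (3 x 3 default factor correlations).
#' @export
default_questionnaire_spec <- function(seed = 20) {
  scales <- data.frame(
    scale = c("DASS", "STAI", "OCI", "OLIFE", "TFEQ", "AQ", "ASRS", "UPPS"),
    n_items = c(21L, 20L, 18L, 33L, 18L, 28L, 18L, 20L),
    factor = c("AD", "AD", "CIT", "CIT", "IIO", "AD", "IIO", "IIO"),
    primary = c(0.65, 0.65, 0.60, 0.50, 0.50, 0.40, 0.60, 0.55),
    stringsAsFactors = FALSE)
  stopifnot(sum(scales$n_items) == 176)
  set.seed(seed)
  facs <- c("AD", "IIO", "CIT")
  L <- matrix(0, 176, 3, dimnames = list(NULL, facs))
  codebook <- do.call(rbind, lapply(seq_len(nrow(scales)), function(i)
    data.frame(scale = scales$scale[i],
               factor = scales$factor[i],
               item = paste0(scales$scale[i], "_",
                             sprintf("%02d", seq_len(scales$n_items[i]))),
               n_categories = 4L, stringsAsFactors = FALSE)))
  for (r in seq_len(176)) {
    f <- match(codebook$factor[r], facs)
    lo <- scales$primary[match(codebook$scale[r], scales$scale)]
    L[r, f] <- stats::runif(1, lo - 0.1, lo + 0.1)
    L[r, -f] <- stats::rnorm(2, 0, 0.05)
  }
  rownames(L) <- codebook$item
  # cutpoints induce a positive skew (mass at low categories)
  thresholds <- lapply(seq_len(176), function(r) {
    base <- stats::qnorm(c(0.45, 0.75, 0.92))
    sort(base + stats::rnorm(3, 0, 0.15))
  })
  factor_corr <- matrix(c(1, 0.40, 0.50,
                          0.40, 1, 0.30,
                          0.50, 0.30, 1), 3, 3,
                        dimnames = list(facs, facs))
  list(loadings = L, thresholds = thresholds, codebook = codebook,
       factor_corr = factor_corr)
}

.cohort_defaults <- function() list(
  n = 800L,
  fraction_fail = 68 / 800,
  n_items = 27L,
  k_range = c(0.0016, 0.25),
  mu_lnk = -4.77,
  sigma_lnk = 1.80,
  frame_effect = 0.43,
  sd_frame_effect = 0.60,
  magnitude_effect = 0.99,
  sd_magnitude_effect = 0.50,
  mu_log_tau = log(0.5),
  sd_log_tau = 0.50,
  factor_lnk_r = c(AD = 0.10, IIO = 0.10, CIT = 0.10),
  questionnaire = NULL,   # default_questionnaire_spec() unless supplied
  age_mean = 37.6, age_sd = 11.4,
  gender_probs = c(female = 0.492, male = 0.481, diverse = 0.027),
  icar_mean_p = 0.52, icar_disp = 6.0)

#' Generate a complete synthetic study cohort
#'
#' Bundles [generate_item_set()], hyperbolic softmax agents,
#' [simulate_choices()], [simulate_questionnaires()] and covariates into a
#' single reproducible synthetic study: agents' `ln k` correlates with the
#' three questionnaire factors at configured effect sizes (default
#' `r = 0.10` each, the design effect size of the original power analysis),
#' a within-person frame effect lowers `ln k` under date framing, a
#' magnitude effect lowers it for larger rewards, and a configurable
#' fraction of participants is flagged as failing attention checks.
#'
#' @param config named list overriding any default (see Details); unknown
#'   keys raise a configuration error.
#' @param seed integer master seed.
#' @details Config keys and defaults: `n` (800), `fraction_fail` (68/800),
#'   `n_items` (27), `k_range` (0.0016-0.25/day), `mu_lnk` (-4.77),
#'   `sigma_lnk` (1.80), `frame_effect` (0.43), `sd_frame_effect` (0.60),
#'   `magnitude_effect` (0.99), `sd_magnitude_effect` (0.50), `mu_log_tau`,
#'   `sd_log_tau`, `factor_lnk_r` (length-3, AD/IIO/CIT), `questionnaire`
#'   (a spec like [default_questionnaire_spec()]), `age_mean`, `age_sd`,
#'   `gender_probs`, `icar_mean_p`, `icar_disp`.
#' @return list with `choices` (long choice table), `cohort` (covariates,
#'   attention flag, true factor scores and item responses), `codebook`,
#'   and `truth` (agent parameters and factor scores used).
#' @export
generate_cohort <- function(config = list(), seed = 1) {
  defaults <- .cohort_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_config("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (cfg$fraction_fail < 0 || cfg$fraction_fail >= 1)
    stop_config("fraction_fail must be in [0, 1)")
  spec <- cfg$questionnaire %||% default_questionnaire_spec()
  n <- as.integer(cfg$n)
  set.seed(seed)

  ## joint latent draw: standardized ln k plus the three factors
  r <- cfg$factor_lnk_r
  if (length(r) != 3) stop_config("factor_lnk_r must have length 3")
  Sig <- rbind(c(1, r), cbind(r, spec$factor_corr))
  if (min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop_config("factor_lnk_r incompatible with factor_corr (not PD)")
  lat <- MASS::mvrnorm(n, rep(0, 4), Sig)
  fscores <- lat[, 2:4, drop = FALSE]
  colnames(fscores) <- colnames(spec$factor_corr)

  agents <- data.frame(
    participant_id = sprintf("p%04d", seq_len(n)),
    ln_k = cfg$mu_lnk + cfg$sigma_lnk * lat[, 1],
    tau = exp(stats::rnorm(n, cfg$mu_log_tau, cfg$sd_log_tau)),
    frame_effect = stats::rnorm(n, cfg$frame_effect, cfg$sd_frame_effect),
    magnitude_effect = stats::rnorm(n, cfg$magnitude_effect,
                                    cfg$sd_magnitude_effect),
    stringsAsFactors = FALSE)

  items <- generate_item_set(n_items = cfg$n_items, k_range = cfg$k_range,
                             seed = child_seed(seed, 1))
  choices <- simulate_choices(items, agents, seed = child_seed(seed, 2))

  q <- simulate_questionnaires(n, spec$loadings, spec$factor_corr,
                               spec$thresholds, seed = child_seed(seed, 3),
                               factor_scores = fscores)

  ## covariates
  age <- pmin(65L, pmax(18L, as.integer(round(
    stats::rnorm(n, cfg$age_mean, cfg$age_sd)))))
  gender <- sample(names(cfg$gender_probs), n, replace = TRUE,
                   prob = cfg$gender_probs / sum(cfg$gender_probs))
  a <- cfg$icar_mean_p * cfg$icar_disp
  b <- (1 - cfg$icar_mean_p) * cfg$icar_disp
  icar <- stats::rbinom(n, 16, stats::rbeta(n, a, b))
  fail <- stats::runif(n) < cfg$fraction_fail

  cohort <- data.frame(
    participant_id = agents$participant_id,
    age = age, gender = gender, cognitive_ability = icar,
    attention_check_fail = fail,
    AD_true = fscores[, "AD"], IIO_true = fscores[, "IIO"],
    CIT_true = fscores[, "CIT"],
    stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(q$responses))

  list(choices = choices, cohort = cohort, codebook = spec$codebook,
       truth = list(agents = agents, factor_scores = fscores, config = cfg,
                    items = items, seed = seed))
}
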