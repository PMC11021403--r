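# Readers/writers and pipeline orchestration.

.choice_cols <- c("participant_id", "item_id", "frame", "ss_amount",
                  "ss_delay_days", "ll_amount", "ll_delay_days",
                  "magnitude_band", "choice")

# shared schema validation for choice tables (in-memory or from disk)
.check_choices <- function(data) {
  miss <- setdiff(setdiff(.choice_cols, "item_id"), names(data))
  if (length(miss))
    stop("choice table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(data$choice %in% c(0, 1)))
  if (length(bad))
    stop("choice must be 0/1; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(data$ll_amount <= data$ss_amount))
    stop("ll_amount must exceed ss_amount in every row")
  if (any(data$ll_delay_days <= data$ss_delay_days))
    stop("ll_delay_days must exceed ss_delay_days in every row")
  if ("item_id" %in% names(data)) {
    key <- paste(data$participant_id, data$item_id, data$frame)
    dup <- which(duplicated(key))
    if (length(dup))
      stop("duplicate participant x item x frame row(s): ",
           paste(utils::head(dup, 5), collapse = ", "))
  }
  data
}

#' Read a long-format intertemporal choice table
#'
#' @param path CSV or TSV file with columns `participant_id`, `item_id`,
#'   `frame`, `ss_amount`, `ss_delay_days`, `ll_amount`, `ll_delay_days`,
#'   `magnitude_band`, `choice` (0 = smaller-sooner, 1 = larger-later).
#' @return validated data.frame.
#' @export
read_choice_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  .check_choices(d)
}

#' Write a choice table to CSV
#' @param data validated choice data.frame.
#' @param path output file.
#' @export
write_choice_table <- function(data, path) {
  .check_choices(data)
  utils::write.csv(data[, intersect(.choice_cols, names(data))], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a cohort table plus JSON codebook sidecar
#' @param cohort cohort data.frame from [generate_cohort()].
#' @param codebook codebook data.frame (item/scale/factor mapping).
#' @param path output CSV; the codebook goes to `<path>.codebook.json`.
#' @export
write_cohort_table <- function(cohort, codebook, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  jsonlite::write_json(codebook, paste0(path, ".codebook.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' Table-1-style descriptives
#'
#' Mean, sample SD, range, adjusted Fisher-Pearson skewness and N per
#' variable, computed on non-missing values.
#'
#' @param df data.frame of numeric variables.
#' @return data.frame with one row per variable.
#' @export
describe_table <- function(df) {
  do.call(rbind, lapply(names(df), function(v) {
    x <- df[[v]][is.finite(df[[v]])]
    data.frame(variable = v, n = length(x), min = min(x), max = max(x),
               mean = mean(x), sd = stats::sd(x),
               skewness = skewness_adj(x), stringsAsFactors = FALSE)
  }))
}

#' Run the full analysis pipeline
#'
#' Executes the study's analysis order on synthetic (default) or
#' user-supplied data: fit the frame model, fit the magnitude model,
#' predictive-accuracy evaluation (PSIS-LOO, per-participant WAIC),
#' framing-effect inference (BEST, paired t, repeated-measures ANOVA),
#' factor extraction from questionnaire items, and the association layer
#' (outlier-masked correlations and robust-SE regressions). All artifacts
#' are written under `config$out_dir` together with a JSON manifest
#' recording the seed, configuration and stage timings.
#'
#' @param config list: `seed`, `out_dir`, optional `choices_path` /
#'   `cohort_path` (otherwise a synthetic cohort is generated with
#'   `cohort_config`), `family` (default hyperbolic), `mcmc` options list,
#'   `n_factors` (default 3), `run_factors` (default TRUE; the factor stage
#'   dominates runtime on large cohorts), `n_boot` (default 0: no bootstrap
#'   CIs in the pipeline run).
#' @return invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(
    list(seed = 1, out_dir = tempfile("tdisc_run_"), choices_path = NULL,
         cohort_path = NULL, cohort_config = list(), family = "hyperbolic",
         mcmc = list(), n_factors = 3, run_factors = TRUE, n_boot = 0,
         hc_type = "HC3"), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[3]
  log_lines <- character()
  stage <- function(msg) {
    log_lines <<- c(log_lines, sprintf("[%7.1fs] %s", proc.time()[3] - t0, msg))
  }
  res <- list()

  stage("inputs")
  if (is.null(cfg$choices_path)) {
    syn <- generate_cohort(cfg$cohort_config, seed = cfg$seed)
    choices <- syn$choices
    cohort <- syn$cohort
    codebook <- syn$codebook
    write_choice_table(choices, file.path(cfg$out_dir, "choices.csv"))
    write_cohort_table(cohort, codebook, file.path(cfg$out_dir, "cohort.csv"))
  } else {
    choices <- read_choice_table(cfg$choices_path)
    cohort <- if (!is.null(cfg$cohort_path))
      utils::read.csv(cfg$cohort_path, stringsAsFactors = FALSE)
    codebook <- NULL
    syn <- NULL
  }
  if (!is.null(cohort) && "attention_check_fail" %in% names(cohort)) {
    keep <- cohort$participant_id[!cohort$attention_check_fail]
    n_excl <- sum(cohort$attention_check_fail)
    choices <- choices[choices$participant_id %in% keep, ]
    cohort <- cohort[!cohort$attention_check_fail, ]
    stage(sprintf("attention-check exclusion: %d dropped", n_excl))
  }

  stage("fit frame model")
  fit_frame <- fit_hierarchical(choices, cfg$family, "frame",
                                mcmc = cfg$mcmc, seed = cfg$seed)
  if (!fit_frame$converged) stage("WARN: frame model R-hat above limit")
  est_frame <- point_estimates(fit_frame)

  stage("fit magnitude model")
  fit_mag <- fit_hierarchical(choices, cfg$family, "magnitude_band",
                              mcmc = cfg$mcmc, seed = cfg$seed + 1)
  if (!fit_mag$converged) stage("WARN: magnitude model R-hat above limit")
  est_mag <- point_estimates(fit_mag)

  est <- merge(est_frame, est_mag[, c("participant_id",
                                      grep("^lnk_|^me$", names(est_mag),
                                           value = TRUE))],
               by = "participant_id")
  utils::write.csv(est, file.path(cfg$out_dir, "participant_estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(fit_frame$diagnostics,
                   file.path(cfg$out_dir, "posterior_summary_frame.csv"),
                   row.names = FALSE)
  utils::write.csv(fit_mag$diagnostics,
                   file.path(cfg$out_dir, "posterior_summary_magnitude.csv"),
                   row.names = FALSE)

  stage("model evaluation")
  ll <- pointwise_loglik(fit_frame)
  loo <- psis_loo(ll)
  if (any(loo$pareto_k > 0.7, na.rm = TRUE))
    stage(sprintf("WARN: %d observations with pareto_k > 0.7",
                  sum(loo$pareto_k > 0.7, na.rm = TRUE)))
  res$loo <- loo

  stage("framing effects")
  dde <- est$dde[is.finite(est$dde)]
  best_dde <- best_paired(dde, seed = cfg$seed)
  tt <- paired_t(est$lnk_delay, est$lnk_date)
  magm <- as.matrix(est[, c("lnk_small", "lnk_medium", "lnk_large")])
  anova_mag <- rm_anova(magm)
  best_sm <- best_paired(est$lnk_small - est$lnk_medium, seed = cfg$seed + 1)
  best_ml <- best_paired(est$lnk_medium - est$lnk_large, seed = cfg$seed + 2)
  effects <- list(best_dde = best_dde[c("posterior_median_mu",
                                        "prob_above_zero", "hdi95")],
                  paired_t = tt,
                  rm_anova = anova_mag[c("F", "df", "df_gg", "p_gg",
                                         "partial_eta_squared")],
                  best_small_medium = best_sm[c("posterior_median_mu",
                                                "prob_above_zero", "hdi95")],
                  best_medium_large = best_ml[c("posterior_median_mu",
                                                "prob_above_zero", "hdi95")])
  jsonlite::write_json(effects, file.path(cfg$out_dir, "effects.json"),
                       auto_unbox = TRUE, digits = 6, force = TRUE)

  fsol <- NULL
  if (isTRUE(cfg$run_factors) && !is.null(cohort) && !is.null(codebook)) {
    stage("factor analysis")
    itemcols <- intersect(codebook$item, names(cohort))
    items <- cohort[, itemcols, drop = FALSE]
    hc <- hetcor_matrix(items,
                        var_types = rep("ordinal", length(itemcols)))
    nf <- min(cfg$n_factors, cng_factor_count(eigen(hc$matrix,
                                                    symmetric = TRUE,
                                                    only.values = TRUE)$values))
    fsol <- fit_ml_efa(hc, n_factors = cfg$n_factors, n_obs = nrow(items))
    fsc <- factor_scores(fsol, items)
    utils::write.csv(cbind(participant_id = cohort$participant_id,
                           as.data.frame(fsc)),
                     file.path(cfg$out_dir, "factor_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(fsol$loadings),
                     file.path(cfg$out_dir, "loadings.csv"))
    utils::write.csv(data.frame(eigenvalue = fsol$eigenvalues),
                     file.path(cfg$out_dir, "eigenvalues.csv"),
                     row.names = FALSE)
    stage(sprintf("CNG selected %d factor(s); %d extracted", nf,
                  cfg$n_factors))
  }

  assoc <- NULL
  if (!is.null(cohort)) {
    stage("associations")
    scales <- if (!is.null(codebook)) {
      ss <- sapply(split(codebook$item, codebook$scale), function(it)
        rowSums(cohort[, it, drop = FALSE]))
      as.data.frame(ss)
    } else NULL
    td <- est[match(cohort$participant_id, est$participant_id), ]
    if (!is.null(scales)) {
      assoc <- pearson_with_holm(
        td[, c("lnk_delay", "lnk_date"), drop = FALSE], scales)
      utils::write.csv(assoc, file.path(cfg$out_dir, "correlations.csv"),
                       row.names = FALSE)
      covars <- data.frame(age = cohort$age,
                           gender1 = as.numeric(cohort$gender == "male"),
                           gender2 = as.numeric(cohort$gender == "diverse"),
                           cognitive_ability = cohort$cognitive_ability)
      # constant covariates (e.g. no diverse-gender respondents in a small
      # cohort) carry no information and would break the design rank
      covars <- covars[, vapply(covars, function(v)
        stats::var(v, na.rm = TRUE) > 0, TRUE), drop = FALSE]
      regs <- list()
      for (dv in c("lnk_delay", "lnk_date")) {
        for (sc in names(scales)) {
          X <- cbind(covars, scale = scales[[sc]])
          r <- robust_ols(td[[dv]], X, hc_type = cfg$hc_type)
          r$table$outcome <- dv
          r$table$scale <- sc
          regs[[paste(dv, sc)]] <- r$table
        }
      }
      regtab <- do.call(rbind, regs)
      ## Holm across the two DVs per scale x term (the study's test family)
      regtab$p_c <- NA_real_
      for (sc in unique(regtab$scale)) for (tm in unique(regtab$term)) {
        ix <- regtab$scale == sc & regtab$term == tm
        regtab$p_c[ix] <- holm_correct(regtab$p[ix])
      }
      utils::write.csv(regtab, file.path(cfg$out_dir, "regressions.csv"),
                       row.names = FALSE)
      res$regressions <- regtab
    }
  }

  stage("descriptives")
  desc_vars <- est[, grep("^lnk_|^dde$|^me$|^waic$", names(est))]
  desc <- describe_table(desc_vars)
  utils::write.csv(desc, file.path(cfg$out_dir, "descriptives.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "tdisc",
    version = as.character(utils::packageVersion("tdisc")),
    seed = cfg$seed, family = cfg$family,
    config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))),
    mcmc = fit_frame$mcmc,
    converged = c(frame = fit_frame$converged, magnitude = fit_mag$converged),
    elpd = loo$elpd_estimate, elpd_se = loo$se,
    stages = log_lines)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 8, force = TRUE)
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))

  invisible(c(res, list(fit_frame = fit_frame, fit_mag = fit_mag,
                        estimates = est, effects = effects, factors = fsol,
                        associations = assoc, descriptives = desc,
                        manifest = manifest, out_dir = cfg$out_dir)))
}
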