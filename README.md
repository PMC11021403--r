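# tdisc

Hierarchical Bayesian temporal discounting and transdiagnostic symptom
dimensions, as one tested R pipeline.

## What this package is for

Temporal discounting (TD) — the devaluation of a future reward as a
function of the delay until receipt — is aberrant across many mental
disorders, which makes it a candidate *transdiagnostic* marker. Testing
that idea in a general-population sample requires several pieces of
machinery that rarely live in one place:

1. **Discount-rate estimation.** Binary intertemporal choices (27
   MCQ-style items, each framed once in delay units and once as a calendar
   date) are fitted with a hierarchical Bayesian model. Subjective value
   follows a hyperbolic (`V = A/(1+kD)`), exponential (`V = A e^{-kD}`) or
   quasi-hyperbolic (`V = A β δ^D`) family; choices follow a softmax rule
   `P(LL) = logistic(τ (V_LL − V_SS))`. Participant-level `ln k` is
   estimated per condition (frame or magnitude band) with correlated
   multivariate-normal population structure, so the within-person
   **date/delay effect** `ln k(delay) − ln k(date)` and **magnitude
   effect** `ln k(small) − ln k(large)` fall out as differences of point
   estimates.
2. **Model evaluation.** PSIS-LOO elpd with the two-SE comparison rule,
   and per-participant WAIC as an individual model-fit index.
3. **Effect inference.** BEST (Bayesian t-distributed one-group model,
   30000 MCMC iterations) on paired differences, the frequentist paired t
   with the averaged-SD Hedges `g_av`, and repeated-measures ANOVA with
   Greenhouse–Geisser correction and partial η².
4. **Transdiagnostic dimensions.** A heterogeneous
   (Pearson/polyserial/polychoric) correlation matrix over 176 ordinal
   questionnaire items, CNG scree-test factor-count selection,
   maximum-likelihood EFA with oblimin rotation, regression factor scores
   (dimensions labelled AD, IIO, CIT), and bootstrap loading CIs.
5. **Associations.** 3-SD outlier exclusion, Pearson correlations and
   OLS with HC3 heteroskedasticity-robust SEs on z-standardized variables,
   Breusch–Pagan tests, Bonferroni–Holm correction across the two
   dependent variables, and the exact a priori power computation for
   correlation designs.
6. **A synthetic cohort generator** that emulates the full study design
   (agents, items, frame/magnitude effects, a 3-factor ordinal
   questionnaire battery, covariates, attention-check failures), so every
   stage is testable without downloading anything.

The methods vignette
(`vignettes/temporal-discounting-pipeline.Rmd`) documents the models,
priors, sampler, and every defaulted design decision.

## Worked example

```r
library(tdisc)

syn <- generate_cohort(list(n = 60L), seed = 42)          # synthetic study
fit <- fit_hierarchical(syn$choices, family = "hyperbolic",
                        condition_var = "frame",
                        mcmc = list(chains = 2, warmup = 600, iter = 600),
                        seed = 42)
print(fit)
est  <- point_estimates(fit)                              # ln k, DDE, WAIC
best <- best_paired(est$dde, iterations = 30000, seed = 42)
print(best)
tt <- paired_t(est$lnk_delay, est$lnk_date)
power_n_correlation(0.10)                                 # design power
```

Output of this exact script:

```
Hierarchical discounting fit (hyperbolic, conditions: delay/date)
60 participants, 3240 observations; 2 chains x 600 draws
converged: FALSE (max split R-hat = 1.237 )

     parameter   mean     sd   q2.5  q97.5 rhat   ess
1    mu_lnk[1] -4.841 0.2474 -5.345 -4.382 1.03 131.9
2    mu_lnk[2] -5.256 0.2709 -5.819 -4.746 1.04  90.1
3 sigma_lnk[1]  1.776 0.2289  1.413  2.362 1.20  10.3
4 sigma_lnk[2]  1.860 0.2406  1.471  2.439 1.24   8.5
5       R[1,2]  0.961 0.0170  0.922  0.985 1.05  23.9
6       mu_tau -1.054 0.0836 -1.213 -0.887 1.02  84.4
7    sigma_tau  0.434 0.0844  0.280  0.604 1.00  64.5
BEST (n = 60, 30000 iterations): median mu = 0.422, 95% HDI [0.334, 0.499], P(mu > 0) = 1.0000
paired t(59) = 10.15, p = 1.4e-14, g_av = 0.24 [0.17, 0.30]
required n for r = 0.10 at 80% power: 782
```

Reading it: the cohort was generated with group mean `ln k` of −4.77 in
the delay frame and a within-person frame effect of 0.43; the fit recovers
the group means (−4.84 delay, −5.26 date), the BEST posterior median of
the date/delay effect is 0.42 with the whole posterior above zero, and the
paired t confirms the effect with a small averaged-SD effect size — the
qualitative signature of the date/delay phenomenon. The `converged: FALSE`
flag is doing its job for this deliberately short demo run: the group
*means* are well mixed (R-hat ≤ 1.04) but the group SDs need the default 4
× 1000-draw run to pass the 1.05 threshold. The final line is the exact
(non-approximate) sample size needed to detect `r = 0.10` at 80% power,
two-sided α = 0.05.

`run_pipeline(config)` chains all stages (frame model → magnitude model →
LOO/WAIC → BEST/t/ANOVA → factor analysis → associations → descriptives)
and writes CSV/JSON artifacts plus a manifest with the seed and stage log.

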