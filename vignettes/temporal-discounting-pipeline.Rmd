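---
title: "Hierarchical temporal discounting and transdiagnostic dimensions: models and methods"
author: "tdisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical temporal discounting and transdiagnostic dimensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tdisc` implements an end-to-end analysis of individual differences in
temporal discounting (TD) and their association with transdiagnostic
psychiatric symptom dimensions. This vignette documents the models, the
defaults and the numerical choices, in the spirit of a methods appendix:
everything here is what the code does, not a report of empirical results.

## 1. The discounting model

Each participant makes binary choices between a smaller-immediate reward
(amount $A_{SS}$, delay 0) and a larger-later reward ($A_{LL}$ after $D$
days), in an MCQ-style design: 27 items in three magnitude bands, each item
presented once with the delay rendered in days and once as a calendar date.
Subjective values follow one of three families,

$$V_{\mathrm{hyp}} = \frac{A}{1 + kD},\qquad
  V_{\mathrm{exp}} = A e^{-kD},\qquad
  V_{\beta\delta} = A\,\beta\,\delta^{D}\ (D > 0),$$

and choices follow a softmax (logistic) rule in the value difference,
$P(\mathrm{LL}) = \mathrm{logit}^{-1}\!\left(\tau\,(V_{LL} - V_{SS})\right)$,
with a participant-level inverse temperature $\tau > 0$ shared across
conditions. The original analyses do not publish their likelihood; the
logistic value-difference rule is the field-standard choice and is treated
here as a documented modelling decision (`choice_probability()`). For the
quasi-hyperbolic family the `ln k` parameter carries the daily rate of the
$\delta$ component, $\delta = e^{-k}$, so all three families share one
interface.

### Hierarchy and priors

`fit_hierarchical()` jointly models the condition-specific log discount
rates of each participant (conditions are either the two time frames or the
three magnitude bands):

$$\ln k_i \sim \mathrm{MVN}(\mu, \operatorname{diag}(\sigma) R
  \operatorname{diag}(\sigma)), \qquad \ln\tau_i \sim
  \mathcal{N}(\mu_\tau, \sigma_\tau),$$

with weakly informative priors $\mu_c \sim \mathcal{N}(-4, 3)$ (centred on
plausible MCQ rates, about $k \approx 0.018$/day), $\sigma_c \sim
\mathrm{HalfNormal}(2)$, $R \sim \mathrm{LKJ}(2)$, $\mu_\tau \sim
\mathcal{N}(0, 1)$, $\sigma_\tau \sim \mathrm{HalfNormal}(1)$. Correlated
condition-specific rates respect the within-person pairing that the
downstream paired analyses (date/delay effect, magnitude effect) rely on.

### Sampler

The posterior is explored with an adaptive Metropolis-within-Gibbs sampler
rather than a gradient-based one: participant-level parameters are
conditionally independent given the hyperparameters, so all participants
are updated in parallel with vectorised random-walk proposals; group means
are conjugate Gibbs draws. The location-scale "funnel" that makes centred
hierarchical models hard for random-walk samplers is handled with
interweaving-style joint moves: a translation move shifts $\mu_c$ together
with all $\ln k_{ic}$, and a rescaling move multiplies $\sigma_c$ and the
deviations $\ln k_{ic} - \mu_c$ by a common factor (the MVN log-determinant
and the transformation Jacobian cancel, leaving only the likelihood and the
$\sigma$ prior in the acceptance ratio). The rescaling move is repeated
within each sweep because its steps are necessarily small. Step sizes adapt
during warmup toward standard acceptance targets.

Defaults are 4 chains of 1000 warmup + 1000 kept sweeps. Convergence is
summarised with split-$\widehat{R}$ and autocorrelation-based bulk ESS on
all group-level parameters; a fit is flagged non-converged when any
$\widehat{R} > 1.05$ (the flag is returned, never silently swallowed).
Group means and derived contrasts mix quickly; the group SDs and the
condition correlation are the slowest-moving quantities and dominate the
reported $\widehat{R}$. Divergence counts, a Hamiltonian-specific
diagnostic, are reported as 0 for interface completeness.

Point estimates are posterior means of the participant-level draws. The
date/delay effect is defined as $\mathrm{DDE}_i = \ln k_i(\text{delay}) -
\ln k_i(\text{date})$ and the magnitude effect as $\mathrm{ME}_i = \ln
k_i(\text{small}) - \ln k_i(\text{large})$, exactly as differences of
point estimates.

## 2. Predictive accuracy

`psis_loo()` implements Pareto-smoothed importance sampling LOO on the
draws-by-observations log-likelihood matrix: per observation, the largest
$\lceil \min(0.2S, 3\sqrt{S}) \rceil$ importance ratios are replaced by
expected order statistics of a generalized Pareto distribution fitted to
the tail exceedances with the Zhang–Stephens posterior-mean estimator
(with the usual weak prior pulling the shape toward 0.5). Smoothed weights
are capped at the raw maximum; observations with shape $k > 0.7$ are
flagged, not refit. Degenerate zero-variance tails (e.g. a single
effective draw) report $k = -\infty$ and reduce to the in-sample log
score. `compare_elpd()` applies the two-SE rule on the paired pointwise
differences — fits are "distinguishable" iff $|\Delta\mathrm{elpd}| \ge
2\,\mathrm{SE}_{\mathrm{diff}}$ — which is the decision criterion used
throughout, not a p-value. Pointwise units default to observations; WAIC
is also aggregated per participant,

$$\mathrm{WAIC}_i = -2 \sum_{j \in i}\left(\log \tfrac{1}{S}\sum_s p_{sj}
  - \operatorname{Var}_s \log p_{sj}\right),$$

with the $S-1$ variance denominator, as a per-person model-fit index
(lower = better).

## 3. Framing and magnitude inference

`best_paired()` is the canonical one-group BEST model — a Student-t
likelihood with location $\mu$, scale $\sigma$ and normality $\nu$ — fitted
to paired differences by adaptive MCMC with the canonical priors
($\mu \sim \mathcal{N}(\bar d, 1000\,s_d)$, $\sigma \sim \mathrm{Unif}(s_d/1000,
1000\,s_d)$, $\nu \sim 1 + \mathrm{Exp}(29)$), 30000 iterations by
default. It reports $P(\mu > 0)$, the posterior median of $\mu$ (the
"median paired difference") and the 95% HDI. It is run on point-estimate
differences; running it on full posterior draws of the difference is a
documented alternative the interface permits (pass those draws as the
difference vector).

`paired_t()` supplements this with the frequentist paired t-test and the
averaged-SD Hedges effect size $g_{av} = J \cdot \bar d / \tfrac{1}{2}(s_x
+ s_y)$, $J = 1 - 3/(4\,df - 1)$, with a 95% CI from noncentral-t
inversion rescaled from the difference-SD to the averaged-SD metric.
`rm_anova()` runs the one-way within-subject ANOVA with Mauchly's test,
Greenhouse–Geisser correction (the fractional dfs reported by the original
analyses imply such a correction; GG is the variant chosen here), partial
$\eta^2 = SS_{\mathrm{effect}}/(SS_{\mathrm{effect}} + SS_{\mathrm{error}})$,
and all-pairs post-hoc paired t-tests (uncorrected by default, with an
adjustment flag).

## 4. Transdiagnostic dimensions

Questionnaire items are ordinal, so `hetcor_matrix()` builds a
heterogeneous correlation matrix: Pearson for continuous pairs, two-step ML
polyserial for mixed pairs, two-step ML polychoric for ordinal pairs
(thresholds from marginal normal quantiles, then the latent correlation by
maximising the bivariate-normal cell likelihood). Bivariate normal
rectangle probabilities use Owen's single-integral form with 48-node
Gauss–Legendre quadrature; the latent correlation is bracketed in
$[-0.999, 0.999]$. Pairs are computed on pairwise-complete observations.
If the assembled matrix is indefinite it is smoothed by clipping
eigenvalues at $10^{-6}$ and rescaling to unit diagonal, with a flag.

The factor count comes from the Cattell–Nelson–Gorsuch scree test: for
each admissible split $t$, straight lines are fitted to the eigenvalue
triplets $(t-2,\dots,t)$ and $(t+1,\dots,t+3)$ and the selected count
maximises the *increase* in scree slope (slope after minus slope before;
the direction in which the scree flattens at the elbow), ties broken to
the smallest count. Extraction is maximum likelihood (`stats::factanal`,
uniquenesses bounded below at 0.005), followed by a direct-quartimin
(oblimin, $\gamma = 0$) oblique rotation implemented by gradient
projection with multiple random orthonormal starts; columns are ordered by
explained variance and signed so that the majority of salient loadings
($|\lambda| \ge 0.3$) are positive. Factor scores use the Thurstone
regression method, $S = Z R^{-1} \Lambda \Phi$, standardized; the scoring
method and $\gamma$ are decisions, since the original analyses name only
"oblimin" and "factor scores". Bootstrap loading CIs (percentile, 1000
replicates by default) refit the whole hetcor+EFA per resample and are
aligned to the reference solution by Tucker-congruence column matching
with sign flipping, which prevents label switching from corrupting the
intervals; non-converging replicates are dropped and counted, with more
than 10% dropped treated as an error.

## 5. Associations and power

The association layer excludes per-variable outliers beyond 3 SD from the
full-sample mean, computes Pearson correlations on the pairwise mask
intersections, and Holm-corrects p-values across the two dependent
variables (the delay- and date-frame discount rates) within each scale —
exactly the family used by the study design; single-DV analyses report
uncorrected p. Regressions (`robust_ols()`) z-standardize the outcome and
the continuous regressors (so coefficients are standardized $\beta$s;
binary dummies stay on their own scale), use HC3 sandwich standard errors
by default (HC0–HC2 available), normal-quantile Wald CIs, and attach the
Koenker studentized Breusch–Pagan test. Gender enters as two dummies
(male, diverse; female reference). Rank-deficient designs are an error
naming the collinear columns rather than a silent drop.

`power_n_correlation()` reproduces the a priori power computation from the
exact sampling density of the Pearson correlation under bivariate
normality (Hotelling's form with a Gauss-hypergeometric series), not the
Fisher-z approximation: the critical value comes from the exact null
(t-transform) and power integrates the alternative density outside it;
the required n is found by bisection. With $\rho = 0.10$, $\alpha = 0.05$
two-sided and 80% power this yields $n = 782$.

## 6. The synthetic cohort

`generate_cohort()` produces a complete synthetic study so every stage has
a no-download input. It emulates:

- the 27-item two-frame MCQ geometry (9 items per band, larger-later
  amounts in \$25–35 / \$50–60 / \$75–85, indifference rates log-spaced
  over 0.0016–0.25/day — the published instrument's item parameters are
  proprietary, so the geometry, not the items, is reproduced);
- hyperbolic softmax agents with $\ln k \sim \mathcal{N}(-4.77, 1.80)$ and
  a within-person frame effect $\mathcal{N}(0.43, 0.60)$ (delay minus
  date) and magnitude effect $\mathcal{N}(0.99, 0.50)$ (small minus
  large), matching the observed moments of the study population; the
  magnitude effect enters $\ln k$ linearly over bands, a deliberate
  monotone idealisation;
- 176 four-point ordinal items across eight synthetic scales loading on
  three oblique factors (AD, IIO, CIT; inter-factor correlations
  0.40/0.50/0.30), with positively skewed thresholds;
- factor–discounting correlations of $r = 0.10$ each (the design effect
  size of the a priori power analysis), induced through a joint Gaussian
  latent draw;
- covariates (age, three-category gender, a 0–16 cognitive-ability score
  with beta-binomial overdispersion) and an attention-check failure flag
  at rate 68/800.

What it does **not** emulate: item content, acquiescence or other response
styles, careless responding beyond the binary flag, differential item
functioning, and non-monotone magnitude profiles. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
generative assumptions, not robustness to every artefact of real
questionnaire data.

## 7. Verification sizes and numerical notes

The test suite verifies parameter recovery on 10 cohorts of 100 agents
(2 chains, 600 warmup + 600 draws), model comparison on 10 cohorts of 120
agents, BEST on n = 718 differences with the full 30000 iterations, and
the factor pipeline at the full study scale (n = 2000, 176 items); these
sizes were chosen as the smallest at which the Monte-Carlo error of each
check is clearly below its acceptance margin. Exact-oracle checks (PSIS
vs brute-force refit LOO, polychoric vs likelihood grid search, Holm and
CNG vs their defining formulas, two-condition ANOVA vs the squared paired
t) run at toy sizes.

Numerical choices worth knowing: `optimize()` tolerance $10^{-5}$ on
latent correlations; bivariate-normal cell probabilities floored at
$10^{-12}$; rotation convergence at gradient norm $10^{-6}$ with up to 30
step halvings; the degenerate `k_range` with equal endpoints yields
identical indifference rates (documented degenerate case); identical
paired vectors return $t = 0$ rather than an error, while non-identical
zero-variance differences are an error; CNG ties break to the smallest
factor count; child seeds for chains and cohort components are derived
deterministically from the master seed and stay below $2^{31}$.

## 8. Limitations

The sampler trades per-draw efficiency for implementation transparency;
group-SD chains move slowly and long runs are advisable when those are the
quantities of interest. Two-step (not joint) ML is used for latent
correlations, matching common practice but slightly understating threshold
uncertainty; bootstrap CIs absorb this in the factor pipeline. The BEST
default operates on point-estimate differences, which ignores posterior
uncertainty in the individual estimates (the draw-level alternative is
available). The pipeline treats the magnitude model's pooled 18
observations per band as exchangeable across frames, mirroring the
original design decision to fit "another" model on the same 54 choices.
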