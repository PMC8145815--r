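---
title: "Measuring and decomposing income-related inequality in health services utilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing income-related inequality in health services utilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equidecomp)
```

## The problem

Surveys of middle-aged and older rural populations record whether each
respondent used outpatient care recently or inpatient care in the past
year, together with household income, a community identifier and a set
of demographic, lifestyle and health-status covariates. Two questions
follow: how utilization rates differ across groups and policy periods,
and whether utilization is concentrated among the poor or the rich once
respondents are ordered by living standards. `equidecomp` implements the
estimators for both and a generator of synthetic survey waves with known
ground truth, so every stage can be validated end to end.

## Ranks, curves and the concentration index

The living-standards axis is the weighted fractional rank
$\gamma_i$: order respondents by income and give each the mid-point of
its weight span,
$\gamma_i = (\sum_{j<i} w_j + w_i/2)/\sum_j w_j$.
Its weighted mean is exactly $1/2$, and any strictly increasing
transform of income leaves it unchanged — the index below therefore
measures *rank*-related, not level-related, inequality. Tied incomes
share the midpoint of the group's span, which equals the average of the
ranks an arbitrary tie-break would have produced; this keeps results
invariant to row order. Ranking is on household income as supplied;
callers preferring per-capita income can divide by household size before
ranking, since the rank is all that enters downstream.

The concentration index is
$$C = \frac{2}{\mu}\,\mathrm{cov}(y, \gamma),$$
with $\mu$ the weighted outcome mean and the covariance normalised by
total weight (population form). This convention makes the covariance
form coincide exactly with the summation formula
$C = \tfrac{2}{n\mu}\sum_i y_i\gamma_i - 1$ under unit weights, and the
package asserts agreement with the graphical definition
$C = 1 - 2\,\mathrm{AUC}$ of the concentration curve to $O(1/n)$.
Negative $C$ means utilization concentrated among the poor. $C$ is
reported as a relative index without a bounded-outcome correction: the
binary outcomes analysed here sit far from the 0/1 prevalence
boundaries, and the uncorrected relative index is the quantity the
surrounding literature reports.

Standard errors come from the convenient regression
$2\sigma^2_\gamma (y_i/\mu) = \alpha + \beta\gamma_i + \varepsilon_i$,
whose weighted least-squares slope is algebraically identical to $C$
(the package tests this identity to $10^{-8}$). The default standard
error is heteroskedasticity-robust (HC1); when a community identifier is
supplied the cluster-robust error is used instead and both are stored,
because respondents within a village share unobserved access conditions
and the robust-only error is anti-conservative in that case.

## The outcome model

Utilization is modelled as logistic in reference-cell dummies with a
community random intercept,
$\mathrm{logit}\,P(y_{ic}=1) = x_{ic}'\beta + b_c$,
$b_c \sim N(0, \sigma_b^2)$, fitted by maximum likelihood through
`lme4::glmer` and reported as odds ratios with Wald 95% limits. Two
numerical policies matter:

* **Boundary fallback.** When the estimated $\sigma_b$ is at the
  boundary (singular fit, or $\hat\sigma_b < 10^{-3}$), the fixed
  effects equal those of a plain logistic fit, so the model falls back
  to `glm` with cluster-robust (sandwich) standard errors. The boundary
  threshold is deliberately coarse: below it the two fits agree to well
  within estimation error (tested at $n = 6{,}000$).
* **Weights.** Binomial weights in `glmer` are trial counts, not
  sampling weights, so non-unit weights route to the weighted `glm`
  path. The generator emits unit weights by default because the source
  surveys' published analyses do not state that design weights were
  used; arbitrary positive weights are supported everywhere else.

Average marginal effects are discrete changes for categorical terms —
predicted probability with the category switched on for everyone minus
the reference, averaged over the sample with the analysis weights — and
$\overline{p(1-p)}\beta$ for continuous terms. GLMM predictions use the
fixed-effects profile (median community).

## Decomposition and horizontal inequity

With a linear approximation
$y_i = \alpha + \sum_k \beta_k x_{ki} + \varepsilon_i$, linearity of the
covariance gives
$$C = \sum_k \frac{\beta_k \bar x_k}{\mu} c_k + \frac{GC_\varepsilon}{\mu},$$
where $c_k$ is the determinant's own concentration index and
$GC_\varepsilon = 2\,\mathrm{cov}(\varepsilon, \gamma)$. The default
takes $\beta_k$ as logistic average marginal effects — the standard
nonlinear-model approximation for binary outcomes — and an OLS mode is
provided in which the identity is exact (tested to $10^{-9}$, weighted
and unweighted).

Under the AME approximation the identity is only approximate, so the
reported residual is the *remainder* $C - \sum_k \eta_k c_k$: the table
rows then always total $C$, which is what published decomposition tables
implicitly require of their percentage columns. The directly computed
$GC_\varepsilon/\mu$ is retained as a diagnostic; the gap between the
two shrinks with $n$ on logistic-generated data and is reported, not
asserted against a fixed bound.

The horizontal inequity index subtracts the need contributions:
$HI = C - \sum_{k\in\text{need}} \eta_k c_k$. The default need set is
demographics plus health status — sex, age group, disability, body
pain, chronic diseases — with education, living status, smoking and
alcohol as "other" variables and self-assessed economic status as its
own stratum. Published groupings are ambiguous about whether the
economic-status row counts toward the need arithmetic; both readings
are computed (`HI` and `HI_excl_econ_other`) rather than guessing.
Economic status stays in the regression even though income provides the
rank: it is a distinct, coarser construct, and dropping it would push
its share into the residual.

## The descriptive layer

Utilization rates are weighted means with Wilson score limits on the
effective sample size $(\sum w)^2/\sum w^2$; Wilson behaves well at the
8–20% prevalences typical of these outcomes and never leaves $[0,1]$.
Wald limits are available behind a flag for comparison with published
symmetric limits. Chi-square tests are uncorrected Pearson statistics
(`stats::chisq.test(correct = FALSE)`), which is what published 2×2
utilization tables print; a zero marginal is an error rather than a
silent `NaN`. Composition percentages use per-variable totals, because
covariates carry item missingness and the printed percentages of the
source tables only reproduce against each variable's own denominator;
printing rounds half away from zero to two decimals, as the tables do.

## What the generator emulates — and what it does not

`sim_config()` defaults define one synthetic wave: 12,000 respondents in
450 community clusters; log-normal household income
($\mathrm{meanlog} = \log 20000$, $\mathrm{sdlog} = 0.9$ — a long right
tail around a median of 20,000 currency units); categorical covariates
at the marginal frequencies typical of a rural 45+ survey (53.25%
female, 55.2% chronic disease, 25/50/25 economic strata, ...); outcomes
Bernoulli with logit intercepts set so pre-policy prevalence is ≈20%
(outpatient) and ≈8.8% (inpatient), modest covariate effects, negative
income-rank gradients (−0.20 and −0.15) producing pro-poor indices of
realistic magnitude, and community intercepts with SD 0.3 on the
log-odds scale.

Two structural choices make the equity machinery non-trivial. Health
covariates step across income tertiles (e.g. chronic-disease prevalence
0.62/0.55/0.48 from poorest to richest band), so need variables are
genuinely income-correlated and the HI construction has something to
remove. Self-assessed economic status steps across income quartile
bands with overlap, making it strongly but imperfectly rank-correlated,
as a coarse wealth measure is in practice.

The generator deliberately omits: longitudinal linkage of individuals
across waves, item non-response, survey design (PSU/stratum) structure
beyond the community cluster, and any income–cluster correlation.
Passing tests therefore demonstrate the estimators' correctness and
calibration under a clean data-generating process, not robustness to
missingness or informative sampling.

`true_concentration_index()` gives the config-implied ground truth by
replicate simulation with a Monte-Carlo standard error, and is the
oracle for the parameter-recovery tests.

## Problem sizes and numerical conventions

The test suite exercises recovery at the sizes where its bounds are
statistically reliable: logistic coefficient recovery at $n = 50{,}000$
(all coefficients within 3 robust SEs of the generating values),
index recovery at $n = 10^5$ against a 5-replicate Monte-Carlo truth,
the need-only HI null at $n = 10^5$ ($|HI| < 0.01$), and the null-index
magnitude bound at $n = 2\times 10^5$. Unit tests run smaller
($10^3$–$2\times10^4$). Degenerate inputs fail loudly: empty strata,
all-tied incomes (rank variance zero — the index is undefined),
all-zero outcomes (curve shares undefined), zero-mean determinants,
zero chi-square marginals, non-binary outcomes and non-positive weights
or incomes each raise an error naming the offender. The analysis stages
contain no randomness; only the generator consumes seeds, so reports
are byte-reproducible from a fixed CSV.

## Limitations

Cross-sectional data support no causal claims about a policy change;
the before/after contrast is descriptive. HI carries no standard error
(none is established practice for the remainder-based construction and
the source literature reports none). The AME-based decomposition is an
approximation whose residual conflates nonlinearity with genuinely
unexplained rank-correlation; the OLS mode bounds this by an exact
identity at the cost of the linear probability model's defects.
Dominance tests between concentration curves and bounded-outcome
(Wagstaff/Erreygers) corrections are out of scope.
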