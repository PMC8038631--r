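---
title: "Joint mean-dispersion modelling of child MUAC: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint mean-dispersion modelling of child MUAC: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muacjglm)
```

## The model

The response is a child's mid-upper arm circumference (MUAC, cm); the
covariates are age (years), height (cm), weight (kg), hemoglobin, total
protein and albumen (clinical concentrations, kept in their reported
units). The default term list adds three pairwise interactions among the
anthropometric variables — `weight:height`, `age:weight`, `age:height` —
as raw elementwise products, giving ten coefficients including the
intercept. Interaction columns are not centered: centering changes the
interpretation of main effects without changing the fitted surface, and
multicollinearity is something we report (via the correlation table), not
correct.

Two interlinked GLMs are fitted to the same data:

* the **mean submodel** is Gaussian with identity link,
  $\mathrm{E}(y_i) = \mu_i = x_i^\top\beta$,
  $\mathrm{var}(y_i) = \phi_i$, estimated by weighted least squares with
  prior weights $1/\phi_i$;
* the **dispersion submodel** treats the deviance components
  $d_i = (y_i-\mu_i)^2$ of the mean fit as a gamma-family response with
  log link, $\mathrm{E}(d_i) = \phi_i = \exp(g_i^\top\gamma)$,
  $\mathrm{var}(d_i) = 2\phi_i^2$.

The alternating algorithm initializes $\phi$ at the homoscedastic OLS
residual variance $\sum(y_i-\hat y_i)^2/(n-p)$, then cycles: mean fit with
weights $1/\phi_i$; deviance components; gamma fit; update $\phi$.
Convergence is declared when both the joint criterion
$-2h = \sum_i \left[(y_i-\mu_i)^2/\phi_i + \log(2\pi\phi_i)\right]$ and the
mean coefficients move by less than $10^{-8}$, with a cap of 100 outer
iterations (warning, not error, on hitting the cap: the partial fit is
still informative). After convergence the mean model is refitted once with
the final $\phi$ so that the returned weights and dispersions are mutually
consistent. The inner gamma IWLS uses tolerance $10^{-10}$ with a cap of
200 iterations — it converges only linearly (observed rates around 0.6 on
50-row ten-term dispersion fits), so a tight tolerance needs more than a
few dozen steps; because the log link makes the working weight equal the
prior weight, its weighted cross-product is fixed across iterations.

### Assumptions

Gaussian errors for MUAC given the covariates; a log-linear dispersion;
independent observations (a single clinic, no cluster structure); and a
correctly specified mean before the squared residuals are interpretable as
dispersion responses. The usual caveat of double GLMs applies: dispersion
effects are only as trustworthy as the mean model.

## REML and ML dispersion responses

Squared residuals are biased low: $\mathrm{E}(d_i) \approx (1-q_i)\phi_i$
with $q_i$ the mean-model leverage. The REML variant (the default)
corrects this by fitting $d_i/(1-q_i)$ with gamma index weights
$(1-q_i)/2$; the ML variant fits $d_i$ with weights $1/2$. Both are
exposed because the published likelihood values do not state which
weighting produced them and the original records are unavailable; the ML
variant is also the one whose fixed point coincides with stationarity of
the extended quasi-likelihood, which the test suite verifies against a
generic numerical optimizer on 50-row instances.

The weights here are *gamma index* (precision) weights: a
$\chi^2_1$-distributed deviance component has $\mathrm{var}(d) = 2\phi^2$,
i.e. index $1/2$. Under this convention the dispersion-coefficient
covariance is $(G^\top W G)^{-1}$ with $W = \mathrm{diag}(w_i)$ and no
further scale factor — equivalently $2\,(G^\top\mathrm{diag}(1-q_i)\,
G)^{-1}$ — which we confirmed by simulation against the empirical sampling
variance of $\hat\gamma$ (a formulation that applies an extra factor 2 on
top of the $1/2$ weights double-counts the quasi-dispersion and inflates
the standard errors by $\sqrt 2$). The mean-coefficient covariance is
$(X^\top\mathrm{diag}(1/\phi_i)X)^{-1}$, with the dispersion absorbed in
the weights.

## Likelihood criteria

* $-2h$: minus twice the Gaussian log-likelihood at the fitted
  $(\mu,\phi)$.
* $-2\,p_\beta(h)$: the adjusted profile likelihood that profiles out the
  mean coefficients, $-2h + \log\det\!\big(X^\top W X/(2\pi)\big)$ with
  $W=\mathrm{diag}(1/\phi_i)$.
* $\mathrm{cAIC} = -2h + 2\,p_{\text{mean}}$. Both published model fits
  satisfy this identity exactly (a +20 offset for ten mean coefficients),
  which is why the count-based penalty is the default; a leverage-based
  effective-degrees-of-freedom variant is available behind
  `compute_criteria(fit, caic_df = "leverage")` but coincides with the
  count for fixed-effects fits (weighted-hat leverages sum to $p$).
* $\mathrm{AIC} = -2h + 2(p_{\text{mean}}+q_{\text{disp}})$,
  $\mathrm{BIC} = -2h + (p_{\text{mean}}+q_{\text{disp}})\log n$. When the
  criteria disagree, the lowest AIC decides.

## Inference and the term screen

Wald statistics $t = \hat\beta_j/\mathrm{se}_j$ are referred to the
standard normal (the large-sample Z approximation; a
$t_{n-p}$ reference sits behind the `df` argument of `wald_table()`).
Stars follow the conventional thresholds $p<0.001$ (`***`), $p<0.01$
(`**`), $p<0.05$ (`*`); the source tables' own star annotations are
internally inconsistent (including a footnote defining significance "at
p < 0.00"), so printed stars are treated as decoration, and only printed
*t*-values are reproduced.

`backward_eliminate()` refits, drops the single worst term with
$p \ge 0.2$ (the retention threshold used for the exploratory screen),
and repeats. The intercept is never dropped; a main effect is protected
while any of its interactions survives; ties on $p$ break toward the
lexicographically smaller label, making the outcome independent of
candidate ordering. Whether the screen's p-values come from the plain GLM
or the joint model is a free choice in the source analysis, so the fitter
is a parameter (`refit_glm` by default, `refit_joint_with()` as the
alternative).

Gender is named as a candidate determinant in the source study's
objective but appears in none of its fitted tables; it is therefore not a
column of the cohort table, and users with sex-stratified data should
model strata separately.

## The synthetic cohort generator

The original hospital data are available only on request, so the
generator is the package's reproducible stand-in. It emulates exactly the
published structure, no more:

* **marginals** — each covariate is a truncated normal on its published
  range whose *post-truncation* mean and SD equal the published values.
  The latent parameters are solved numerically (closed-form truncated
  moments, two-parameter optimization). Plain normals clipped or rejected
  at the bounds would not do: the age range (0.13–5 y) cuts at $-1.27$ SD,
  so rejection alone would inflate the mean by roughly 14%, violating the
  generator's own calibration contract.
* **dependence** — a Gaussian copula. The latent correlation for each
  pair is calibrated (NORTA) so the *output Pearson* correlation matches
  the published value, using 48-node Gauss–Hermite quadrature and a root
  solve per pair; the calibrated matrix is eigenvalue-clipped back to a
  correlation matrix if needed. Calibration happens once, in
  `generator_config()`, so replicate draws are cheap.
* **response** — MUAC is drawn from the joint-GLM mechanism itself,
  $y_i = x_i^\top\beta + \sqrt{\exp(x_i^\top\gamma)}\,\varepsilon_i$, with
  the published mean and dispersion coefficient patterns as defaults.
  This makes parameter recovery by `fit_joint()` well-posed by
  construction. Non-positive draws (possible only in an extreme tail) are
  redrawn rowwise.

One integer seed drives a single RNG stream consumed in a fixed order
(latent covariate matrix first, then response noise); the caller's RNG
state is saved and restored.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: marginal skewness (the published age
median of 1.0 y against a mean of 1.63 y implies right skew that a
truncated normal cannot carry), measurement error and digit preference,
missingness, cluster or seasonal structure, and the published
MUAC–covariate correlations (those are an emergent consequence of the
response mechanism, not a calibration target). Tests on synthetic cohorts
establish internal statistical correctness of the estimator, not clinical
conclusions.

## Numerical choices and degenerate inputs

* Zero deviance components are floored at $10^{-10}\times\bar d$ rather
  than dropped, keeping the two submodels aligned on the same $n$.
* Rank deficiency in either design matrix is an error naming a dependent
  column; a singular profile-adjustment matrix is an error rather than a
  silent `-Inf`.
* A constant column makes correlations undefined and is an error naming
  the column; tiny floating-point overshoot of $|r|=1$ is clamped before
  the t transform.
* `histogram_data()` uses right-open bins with a closed last bin; a
  zero-range input occupies a single bin of a unit-width span.
* `running_mean()` requires an odd window and shrinks it at the edges;
  QQ plotting positions are $(i-0.5)/n$.
* Residual standardization divides by $\sqrt{\phi_i(1-q_i)}$ — the
  standard Gaussian studentization, chosen because the source analysis
  requires standardized residuals without printing a formula.

## Problem sizes in the test suite

The suite runs on synthetic cohorts sized to exercise the asymptotics
without waste: single fits at $n$ = 163–5000; coefficient-recovery and
Wald-coverage checks over 200 replicates at $n=1000$; the AIC
model-comparison direction over 100 replicates at $n=1000$; generator
calibration at $n = 10^5$ (means within 2% relative error, the age–weight
correlation within 0.03 of its 0.799 target); oracle-equivalence checks on
ten 50-row instances with two mean and two dispersion terms. The whole
suite completes in well under a minute on a single core.

## Known limitations

* The published coefficient and likelihood values themselves cannot be
  reproduced from raw data — the cohort is private — so agreement with the
  source is established at the level of table arithmetic (Wald statistics,
  criterion identities) plus distributional behaviour on the calibrated
  generator.
* The dispersion model inherits any mean-model misspecification; no
  robust or sandwich standard errors are provided.
* No random effects, non-Gaussian mean families, or non-log dispersion
  links (the log link is assumed: the source never names its dispersion
  link, and log is the standard choice that keeps $\phi>0$ and matches the
  sign interpretation of the published dispersion table).
* No WHO weight-for-height Z-scores or MUAC cut-off classification; the
  package models MUAC, it does not diagnose.
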