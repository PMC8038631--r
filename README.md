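# muacjglm

Joint mean–dispersion generalized linear models for mid-upper arm
circumference (MUAC) in malnourished children.

## The problem

MUAC is a rapid, low-cost screen for acute malnutrition in children under
five: a tape measurement of the upper arm whose value tracks subcutaneous
fat and muscle mass. Clinically it matters not only *what* MUAC a child of
given age, size and blood chemistry is expected to have, but also *how
reliable* that expectation is — which covariates inflate or shrink the
spread of MUAC around its predicted value, and hence where MUAC-based
classification is most likely to mislead.

An ordinary Gaussian GLM answers only the first question; it assumes a
constant residual variance. This package implements the joint (double) GLM
approach, which models the mean and the dispersion together:

- **mean submodel** — `E(y_i) = mu_i`, `mu_i = x_i' beta`,
  `var(y_i) = phi_i` (Gaussian, identity link);
- **dispersion submodel** — `E(d_i) = phi_i`,
  `log(phi_i) = g_i' gamma`, `var(d_i) = 2 phi_i^2`
  (gamma family, log link), where `d_i = (y_i - mu_i)^2` are the deviance
  components of the mean fit.

The two submodels are interlinked — the mean model is weighted by
`1/phi_i` and the dispersion model's response comes from the mean model's
residuals — and are fitted by alternating iterative weighted least squares
until the joint criterion `-2h = sum[(y_i - mu_i)^2 / phi_i +
log(2 pi phi_i)]` stabilizes. REML weighting of the dispersion responses
(`d_i/(1-q_i)` with index weights `(1-q_i)/2`, `q_i` the mean-model
leverage) is the default; plain ML is available. Model choice uses
`cAIC = -2h + 2 p_mean`, `AIC = -2h + 2 (p_mean + q_disp)` and
`BIC = -2h + (p_mean + q_disp) log n`, preferring the lowest AIC when they
disagree.

Because the original hospital records are not public, the package includes
a first-class synthetic cohort generator calibrated to the published
summary of 163 malnourished children: truncated-normal marginals matched
to the published means/SDs/ranges, a Gaussian copula calibrated (via
Gauss–Hermite quadrature) so output Pearson correlations hit the published
correlation matrix, and a MUAC response drawn from the joint-GLM mechanism
itself with the published mean and dispersion coefficient patterns.

## Worked example

```r
library(muacjglm)

cfg    <- default_generator_config(n = 163, seed = 42)
cohort <- generate_cohort(cfg)

fit  <- fit_joint(cohort)                                   # joint GLM (REML)
glm0 <- fit_joint(cohort, disp_terms = character(0), method = "ML")

summary(fit)$dispersion
compare_models(list(glm0, fit), labels = c("gaussian_glm", "joint_glm"))
```

```
          term    estimate         se       t         p    
   (Intercept)    -2.56124    1.53135 -1.6725   0.09442    
           age   -0.786921   0.853323 -0.9222    0.3564    
        weight    0.358604   0.232194  1.5444    0.1225    
        height   0.0296462  0.0230706  1.2850    0.1988    
    hemoglobin    0.277114  0.0681447  4.0665 4.771e-05 ***
       protein  -0.0383056  0.0182975 -2.0935   0.03631   *
       albumen   0.0086666  0.0235306  0.3683    0.7126    
 weight:height -0.00483619 0.00288081 -1.6788    0.0932    
    age:weight   -0.027843  0.0512811 -0.5429    0.5872    
    age:height   0.0126282   0.010748  1.1749      0.24    
Model comparison (lower is better):
    criterion gaussian_glm joint_glm         best
          -2h      487.085   450.246    joint_glm
 -2 p_beta(h)      548.913   517.437    joint_glm
         cAIC      507.085   470.246    joint_glm
          AIC      509.085   490.246    joint_glm
          BIC      543.116   552.121 gaussian_glm
Overall winner (lowest AIC): joint_glm
```

The dispersion table is the interesting half: on this synthetic cohort
(drawn from the calibrated truth) hemoglobin carries a significant positive
dispersion coefficient and protein a significant negative one — children
with imbalanced hemoglobin show *more* scatter between their actual and
predicted MUAC, higher protein *less*. The comparison block shows the joint
model dominating the constant-dispersion GLM on -2h, cAIC and AIC; the
lowest-AIC rule picks the joint model.

For the whole pipeline in one call (descriptives, correlations, optional
backward-elimination screen at p < 0.2, both fits, comparison, diagnostics,
JSON report):

```r
report <- run_pipeline(pipeline_config(generator = cfg, out = "report.json"))
plot(diagnostics_bundle(fit))   # residuals vs fitted, |residuals|, QQ, histogram
```

A thin command-line wrapper over the same functions ships in
`inst/cli/muacjglm.R` (subcommands `simulate`, `fit`, `report`,
`pipeline`).

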