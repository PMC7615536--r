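# trajmix

Joint trajectory modelling of two co-developing questionnaire traits —
an ADHD-symptom subscale (scored 0–10, measured at ages 4, 7, 8, 9, 12,
13, 17, 25) and a social-communication checklist (scored 0–24, measured
at ages 7, 10, 13, 17, 25) — from childhood to adulthood. The package is
aimed at researchers studying how neurodevelopmental trait domains
co-evolve in longitudinal cohorts: it identifies latent subgroups with
distinct joint trajectories and characterises them against covariates,
distal outcomes and cross-trait correlations.

## The model

The core is a parallel-process piecewise growth mixture model. For
subject *i* in latent class *k*, the stacked wave scores are

    y_i = Λ η_i + ε_i,   η_i ~ N(α_k, Ψ̃),   ε_i ~ N(0, Θ)

with one intercept and two linear slope factors per process (knot at age
17; first-slope loading min(age, 17) − first age, second-slope loading
max(age − 17, 0)). Second-slope variances are fixed to zero, the free
4 × 4 growth-factor covariance Ψ is shared across classes, and residual
variances are time-invariant per process. Missing waves enter through
their marginal normal density (full-information maximum likelihood).
Estimation is multi-start ECM with closed-form conditional updates and a
monotone log-likelihood; classes are enumerated by an adjusted
likelihood-ratio test plus AIC/BIC/entropy and a smallest-class rule,
with a parametric bootstrap LRT as the reference test.

Downstream analyses follow the standard three-step logic: modal class
assignment, its classification-error matrix Q, bias-corrected
multinomial regression of the *true* class on covariates (fixed ln Q
logits), BCH inverse-error weighting for continuous distal outcomes with
Wald equality tests, posterior-weighted ML proportions for binary
outcomes, and a Spearman-correlation workflow with predictive-mean-
matching multiple imputation, Rubin pooling and Silver's test for
comparing dependent correlations across ages.

A seeded synthetic cohort generator emulates the measurement design
(bounded integer scales, dropout-style attrition, class-linked auxiliary
variables) and ships two documented scenarios: a realistic one
(three classes, 87/6.5/6.5%, entropy ≈ 0.9) and a sharper one for
parameter-recovery studies.

## Worked example

```r
library(trajmix)

cfg    <- default_generator_config(n_subjects = 2500, seed = 42, aux = TRUE)
gen    <- generate_cohort(cfg)        # 2397 subjects retained, 103 lost to attrition
enum   <- enumerate_classes(gen$cohort, k_max = 3, seed = 1,
                            n_starts = 12, n_final = 3)
round(enum$stats[, c("K", "loglik", "AIC", "BIC", "entropy",
                     "smallest_class_share", "lmr_p")], 3)
#>   K    loglik      AIC      BIC entropy smallest_class_share lmr_p
#> 1 1 -48688.95 97413.90 97517.98      NA                1.000    NA
#> 2 2 -48455.05 96960.10 97104.65    0.88                0.108     0
#> 3 3 -48249.22 96562.44 96747.46    0.90                0.056     0
enum$recommended_k
#> [1] 3
```

Each extra class improves fit (lower AIC/BIC, significant LRT), the
3-class solution separates well (entropy 0.90) and its smallest class
clears the 5% rule, so three classes are retained — recovering the
generating structure:

```r
fit <- enum$fits[[3]]
fit
#> parallel-process growth mixture fit: K = 3, n = 2397
#> log-likelihood -48249.219 (32 parameters), converged in 298 iterations
#> class shares: 0.876 0.069 0.056
```

Characterise the classes against a binary covariate (male sex, generated
with class-conditional rates 0.49/0.73/0.54) and a standardised
polygenic-score-like variable (class means 0/0.14/0.14):

```r
lab <- modal_assignment(fit$posteriors)
Q   <- classification_error_matrix(fit$posteriors, lab)$Q

ts <- threestep_multinomial(lab, Q, gen$cohort$male)
round(ts[ts$reference == 1, c("class", "OR", "ci_low", "ci_high", "p")], 3)
#>   class    OR ci_low ci_high     p
#> 1     2 1.829  1.228   2.725 0.003
#> 2     3 1.218  0.767   1.935 0.403

bd <- bch_distal(bch_weights(lab, Q), gen$cohort$pgs_adhd)
round(bd$means, 3)
#>   class   mean    se    n effective_n
#> 1     1 -0.005 0.022 2397    2099.517
#> 2     2  0.045 0.098 2397     164.247
#> 3     3  0.143 0.114 2397     133.237
bd$wald$p
#> [1] 0.4011592
```

Class 2 (the declining-trajectory class) shows a male excess (OR 1.83
against the majority class); with only ~160 subjects per minority class
the polygenic-score contrast of ~0.15 SD is within noise here (Wald
p = 0.40) — a realistic picture of the power such contrasts have at this
cohort size. The full pipeline (`run_pipeline`, or
`inst/scripts/trajmix.R` from a shell) adds the stratified correlation
workflow and writes per-stage CSV/JSON outputs plus a Markdown summary.

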