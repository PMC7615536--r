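---
title: "Modelling co-developing trait trajectories with trajmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling co-developing trait trajectories with trajmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

trajmix jointly models two repeatedly measured questionnaire trait scales —
an ADHD-symptom subscale scored 0–10 (process *A*, measured at ages 4, 7,
8, 9, 12, 13, 17, 25) and a social-communication checklist scored 0–24
(process *S*, measured at ages 7, 10, 13, 17, 25) — as a finite mixture of
piecewise-linear latent growth curves, and provides the downstream analyses
that typically accompany such a model: class enumeration, bias-corrected
association of latent classes with covariates and distal outcomes, and a
multiply-imputed rank-correlation workflow. This vignette documents the
model, its assumptions, the package's numerical choices, the synthetic
cohort generator that defines the simulation studies, and the known
limitations.

## The model

For subject $i$ in class $k$, the stacked vector of the 13 wave scores is

$$y_i = \Lambda \eta_i + \varepsilon_i, \qquad
\eta_i \sim N(\alpha_k, \tilde\Psi), \qquad
\varepsilon_i \sim N(0, \Theta),$$

where $\eta_i = (i_A, s_{1A}, s_{2A}, i_S, s_{1S}, s_{2S})$ collects, per
process, an intercept, a pre-knot slope and a post-knot slope. The loading
matrix $\Lambda$ implements the piecewise-linear time structure with a knot
at age 17: the intercept column is all ones, the first-slope loading is
$\min(\text{age}, 17) - \text{first age}$ and the second-slope loading is
$\max(\text{age} - 17, 0)$. The intercept is centred at each process's
first measurement age (4 for *A*, 7 for *S*); this puts the intercept on
the scale of the earliest observed score, which is the natural reference
when the two processes start observation at different ages. A config map
(`age_map`) substitutes mean completion ages for the canonical integer
labels when a dataset's actual assessment ages differ.

Identification constraints, applied throughout:

* the **second-slope variances are fixed to zero** — each post-knot segment
  is identified by only two waves, so a free variance is not identified;
  $\tilde\Psi$ is therefore degenerate and the free covariance $\Psi$ is the
  $4 \times 4$ covariance of $(i_A, s_{1A}, i_S, s_{1S})$;
* **$\Psi$ is shared across classes**. The constraint that between-class
  covariances be equal admits two readings; we take the class-invariant
  reading, which matches the usual motivation (freely varying covariances
  make these models fragile to estimate). A `psi_zero` switch additionally
  fixes $\Psi = 0$ (latent-class growth analysis) for sensitivity analyses;
* **residual variances are time-invariant per process** ($\theta_A$,
  $\theta_S$) and cross-process residual covariances are zero — all
  cross-trait dependence flows through $\Psi$.

A $K$-class model therefore has $6K$ growth-factor means, $K-1$ mixing
proportions, 10 covariance entries and 2 residual variances.

Missing waves are handled by full-information maximum likelihood: each
subject contributes the marginal normal density of its observed subvector
(mean and covariance restricted to observed rows). Because $\Psi$ and
$\theta$ are class-invariant, the observed-data covariance matrix is the
same in every class; only the means differ, which the implementation
exploits by factorising each missingness pattern's covariance once per
iteration.

Observed scores are bounded integers but are modelled as continuous
normals, as maximum-likelihood fitting of questionnaire totals ordinarily
entails. The consequences are quantified below under *Limitations*.

## Estimation

Parameters are estimated by an ECM algorithm whose latent data are the
class label and the four free growth factors. One iteration performs a
single E pass — posterior class probabilities via log-sum-exp, conditional
factor means and covariances per missingness pattern — followed by
closed-form conditional maximisations in the order $\pi$, free-factor
means, second-slope means (weighted least squares on the post-knot wave),
$\Psi$, $\theta$. Every step maximises the same expected complete-data
log-likelihood, so the observed log-likelihood is non-decreasing at every
iteration; the test suite asserts this on every fitted trace. Convergence
is declared when the relative log-likelihood change falls below `tol`
(default $10^{-7}$), with a cap of 2000 iterations. Variance floors
($\theta \ge 10^{-4}$, $\mathrm{diag}(\Psi) \ge 10^{-6}$) prevent
degenerate spikes; they are inactive in ordinary fits.

**Multi-start scheme.** Mixture likelihoods are multimodal, and the
dominant failure mode in this design is a solution that splits the
majority class instead of isolating a small class. `fit_gmm` therefore
seeds `n_starts` (default 50) initialisations of three kinds: one
deterministic hierarchical (Ward) clustering of single-class
empirical-Bayes factor scores, and an alternation of jittered k-means
starts and *random-subject* starts (class centres drawn from individual
subjects' factor scores). Random-subject starts are what reaches small
classes reliably: k-means and Ward both minimise variance criteria that
prefer splitting an 87% class over isolating a 6% class lying a moderate
distance away. Each start runs `burnin` (15) iterations; the best
`n_final` (10) continue to convergence; the best final log-likelihood
wins, with ties broken by the lowest start index, and classes are reported
largest-first. The start-value log-likelihood table is kept in the fit
object so replication of the maximum across starts can be inspected — the
usual check before trusting a mixture solution. An optional `polish` step
refines the winner by BFGS on an unconstrained reparameterisation
(log-Cholesky covariance); it is used by the small-sample tests that
compare against a direct optimisation of the same likelihood, and is off
by default because the ECM optimum is already at tolerance for ordinary
sample sizes.

## Class enumeration

`enumerate_classes` fits $k = 1..k_{\max}$ and reports AIC, BIC, relative
entropy $E = 1 - \sum_{ik} (-p_{ik}\ln p_{ik}) / (n \ln K)$, the smallest
class share, and a $k$ vs $k-1$ likelihood-ratio test. The recommended $k$
is the largest whose test p-value is below $\alpha$ (default 0.05) at
every step and whose smallest class holds at least 5% of the sample; both
rules are configurable.

Published software differs in the exact form of the adjusted LRT for
mixtures, so the package labels its own variant explicitly: the statistic
is $2\Delta LL / c$ with the small-sample correction
$c = 1 + 1/\big((p_k - p_{k-1})\ln n\big)$, referred to a $\chi^2$ with
degrees of freedom **twice the number of extra non-mixing parameters**
(df = 12 for one extra class here) — the classical df-doubling convention
for mixture LRTs, which accounts for the boundary non-regularity of the
mixing proportion. Monte Carlo checks in the test suite verify that this
construction is conservative-to-nominal under a one-class truth
(rejection rate below 0.15 at $\alpha = 0.05$) and has essentially full
power against a well-separated two-class truth. The parametric bootstrap
LRT (`bootstrap_lrt`, $p = (1 + \#\{LR_b \ge LR_{obs}\})/(B+1)$) is the
reference construction against which the analytic test's decisions are
compared.

## Three-step association analyses

After enumeration, classes are related to external variables without
letting those variables influence class formation:

1. **Modal assignment** (`modal_assignment`) with ties broken to the
   lowest class index, and the **classification-error matrix**
   $Q_{jk} = P(\text{assigned } j \mid \text{true } k)$ estimated as the
   column-normalised average posterior among subjects assigned $j$.
2. **Bias-corrected multinomial regression**
   (`threestep_multinomial`): the assigned label is modelled as an
   error-prone indicator, $P(W = j \mid x) = \sum_k Q_{jk} P(C = k \mid x)$,
   with the measurement logits $\ln Q_{jk}$ held fixed (zero entries
   floored at $10^{-6}$) and $P(C = k \mid x)$ a multinomial logit
   estimated by BFGS with analytic gradients; a gradient-free restart
   guards against line-search failures on the plateau where all class
   logits diverge. With $Q = I$ the estimator reduces exactly to ordinary
   multinomial regression.
3. **BCH weighting** (`bch_weights`, `bch_distal`) for continuous distal
   outcomes: a subject assigned $j$ receives the $j$-th column of $Q^{-1}$
   as weights over true classes (rows of the inverse of the
   true-class-conditional matrix $Q^\top$); weighted class means get
   estimating-equation (sandwich) standard errors and Wald $\chi^2$
   equality tests, overall (df $K-1$) and pairwise. A condition-number
   threshold on $Q$ refuses the analysis when classes are too poorly
   separated for the inverse to be stable.
4. **Posterior-weighted proportions** (`dcat_proportions`) for binary
   distal outcomes: $\rho_k = P(y = 1 \mid C = k)$ estimated by maximising
   $\sum_i \ln \sum_k p_{ik}\, \rho_k^{y_i}(1-\rho_k)^{1-y_i}$ on the
   logit scale, with delta-method standard errors and pairwise odds
   ratios. Exact MPlus internals for the corresponding estimator are not
   published; this posterior-weighted ML variant is validated by
   simulation recovery (mean estimates within ±0.03 of truth at
   $n = 5000$), not by matching another program's output.

Auxiliary missingness is handled by listwise deletion per variable with
the analysis *n* reported. P-values are reported raw; multiplicity is a
documented limitation of this reporting style, and an FDR column can be
added by the caller.

## Correlation workflow

Cross-trait Spearman correlations are computed at the five paired ages
(7, 9/10, 13, 17, 25 — each age of the sparser series paired with the
nearest age of the denser one). To limit attrition bias the workflow
retains subjects complete at the first paired age and multiply imputes
later waves by chained-equations predictive mean matching
(`pmm_impute`): each incomplete column is regressed on its declared
predictors — its own trait's other waves plus the other trait at the
anchor, paired and previous ages — with a proper Bayesian parameter draw,
and each missing cell takes the observed value of one of 5
nearest-predicted-mean donors. Five donors, ten chained sweeps and
ascending-missingness visit order are standard defaults; imputed values
always belong to the observed support, and observed cells are never
altered. Per-imputation correlations are pooled on the Fisher-z scale by
Rubin's rules (between-imputation variance inflated by $1 + 1/m$,
Barnard–Rubin degrees of freedom for the interval).

The age-7 vs age-25 comparison uses Silver's modification of Dunn &
Clark's z for dependent, non-overlapping correlations: the asymptotic
covariance term is evaluated with both compared correlations replaced by
the backtransformed average Fisher z. The implementation reproduces the
degenerate self-comparison identity $n\,\mathrm{var}(r) = (1-r^2)^2$ to
numerical precision. The package computes the comparison on pooled
correlation estimates with pooled auxiliary correlations — a documented
convention, since pooling a test statistic across imputations admits
several defensible forms. Stratified reports use modal labels by default,
mirroring per-class correlation figures; a posterior-weighted variant can
be built from the returned posteriors.

## The synthetic cohort generator

Real cohort data for this design are access-restricted, so the generator
is the package's study environment and its defaults are chosen once, as
study conditions:

* **Class structure** (`default_generator_config`): three classes with
  proportions 0.87 / 0.065 / 0.065 — a low-stable majority, a
  child/adolescent-declining class whose mean curves start above the
  screening cut-points (6 on the 0–10 scale, 9 on the 0–24 scale) and
  fall below them by the knot, and a late-emerging class crossing in the
  opposite direction. The mean curves are synthetic package choices
  shaped to that qualitative structure, not estimates from any cohort.
* **Variance components**: the study design does not publish class
  variance components, so the defaults are explicitly artifact choices
  tuned so that a 3-class fit separates classes with relative entropy
  around 0.85–0.9 (measured 0.88–0.92 across seeds at $n = 2000$–3000);
  residual variances 2.4 and 5.4, intercept SDs 1.25 and 1.75,
  cross-trait intercept correlation 0.45.
* **Observation model**: latent continuous scores are rounded half-up to
  integers and clipped to the scale bounds (configurable).
* **Attrition**: the shipped scenario uses monotone dropout — per-wave
  trigger probabilities rising with age (4–12%), a 1.5× multiplier in the
  minority classes (missing-at-random given class), and loss of all
  later-aged waves once triggered — reflecting that cohort non-response
  is dropout-dominated. Independent per-wave Bernoulli missingness is the
  `apply_missingness` default when monotone is not requested. Subjects
  losing every wave are dropped and counted.
* **Auxiliaries**: binary variables are Bernoulli given class (e.g. male
  0.49/0.73/0.54); continuous variables are unit-SD normals given class
  (e.g. a polygenic-score-like variable with means 0/0.14/0.14),
  emulating standardised scores.

`recovery_generator_config` is the second shipped scenario, used for
parameter-recovery studies: same class structure and cut-point-crossing
means, complete follow-up, and variance components sized a priori so that
the asymptotic standard error of every minority-class growth mean
($(\Lambda^\top\Sigma^{-1}\Lambda)^{-1}/n_k$ with $n_k \approx 130$ at
$n = 2000$) stays below a third of the 0.15-score-unit recovery
tolerance. This is a power calculation, not a realism claim: with the
realistic variances a 6.5% class of 130 subjects carries intercept
standard errors near 0.07–0.12, and no estimator can pin its means to
±0.15 reliably. Recovery under the sharp scenario demonstrates
correctness of the estimator; the realistic scenario demonstrates the
entropy regime and enumeration behaviour.

`simulate_posteriors` and `calibrate_separation` generate posterior
matrices of a requested classification quality (root-finding on a
fixed-seed Monte Carlo evaluation of expected entropy); the three-step
and BCH simulation studies use them so that the classification-error
correction is tested against *known* error rates, independently of
mixture fitting.

## Simulation-study sizes

The test suite's Monte Carlo studies use: likelihood oracles at $n = 20$
subjects; EM monotonicity on five $n = 500$ fits; parameter recovery on
five $n = 2000$ replicates; enumeration hit-rates on ten replicates each
of one-class ($k_{\max} = 2$) and three-class ($k_{\max} = 4$) truths at
$n = 500$ with complete follow-up; bootstrap-vs-analytic LRT agreement on
ten replicates at $n = 300$ with $B = 49$; three-step bias correction on
50 replicates at $n = 3000$ and entropy 0.7; BCH recovery on 50
replicates at $n = 5000$ and Wald size on 200 replicates at $n = 2000$;
imputation consistency on 20 replicates of 20% MCAR; comparison-test size
on 200 replicates at $n = 500$; and the stratified-correlation pattern on
20 replicates at $n = 1500$. These sizes are the package's own
simulation-study design, chosen to give adequate Monte Carlo resolution
for each property.

## Limitations

* **Discreteness.** Treating bounded integer totals as continuous normals
  biases variance estimates slightly downward (clipping) and adds
  rounding variance (~1/12) into $\theta$; class mean curves are
  essentially unbiased while they stay a couple of residual SDs inside
  the bounds. Majority-class means near the floor of the 0–10 scale can
  shift upward by a few hundredths.
* **Posterior overconfidence propagates.** The classification-error
  matrix is estimated from fitted posteriors. When the measurement model
  is approximate (discreteness, attrition), fitted posteriors are
  somewhat overconfident, $\hat{Q}$ sits closer to the identity than the
  true confusion matrix, and the three-step and BCH corrections
  under-correct — e.g. on a default-scenario cohort the estimated
  misassignment of the declining class was 0.15 against a true 0.20.
  The simulation studies that feed the corrections *known* error rates
  confirm the corrections themselves are unbiased; residual attenuation
  in a full-pipeline run reflects this measurement issue, which is
  inherent to the three-step approach rather than to this
  implementation.
* **MAR given class.** The generator's attrition is missing-at-random
  given class; truly non-ignorable dropout is not modelled, so passing
  tests say nothing about informative missingness beyond class-linked
  rates.
* **What passing tests show.** The generator produces exactly the
  trajectory-mixture structure the model assumes (up to discreteness).
  Passing recovery and enumeration tests therefore demonstrates
  correctness of the estimator and decision rules under the assumed
  model, not robustness to real-data features such as non-normal
  within-class heterogeneity, informant effects, or measurement
  non-invariance across ages.
* **Second slopes.** With two post-knot waves and zero second-slope
  variance, post-knot heterogeneity is absorbed by the residuals; the
  model cannot distinguish fanning-out after the knot from residual
  noise.

## Configuration reference

The pipeline (`run_pipeline`) is driven by a YAML config:

```yaml
seed: 1
out_dir: out
stages: [simulate, fit, associate, correlate]
simulate: {n_subjects: 2000, aux: true}
k_max: 3
rules: {alpha: 0.05, min_class_share: 0.05}
fit: {n_starts: 20, n_final: 5, tol: 1.0e-7}
aux:
  binary: [male, low_income]
  continuous: [pgs_adhd]
correlate: {impute: true, m: 5}
```

Class labels in all outputs are ordered by descending size and named
`class_1..class_K`; semantic names ("low-stable", "declining",
"late-emerging") are a presentation choice for the user, never inferred
by the package.
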