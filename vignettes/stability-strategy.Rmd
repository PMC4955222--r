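---
title: "Selection stability of prognostic signatures under competing risks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection stability of prognostic signatures under competing risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-dimensional prognostic signatures — a few dozen gene-expression features
linked to a clinical event — are notoriously unstable: refitting the same
pipeline on a perturbed version of the same cohort often yields a largely
different feature list. In a competing-risks setting (here: death after a
cardiovascular event, cause 1, versus death without one, cause 2, in a
hemodialysis cohort followed for 24 months) instability has additional
sources: the choice between modeling the cause-specific hazard and the
subdistribution hazard, later updates of the endpoint classification, and a
handful of influential observations. `crstab` implements a resampling
strategy that makes these sources measurable: it quantifies per-feature
selection stability, exposes outlier-driven artifacts through the joint
selection behavior of feature pairs, and attributes stability differences to
explicit modeling choices with a regression model.

## Models and estimation

Observations are $(T_i, \Delta_i, \epsilon_i, X_i)$: observed time, event
indicator, event type in $\{1, 2\}$, and covariates (clinical plus
expression). Two regression models link covariates to the cause of interest:

* the **cause-specific hazard** model
  $h_{cs1}(t \mid X) = h_{0,cs1}(t) \exp(X'\beta)$, a Cox model in which
  other-cause events are censored at their event time;
* the **Fine–Gray subdistribution hazard** model
  $h_{sh1}(t \mid X) = h_{0,sh1}(t) \exp(X'\beta)$, directly linked to the
  cumulative incidence $F_1(t) = P(T \le t, \epsilon = 1)$. Subjects with a
  competing event remain in the risk set after their event time with weight
  $G(t-)/G(T_i-)$, where $G$ is the Kaplan–Meier estimate of the censoring
  distribution.

Both are estimated by Newton–Raphson maximization of the (weighted) Breslow
partial likelihood; ties are handled by the Breslow approximation throughout,
which keeps the two model families numerically consistent. Convergence is
declared when the relative change of the partial log-likelihood falls below
$10^{-9}$ (at most 50 iterations with step-halving). The engine is shared by
the low-dimensional fits (`fit_cox_cause_specific()`, `fit_fine_gray()`), the
per-feature screen (`univariate_screen()`, Wald p-values — one fit per
feature is the cheapest choice at tens of thousands of features), and the
boosting algorithm below; it is written in C++ because the stability analysis
refits the model hundreds of thousands of times.

### Componentwise likelihood-based boosting

`boost()` performs regularized multivariable estimation with a small set of
mandatory, unpenalized clinical covariates (age and prior cardiovascular
event by default). All candidate coefficients start at zero; each step
computes, for every candidate $j$, the penalized one-parameter update
$\Delta\beta_j = U_j / (I_j + \lambda)$ from the partial-likelihood score and
Fisher information at the current linear predictor, applies the update of the
candidate maximizing $U_j^2/(I_j + \lambda)$, and refreshes the mandatory
covariates. The number of steps is chosen by event-stratified 10-fold
cross-validation of the held-out partial likelihood
(Verweij–van Houwelingen contribution) when prediction is the goal, and fixed
at 100 steps for all stability runs, which fixes the model complexity across
subsamples.

Decisions the literature leaves open, and what this package does:

* **Penalty.** $\lambda = 9 \times$ (events of the modeled cause), the
  convention of the componentwise-boosting family this algorithm belongs to;
  exposed as an argument.
* **Standardization.** Candidates are standardized internally (mean 0, sd 1)
  because componentwise selection is scale-sensitive; candidate coefficients
  are reported on the standardized scale.
* **Mandatory refresh.** One Newton step per boosting step (with
  step-halving), not full re-convergence; `mand_full_refit = TRUE` gives the
  expensive variant. On all cohorts we generate the two agree closely.
* **Ties in the selection criterion** break towards the lowest feature index,
  for determinism.

### Stability analysis

`draw_subsamples()` draws B subsamples of size $\lfloor n/2 \rfloor$ without
replacement (default B = 10,000 at study scale; the test profile uses
B = 200, at which the standard error of an inclusion frequency $f$ is
$\sqrt{f(1-f)/B} \le 0.035$). `build_selection_matrix()` records, per
subsample, the signature of one modeling configuration: either the features
with nonzero boosting coefficients after 100 steps, or — to mimic the common
per-gene workflow — the $k$ features with the smallest univariate p-values,
with $k$ set to the rounded mean boosting signature size on the same
subsamples so both approaches select equally sparse signatures. Subsamples
with fewer than two events of the modeled cause are recorded as missing rows
and excluded from the frequency denominators rather than dropped silently.

`joint_selection_odds_ratios()` cross-tabulates the inclusion indicators of
every feature pair passing an inclusion-frequency threshold (default 0.1) and
reports $OR = n_{11} n_{00} / (n_{10} n_{01})$, with a continuity correction
of 0.5 added to every cell when any cell is empty (the source analyses do not
state their handling; 0.5 is the standard Haldane–Anscombe choice).
$OR \gg 1$ marks pairs selected together; $OR \ll 1$ marks alternative
selection, the signature of features carrying redundant — possibly
artifactual — information.

**Outlier flagging.** The original workflow identified influential
observations by visual inspection of scatter plots of features implicated by
the odds-ratio structure. `flag_outlier_observations()` makes this
algorithmic: robust z-scores $(x - \mathrm{med})/(1.4826 \cdot \mathrm{MAD})$
are computed per implicated feature and subjects exceeding a threshold
(default 4) on any of them are flagged; features with zero MAD are skipped.
The pipeline scans every feature in the odds-ratio table (all features with
inclusion frequency at least 0.1), which bounds the expected number of
falsely flagged subjects at roughly
$n \cdot m \cdot P(|Z| > 4) \approx 250 \cdot 80 \cdot 6 \times 10^{-5} \approx 1$
per run on clean Gaussian data, while `suggest_implicated_features()`
additionally reports mutually facilitating pairs (OR above 5) as the most
suspicious candidates for visual review with `plot_outlier_scatter()`. This
is a deliberate surrogate for a visual-inspection step, not a reproduction of
it; the threshold is exposed.

**Attribution to modeling choices.** For every feature reaching inclusion
frequency 0.1 under any configuration, `stability_regression()` fits a
binomial (logit) regression of the per-configuration inclusion counts on four
binary modeling choices — Fine–Gray vs cause-specific ("sh"), outlier
exclusion, original vs updated endpoint, univariate vs multivariable
selection — plus the five two-way interactions involving the hazard model and
the endpoint (the interaction of outlier handling with the selection method
is omitted, matching the term structure of the source analysis; factors that
do not vary in a restricted configuration grid drop out). Perfectly separated
patterns are flagged degenerate and reported as non-estimable rather than
given arbitrary coefficients. `multi_feature_stability()` applies Bonferroni
correction across features per term and tabulates counts of significantly
positive/negative effects.

### Prediction error

`run_prediction_error_study()` compares three models for the cause-1
cumulative incidence — the Aalen–Johansen null model, clinical covariates
only, and clinical + expression boosting with cross-validated steps — by
.632+ bootstrap prediction-error curves: B sets of $0.632n$ subjects drawn
*without* replacement (as in the source design; the .632+ weighting formula
is retained), model development repeated entirely on each in-bag set
(including the cross-validation), Brier score of the out-of-bag subjects
tracked over a grid of 40 equally spaced times up to the 95th percentile of
observed times. The inverse-probability-of-censoring weights use the
marginal censoring Kaplan–Meier of the full data: subjects with an event of
any cause by $t$ are weighted $1/G(T_i-)$ (a cause-2 event counts as status
0, consistent with cumulative-incidence prediction), subjects still
event-free at $t$ are weighted $1/G(t)$, and subjects censored before $t$
contribute nothing. The no-information error pairs every subject's outcome
with every subject's prediction. `compare_models()` integrates the
per-bootstrap difference of two models' out-of-bag curves over the grid
(trapezoidal rule) and applies a two-sided Wilcoxon signed-rank test across
bootstrap sets.

## The synthetic cohort generator

The cohort the strategy was developed on is not publicly available, so
`generate_cohort()` builds cohorts with the structure the strategy assumes,
plus ground truth, making every stage testable:

* **Expression**: correlated Gaussian blocks,
  $x = \sqrt{\rho}\, z_{block} + \sqrt{1-\rho}\, \varepsilon$ (default blocks
  of 10 at $\rho = 0.5$). Truly prognostic features sit at the head of their
  own block, so each competes with nine correlated null neighbours — the
  mechanism that caps realistic inclusion frequencies well below 1.
* **Event times**: latent cause-specific exponential hazards with linear
  predictors over the informative features (default log-HR 0.5 per SD — a
  hazard ratio of about 1.65, typical for a strong single prognostic
  marker), age (log-HR 0.3 per SD on both causes) and prior cardiovascular
  event (log-HR 0.5 / 0.2 on causes 1/2; prevalence 0.3); observed time is
  the minimum of the two latent times, exponential dropout, and
  administrative censoring at 24 months. Because simulation is cause-specific,
  ground-truth effects live on the cause-specific scale; subdistribution
  recovery checks therefore assert signs and rankings, not coefficient
  values.
* **Scales**: the default desk profile (n = 250, p = 500, 5 informative
  features per cause) keeps $p \gg$ events while running the full pipeline in
  minutes. `study_spec()` reproduces the study conditions — n = 321 over 24
  months with baseline rates 0.0026 / 0.0079 per month, calibrated by
  Monte-Carlo so the expected event counts match the reported 30 deaths with
  and 71 without a prior cardiovascular event; the feature count defaults to
  the study's ~26k but the event-time distribution does not depend on the
  number of null features, so tests reduce it.
* **Outliers**: three subjects receive values shifted by 6 SD on two null
  features inside the first informative feature's block (a shared aberrant
  measurement). The subjects are cause-1 events whose *idiosyncratic*
  component of that informative feature is smallest: their events are not in
  line with the true feature's trend, so the aberrant values manufacture a
  spurious competitor that suppresses the true feature, and excluding the
  three subjects lets it recover. Selecting on the idiosyncratic component
  rather than the observed value keeps their target-feature values unbiased,
  so the injected extremes sit near robust z of 6.
* **Endpoint update**: random reclassification between the three endpoint
  categories with fractions (none→1: 0.015, none→2: 0.05, 1→2: 0.2,
  2→1: 0.03) mirroring the order of magnitude of the reclassifications
  reported for the study cohort, whose exact counts do not reconcile
  arithmetically and are not reproduced.

What the generator does **not** emulate: microarray-specific noise (dye bias,
print-tip effects, intensity-dependent variance), non-Gaussian expression
distributions, clinical covariates beyond age and prior events, and
covariate-dependent censoring. Passing tests therefore demonstrate that the
machinery recovers structure of this idealized form; they do not certify
behavior under assay-specific artifacts.

## Validation design and problem sizes

The test suite validates every estimator against an independent route:
partial-likelihood optima against derivative-free (Nelder–Mead) maximization
of brute-force likelihood implementations on small instances, and against
`survival::coxph` / `cmprsk::crr`; the Aalen–Johansen estimator against
hand-computed increments and `cmprsk::cuminc`; Benjamini–Hochberg selection
against its step-up definition; the binomial stability regression against
direct likelihood maximization. Monte-Carlo checks use the generator:
selection-recovery runs use the desk profile with B = 200 subsamples and 20
replicates, evaluating each cause's informative features under the boosting
model for that cause and pooling both causes (the cause-1 profile alone, with
only about 40 events, leaves an informative feature dominated by a correlated
block-mate in a nontrivial fraction of cohorts — the very instability the
package measures); recovery is assessed on cohorts *without* injected
outliers, since the outlier scenario is analyzed separately (injected
outliers by design suppress true features, which would confound a recovery
measurement).
The prediction-error studies in the tests use reduced sizes (n around
120–200, B of 15–30 bootstrap sets, at most 30 cross-validation steps) —
chosen so the full suite runs in minutes on one CPU while leaving every
qualitative contrast (null vs clinical vs combined model ordering) intact.

## Known limitations

* The Fine–Gray implementation supports neither time-varying covariates, nor
  stratified baselines, nor left truncation.
* Standard errors are model-based (inverse observed information); the
  sandwich variance usually reported for Fine–Gray models is not implemented,
  so p-values from `fit_fine_gray()` under heavy censoring are mildly
  optimistic. The stability machinery does not use these p-values.
* The univariate screen records non-converged per-feature fits as p = 1
  rather than failing; with pathological features this is conservative.
* `dot632plus()` clips the relative-overfitting ratio into [0, 1]; when the
  out-of-bag error exceeds the no-information error the estimate equals the
  no-information error, which can understate the error of badly overfit
  models.
* With B = 200 subsamples, inclusion-frequency differences below about 0.07
  are within resampling noise; B should be raised to the study-scale 10,000
  for publication-grade frequency tables.
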