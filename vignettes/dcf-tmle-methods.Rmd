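---
title: "Methods: generalized double cross-fitted TMLE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generalized double cross-fitted TMLE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Estimand and identification

`dcftmle` estimates the average treatment effect on the risk-difference
scale, ψ = E[Y¹ − Y⁰], for a binary treatment A and binary outcome Y given
covariates L. Identification rests on the usual assumptions: no unmeasured
confounding given L, positivity (0 < P(A=1|L) < 1), consistency, and no
interference. Nothing in the package checks these for you; the synthetic
mechanisms below satisfy them by construction.

## TMLE and the targeting step

Given initial estimates g(L) = P(A=1|L) and q(a,L) = P(Y=1|A=a,L), the
targeting step fits the one-parameter logistic fluctuation

    logit q_ε(A,L) = logit q(A,L) + ε · H(A,L),
    H(A,L) = A/g(L) − (1−A)/(1−g(L)),

by offset maximum likelihood without an intercept (`tmle_target()`). The
updated predictions q*(1,L), q*(0,L) give the plug-in estimate
ATE = mean(q*(1,L) − q*(0,L)), and the defining property of the update is
that the clever-covariate score mean(H·(y − q*)) is numerically zero
afterwards. The influence curve on an estimation set of size m is

    IC_i = H_i (y_i − q*_i) + (q*(1,L_i) − q*(0,L_i)) − ATE,

and the split-level variance is Var(IC)/m.

Numerical choices: a single signed-ε fluctuation (rather than separate
ε₀, ε₁) for parity with the most common TMLE implementations; the
fluctuation is solved by IRLS (`glm.fit`) with convergence tolerance
1e−12 and at most 100 iterations, and a non-convergent fit signals a
split failure rather than returning a number. Propensity predictions are
truncated to [0.01, 0.99] and outcome predictions to [0.0005, 0.9995]
before any logit; the tighter propensity bound guards the unbounded
1/g weights, the looser outcome bound only protects the logit transform.
These bounds are stability choices, not estimates, and are deliberately
exposed as arguments of `tmle_target()` for sensitivity analysis.

## Double cross-fitting

With flexible nuisance learners, using the same records to fit a nuisance
model and to evaluate the influence function requires a Donsker-class
complexity restriction. Double cross-fitting removes it: the propensity
model, the outcome model and the effect evaluation each use pairwise
disjoint index sets. The package partitions the data into p ≥ 3
near-equal random splits (`make_splits()`; sizes differ by at most one)
and assigns roles in one of two ways.

**Generalization 1 (equal splits, `roles_gen1()`).** For estimation split
s, the propensity model trains on split s−2 and the outcome model on
split s−1 (labels mod p). Every split serves each role exactly once per
repetition; for p > 3, the other p−3 splits sit out of that particular
split-estimate. The orientation — which neighbour trains which model —
is statistically exchangeable, and the reverse convention is equally
valid; this one is fixed and documented because it makes the p = 3
equivalence below exact.

**Generalization 2 (full data use, `roles_gen2()`).** For estimation
split s, the remaining p−1 splits are alternated in cyclic order after
s: odd offsets train the propensity model, even offsets the outcome
model. Each nuisance model therefore trains on (p−1)/2 splits ≈ n/2
records regardless of p, which is the point: nuisance stability no
longer degrades as p grows. This requires odd p. At p = 3 the role
triples coincide exactly with Generalization 1 — with both schemes fixed
as above, a shared seed yields bit-identical repetition estimates, which
the test suite asserts. For even p a fallback (off by default, behind
`allow_even_p`) pools the p−1 non-estimation splits and re-splits the
pooled records into two equal halves.

## The three aggregation layers

Within a repetition, the p split estimates are averaged:
ATE_r = (1/p) Σ_s ATE_s. For the repetition variance the package uses
the variance of a mean of independent estimates computed from disjoint
data: var_r = (1/p) Σ_s Var_s(IC)/n, i.e., the split-level IC variances
referred to the full sample size and averaged. The superficially natural
alternative — averaging the per-split variances Var_s(IC)/n_s directly —
estimates the variance of a *single* split estimate and is too large by
a factor of about p; it produces standard errors inconsistent with the
observed sampling variability at every p (about +95% relative SE error
at p = 3 in our own calibration runs), so it is not used.

Across repetitions (fresh random partitions each time, r of them):

    ATE = median_r(ATE_r)
    var = median_r( var_r + (ATE_r − ATE)² )

The between-repetition term charges the variance for the splitting noise
visible across repetitions. Medians are used so that occasional wild or
failed repetitions cannot dominate; with an even number of successful
repetitions the median is the mean of the two central order statistics.
Failed repetitions are excluded from both medians and reported in
`n_failed`; an optional retry mode (`retry_failed`, off by default)
re-runs a failed repetition under fresh child seeds instead.

## Super learner

Both nuisance models are fit by `fit_super_learner()`: V-fold
cross-validation (default 10 folds, stratified on the outcome so sparse
events spread across folds), candidate out-of-fold predictions combined
with simplex-constrained weights, candidates refit on the full training
set for prediction. The meta-learning objective is the cross-validated
negative Bernoulli log-likelihood — the canonical choice for probability
estimation — minimised over the simplex by L-BFGS-B on a nonnegative
reparametrisation w = x/Σx, started from the uniform point and from
every vertex; the vertices themselves are also evaluated, so the
ensemble's CV risk never exceeds any single candidate's (asserted in the
tests to 1e−8). A single-candidate library skips cross-validation
entirely (the simplex is a point).

The default roster (`default_learners()`) and the frozen hyperparameters:

| learner | details |
|---|---|
| `logit_main_effects` | untransformed main effects, IRLS; aliased columns contribute zero |
| `gam_4_splines`, `gam_6_splines` | `mgcv` smooths with basis dimension k = 4 / 6 per continuous covariate (more than 10 distinct values); binary covariates enter linearly; REML |
| `nnet_2_hidden` | one hidden layer, 2 logistic units, weight decay 1e−4, maxit 500, seeded initialisation |
| `random_forest_500_minleaf20` | 500 trees, terminal node size ≥ 20, probability votes |
| `empirical_mean` | the training-set event rate |

"Basis dimension per continuous covariate" is the standard GAM-wrapper
reading of a spline budget; the decay and iteration cap for the neural
net are stability choices for a 2-unit probability net. Candidates that
fail on any fold, or on the full-data refit, are dropped with a warning
and the weights renormalise over the survivors; if the training outcome
is constant or every candidate fails, a `dcftmle_degenerate_outcome`
condition is raised and the enclosing repetition is marked failed. This
is the realistic failure mode with many sparse binary covariates, and it
is why the aggregation layer tolerates missing repetitions.

## Reproducibility and seeding

Every stochastic component draws from a deterministic child-seed stream:
repetition j of root seed S runs under `child_seed(S, j)`, and each
nuisance fit within it under a further (split, role)-indexed child. Three
consequences: results are independent of execution order (repetitions
could run concurrently with identical output); the first r₁ repetitions
of an r₂ > r₁ run are bit-identical to the r₁ run, so
repetition-sensitivity curves (r = 1, 5, 25, …) never refit anything;
and any single repetition can be reproduced in isolation from the run
manifest that the CLI writes. The same scheme seeds the simulation
harness per dataset, which is what makes `run_scenario()`'s resume mode
(skip rows already present in the output CSV) exact.

## Synthetic data-generating mechanisms

`generate_dataset()` emulates a statin-initiation / cardiovascular-event
setting: five covariates — age (years, uniform 40–75), natural-log LDL
cholesterol (normal around 4.7 + 0.005·age, SD 0.2), diabetes and
frailty indicators (logistic models with quadratic and exponential
terms), and a unitless risk score (a logistic function of the others
with an age×LDL interaction) — a binary treatment assigned with
confounding by indication (higher-risk, sicker individuals are more
likely treated; marginal treatment prevalence ≈ 0.32, propensities
within (0.08, 0.90)), and a binary outcome (marginal risk ≈ 0.14) whose
risk is lowered by treatment with effect modification by LDL. All
coefficients live in a single auditable record, `dgm_coefficients()`,
and the truth ψ ≈ −0.081 is always *computed*, by large-sample
potential-outcome simulation (`true_psi()`, independent Bernoulli draws
under each arm, Monte Carlo SE reported), never hard-coded; zeroing the
two treatment coefficients recovers ψ = 0 within Monte Carlo error. The
crude treated-minus-untreated contrast is ≈ +0.013 — the mechanism's
confounding reverses the sign of the association, a deliberately hostile
test for the estimators. Nonlinearities and interactions in the
structural equations mean that main-effects learners are misspecified,
as intended.

This mechanism emulates the *statistical structure* of the
cardiovascular simulation settings used in the cross-fitting literature;
the exact published coefficient values were not available to transcribe,
so these were chosen once for epidemiological plausibility and are
documented here as the package's own study conditions. What it does not
emulate: survey-design features, high-dimensional or sparse covariate
sets, measurement error, or missingness — conclusions from these
simulations speak to low-dimensional confounding with smooth
nonlinearities only.

`generate_simple_dataset()` is the package's exact-truth device: one
uniform covariate, logistic treatment and outcome models, and a
treatment coefficient solved by numerical integration plus root-finding
so the marginal risk difference equals a requested value exactly. It
underpins parameter-recovery and double-robustness tests that need a
truth independent of any Monte Carlo draw.

## Performance measures

`performance()` computes, per estimator: bias; empirical SE (SD of the
estimates); average model SE as sqrt(mean(SE²)) — the convention of the
standard simulation-study tooling — with the arithmetic mean reported
alongside as `avg_model_se_mean`; relative SE error
100·(avg model SE / empirical SE − 1); MSE; coverage of the nominal 95%
intervals; bias-eliminated coverage (coverage of the mean estimate,
isolating variance-calibration from bias); and the Monte Carlo SE of
each via the standard formulas (e.g., √(c(1−c)/S) for coverage,
empSE/√(2(S−1)) for the empirical SE, delta method for the ratio).
Failed or flagged datasets are excluded with their count reported.
Constant estimates make the relative SE error undefined; it is returned
as `NA` rather than ±Inf. `zip_data()` exports the truth-centred
intervals ranked by |z| for zip plots; plotting itself is left to the
user so the core stays headless.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen as the package's own verification budget: parameter recovery uses
50 Monte Carlo datasets of n = 3000 (p = 5, r = 25, logistic-only
roster); the calibration grid uses 100 datasets of n = 3000 with r = 10
over p ∈ {3, 5, 10} (Generalization 1) and p ∈ {3, 5, 9}
(Generalization 2); truth simulations use 1–2 million potential-outcome
draws (MC SE ≈ 0.0003). The single-candidate logistic roster keeps the
entire pipeline identical while collapsing the super learner to a unit
weight.

Two limitations of that budget are worth stating plainly. First, with a
parametric logistic nuisance roster the influence-function SE is known
to be mildly conservative (estimating a correctly-parametrised
propensity *improves* the efficiency of the effect estimate relative to
plugging in the truth, while the IC variance does not credit it); we
measure roughly +8–14% relative SE error across configurations,
including for the non-cross-fit comparator. Second, the fine-grained
dependence of SE calibration on the number of splits — degradation of
flexible learners as training splits shrink under Generalization 1
versus their stability under Generalization 2 — is a property of
data-adaptive learners (notably the random forest) at full simulation
scale (thousands of datasets, r ≈ 100); it is not expected to be
detectable, and in our runs is not reliably reproduced, with fast
parametric learners at 100 datasets and r = 10, where the Monte Carlo SE
of a relative SE error is itself ≈ 8 percentage points. Passing
desk-scale tests therefore validates the estimator's correctness,
reproducibility and calibration machinery — not the full-scale
learner-complexity phenomena, which require the full roster and
cluster-class compute via the same `scenario_config()` interface.

## Known limitations

* Binary treatment, binary outcome, risk-difference scale only; no
  continuous outcomes, no survey weights, no CV-TMLE variant.
* Generalization 2 with even p exists only behind the explicit pooling
  flag; the default refuses rather than silently unbalancing roles.
* The failure policy drops repetitions; if failures correlate with the
  data pattern (e.g., rare outcomes), the surviving-median estimate is
  conditional on fit success. The retry mode trades this for extra
  computation.
* `set.seed()` is called internally by the generators and fitting
  functions; callers holding their own RNG state should isolate it.
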