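---
title: "Models and methods for days-alive-without-life-support outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for days-alive-without-life-support outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Days alive without life support (DAWOLS), days alive and out of hospital
(DAOH) and similar count outcomes compress a patient's whole trial
experience — survival *and* resource use — into a single number of days
within a fixed follow-up window. Their distributions are awkward: a heavy
point mass at the minimum (patients who die, conventionally assigned the
worst possible value), often a second point mass at the maximum (patients
never on life support before follow-up ends), and a skewed interior. This
vignette records how `dawols` defines these outcomes, which models it fits
and from what likelihoods, how estimands and diagnostics are computed, and
the numerical and design choices behind each step.

## Outcome construction

A patient-day is in exactly one of four states: `home`, `hospital`,
`life_support`, `dead`. Days are 1-based and the follow-up window is the
closed set `{1, ..., max_days}`; death is absorbing. The outcome is the
number of days in a configurable *free-state* set — `{home, hospital}`
gives DAWOLS, `{home}` gives DAOH; one code path serves both. Two
conventions deserve stating because the literature leaves them implicit:

* any day with state `life_support` counts as a supported day, including
  the days support starts and stops;
* the day of death is a dead day, never a free day.

Both choices are conservative (they never credit a questionable day as
free) and match the worst-outcome framing used for death handling.
Missing patient-days are a hard error, not imputed: the methods here
assume complete follow-up, and silently imputing daily states would
change the outcome definition.

Death handling is explicit and total: `penalize_zero` assigns
non-survivors 0 days, `penalize_minus_one` assigns the ordinal category
`-1`, strictly worse than every real value (only meaningful on the
ordinal scale), and `actual` keeps the observed free days. Survivors are
never modified, and the three rules are related by construction:
penalised outcomes never exceed actual ones, with equality exactly for
survivors.

## The four model families

All four families support any number of arms and covariates; covariates
enter every sub-model by default because a prognostic variable that
shifts the interior mean usually also shifts the probability of the
boundary values.

**Linear.** Gaussian likelihood for the day count. Means are typically
estimated well even under gross non-normality, but the predictive
distribution is unbounded in both directions — useful below as a
diagnosable misspecification.

**Hurdle negative binomial.** A logistic sub-model for `P(Y = 0)` and a
*zero-truncated* negative binomial for the positive counts, in the
mean–dispersion parameterisation (`Var = mu + mu^2 / phi`, log link).
The truncated count likelihood divides by `1 - NB(0; mu, phi)`; its
conditional mean `mu / (1 - p0)` is computed via `expm1` on the log scale
so it stays accurate when `p0` is near 1.

**Zero–one-inflated beta (ZOIB).** The outcome is rescaled to a
proportion of `max_days` (boundary membership decided on the integer
days, never by floating-point comparison). Three sub-models, factorised
as `P(boundary)`, then `P(one | boundary)`, then a beta density
(mean–precision, logit links) for the interior. This factorisation — and
not the alternative `P(zero)`, `P(one | not zero)` — is used throughout,
including in predictive simulation.

**Cumulative logistic.** Proportional-odds regression over the distinct
observed values as ordered categories, with `-1` as a death category
below all others. `P(Y <= k) = F(theta_k - x'beta)` with the logistic
CDF, so a positive arm coefficient favours higher (better) categories
and `exp(beta_arm)` is the cumulative odds ratio with that orientation.

## Inference engine

Point estimates are maximum likelihood. The multi-part likelihoods
factorise, so each part is maximised separately: logistic parts by IRLS
on data collapsed to unique covariate cells (exact for the binomial
likelihood), the Gaussian part in closed form, and the truncated-NB,
beta and cumulative-logit parts by BFGS with analytic gradients on
sufficient-statistic objectives. Constrained parameters are optimised
unconstrained: dispersions and precisions on the log scale, cutpoints as
a first cutpoint plus log-differences, which enforces strict ordering by
construction.

Uncertainty comes from a parametric bootstrap: `D` datasets (default
1000) are simulated from the fitted model at the observed design and
refitted, warm-starting at the parent estimate; the resulting `D x p`
draws matrix has the same downstream contract as a matrix of posterior
samples, and every derived quantity (group means, effect estimates,
RMSE/MAE, mean gaps) is computed per draw and summarised by the median
and the 2.5/97.5 percentiles. The package targets the regime where
flat-prior posteriors and the bootstrap sampling distribution agree; a
pluggable `engine = "sampler"` interface accepts a genuine posterior
sampler (with its own chains, warmup and convergence gating) for users
who want informative priors, but no MCMC backend is shipped.

Degenerate resamples are handled, not ignored: a logistic sub-model that
separates (an arm with 0% or 100% zeros or boundary values) falls back
to a penalised fit with zero-mean Gaussian shrinkage (sd 10 on the
intercept, 2.5 on slopes — weakly informative on the logit scale) and a
warning; non-convergence is retried once from a cold start and otherwise
flagged in the fit metadata, never silent.

## Estimands

Group expected means are assembled from *all* sub-models: `x'beta`
(linear); `(1 - pi) * mu / (1 - p0)` (hurdle); `(alpha gamma +
(1 - alpha) mu_b) * max_days` (ZOIB); and `sum_k v_k p_k` over the value
map (cumulative). For the cumulative model the death category is handled
both ways reports commonly need: remapped to 0 days before the weighted
sum (`minus_one_as_zero`) or kept at `-1` (`minus_one_as_is`).

Patient-level predictions are truncated to the valid space *before*
averaging — clamp-then-average, matching patient-level truncation — and
then averaged within arm. With covariates this is marginal
standardisation over the pooled analysis set (several of the sub-models
are non-collapsible, so conditional and marginal effects differ);
passing a single covariate row instead gives conditional-at-values
means. Mean differences and ratios of means are computed per draw
against the first declared arm (the control), one estimate per
non-control arm, so a ratio above 1 coincides with a positive difference
draw by draw. Percentile summaries use R's default type-7
(linear-interpolation) quantile rule everywhere; the choice of rule is
immaterial at `D = 1000` but is stated so results are exactly
reproducible.

## Model fitness

RMSE and MAE compare *expected-value* predictions — not predictive
draws — against the fitted data, per draw, on the days scale with deaths
coded 0. This matters: families as different as a Gaussian and a
three-part mixture produce near-identical RMSEs under expected-value
prediction, because in-sample both track the group means; predictive
draws would instead mix in each family's dispersion. MAE is the median
absolute error over patients within a draw, then summarised over draws
by the same median rule as everything else (the mean-over-draws reading
is the plausible alternative; the median keeps a single summary rule
package-wide). Evaluation is in-sample by default — the question is
whether the model can represent the data it was fit to — and a holdout
table can be passed explicitly. Information-criteria comparison is
deliberately absent: the families model different transformations of the
outcome (days, proportions, categories), so their likelihoods are not
comparable.

Predictive checks simulate replicated datasets under randomly chosen
parameter draws, discretise to whole days on the valid grid, and compare
per-arm histograms by total-variation distance. Calibration needs a
null with the same structure as the observed data: the observed outcomes
carry sampling variation only, while each replicate also carries a
parameter draw, so scoring replicates against each other would inflate
the null distances and flag well-fitting models as "too close" to their
data. The null therefore simulates pseudo-observations at the *point*
estimate, scores each one against the replicates exactly as the real
data are scored, and judges the observed statistic against the central
95% of those scores. A residual conservatism remains — the real data
produced the point estimate, a fresh pseudo-observation did not — which
leaves the observed statistic slightly low on average; this is the
familiar plug-in effect of in-sample predictive checks. The checks also
report per-replicate means and the proportions at the minimum and
maximum — the zero-share envelope is what exposes a linear fit to
zero-inflated data.

The proportional-odds diagnostic computes, per cutpoint, the empirical
cumulative log odds ratio between two arms with the Haldane–Anscombe 0.5
correction for empty cells. A flat profile is consistent with
proportional odds; a trend, and especially a sign change (mortality
effect opposing the survivor-days effect), is the pattern under which
the cumulative model pulls group means toward each other.

## The synthetic generator

`simulate_trial()` draws each patient through the mixture: death with
probability `p_death`; otherwise the maximum with probability `p_max`;
otherwise an interior free-day count from a negative binomial truncated
to `1..max_days - 1`. The truncated NB was chosen deliberately so the
hurdle-NB family is (nearly) correctly specified in at least one test
scenario; proportional-odds-consistent ordinal data come from a separate
generator (`simulate_po_trial()`) that samples the cumulative model
directly, because the mixture generator does not satisfy proportional
odds and the cumulative family deserves one test under its own
assumption. `scenario_true_mean()` gives the exact mixture mean by
summation, which anchors parameter-recovery and consistency tests to
closed-form truth.

`default_scenarios()` fixes the study conditions used across tests and
the acceptance script: two arms of 486 patients, 28-day follow-up,
mortality 32% vs 27%, `p_max` 0.40 vs 0.44, interior NB mean 23/24 with
dispersion 6. These values were chosen once to reproduce the published
shape of 28-day DAWOLS in a large ICU corticosteroid trial — observed
group means near 14.8 and 16.3 days with heavy inflation at both 0 and
28 — and are not tuned thereafter. The death-day distribution
(geometric with rate 0.15, truncated to the window) affects only the
daily-state expansion, never the outcome value. Each arm draws from its
own child random stream (a hash of the arm label mixed with the root
seed), so adding an arm never perturbs the others.

What the generator does *not* emulate: covariate-dependent mortality,
informative censoring or partial follow-up, readmission structure, or
interior distributions outside the NB shape (beyond a single optional
binary covariate shifting the interior mean additively). Tests passing
on these conditions show the machinery is correct under a realistic
shape, not that any family fits a given real trial.

## Numerical choices

* Optimiser: BFGS, relative function tolerance `3e-15` for point
  estimates (needed so saturated fits reproduce empirical frequencies to
  1e-6) and `1e-9` for bootstrap refits, which warm-start at the parent
  estimate.
* Starting values: empirical logits for logistic parts; log sample mean
  and method-of-moments dispersion for the count part; empirical
  cumulative logits for cutpoints.
* The cumulative-logit objective carries a `1e-8` ridge on the working
  parameters — a numerical guard that keeps cutpoints finite when a
  bootstrap replicate empties a category, with bias far below estimand
  precision.
* Interior beta draws are clamped away from exact 0/1 by `1e-12` so a
  simulated interior value can never be misclassified as a boundary
  value on refit.
* Degenerate inputs error early with named patients/days (daily-table
  validation), and a `-1` outcome reaching a proportion-scale model is
  an instructive error (recode deaths to 0 first), not a silent NaN.

## Problem sizes

The test suite exercises recovery and coverage at 1000 patients per arm
with 200 bootstrap draws over 100 replicates per family; type-I
behaviour at 500 per arm over 200 replicates; and predictive-check
calibration over 100 seeded runs — sizes at which bootstrap percentile
intervals are close to nominal while the full suite stays comfortably
runnable on a laptop. The acceptance script analyses one simulated trial
of 972 patients with 500 draws per family.

## Known limitations

Single imputation-free complete-follow-up design; no censoring or
competing-risk machinery; no informative priors (the sampler interface
exists, a backend does not); no partial proportional odds — a violated
PO assumption is *diagnosed*, not relaxed; and the win-ratio /
probabilistic-index family of estimands is out of scope. The cumulative
model's group means inherit the usual caveat that they depend on the
observed value set, and with `minus_one_as_is` the "mean" mixes a
penalty category into a days scale — both variants are reported so the
difference is visible rather than hidden.
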