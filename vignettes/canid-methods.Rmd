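---
title: "Scoring and evaluating the CANID battery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and evaluating the CANID battery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery in `canid`: the scoring
rules, the composite model and its frozen-constant projection, the
repeatability estimators, the longitudinal aging model, and the behavioral
simulator — including the numerical choices and the places where the design
was genuinely open.

## Trial-level scoring

**Spatial Reversal.**  A session is a side-choice trial (unscored), a
baseline block, and up to three reversal blocks.  A block ends when the dog
first approaches the open path on at least 3 of 4 consecutive scored
trials; `criterion_met()` evaluates this on the trailing window after each
scored trial, so the earliest possible criterion trial is the fourth and a
block has length 4–20, consistent with the measure's printed range.  The
three dependent measures are blocks completed (0–4, baseline included),
longest block entered (baseline included), and unused reversal trials out
of 20.  Two rules need care:

* *Worst score.*  A dog that never meets the baseline criterion within 20
  scored trials does not enter the reversal phase and is assigned blocks =
  0, longest block = 20, trials remaining = 0.
* *Cap mid-block.*  If the 20-trial reversal cap lands inside a block, the
  incomplete block counts toward the longest block (it was entered — the
  measure captures perseveration) but not toward blocks completed, which
  requires criterion.

No-choice administrations and their motivator trials do not consume trials
from the caps; the scored repeat replaces the original (the protocol
re-runs the trial, so only the final administration carries information).
Whether no-choice administrations should consume cap trials is not
determinable from the protocol description; we chose replacement because
the original trial is explicitly re-administered.  A sequence that stops
with the protocol unresolved (fear abort) yields missing measures rather
than a partial score.

**Delayed Search.**  Twelve trials in five types (4 no-delay, 2 at 10 s,
then 2 + 2 + 2 at 10/20/40 s with distraction); the measure is the
proportion of correct first searches per type, with terminal no-choices
reducing the denominator and four accumulated no-choices discontinuing the
task.  **Cylinder.**  Four trials; success is retrieving the reward
without first touching the cylinder exterior; dogs responding on three or
fewer trials are excluded (the proportion's denominator is fixed at 4).

## Composite scoring

`canid_fit()` estimates everything on baseline sessions and freezes the
constants; `predict()` reapplies them without refitting, so follow-up
sessions are projected into the baseline principal-component space.  The
order of operations is: task PCA → Yeo-Johnson (Spatial Reversal and
Delayed Search) → z-standardization → overall PCA → overall
z-standardization.  The steps themselves are fixed by the scoring system;
their order is not, and we place the normalization between the task and
overall PCAs so the overall component consumes comparable, roughly normal
inputs.  All standardization constants come from baseline only — using
pooled constants would leak follow-up information into the projection.

PCAs are computed on the correlation scale (inputs centered and scaled)
because the inputs are incommensurate — block counts against proportions.
The first component's sign is arbitrary in an eigendecomposition, so
orientation is pinned: positive loading for blocks completed (Spatial
Reversal), for the no-delay proportion (Delayed Search), and for the
Spatial Reversal score on the overall component.  With these conventions
higher scores mean better performance on every scale, and refitting on
any platform reproduces identical signs.

**Yeo-Johnson lambda** is estimated by maximizing the profile normal
log-likelihood over λ ∈ [−3, 3] with `stats::optimize()` (golden-section
search, tolerance 1e-6).  The bounded search keeps the estimate
reproducible and independent of optimizer defaults; the test suite checks
it against a 0.001-step likelihood grid and against
`car::powerTransform()`.

**Missing data** is handled at two levels, mirroring how the battery is
analyzed in practice.  Missing Delayed Search trial-type proportions
(dogs that stopped choosing) are imputed by predictive mean matching:
a pattern-specific linear regression on the observed trial types is fit on
the baseline complete-case donor pool, and the imputed value is the
observed value of one of the k = 5 nearest donors by predicted value,
drawn with a caller-supplied seed.  k = 5 is the conventional PMM default.
We impute at the proportion level (not the trial level) because the
proportions are the measures the PCA consumes; the donor pool guarantees
imputed values stay in the support of real scores.  A session missing
exactly one *task score* gets a deterministic regression prediction from
the two observed scores and test location (no noise term — the imputation
feeds a point estimate, not an inference about the missing score).
Sessions missing two or more task scores receive no overall score.
Both imputation models are fitted on baseline complete cases and reused at
follow-ups, consistent with the frozen-projection design.

## Repeatability

All ICCs are variance-component ratios `var(dog) / (var(dog) +
var(residual))`, truncated to [0, 1]:

* `pairwise_icc()` uses the dogs observed at both of two timepoints.  On
  this balanced subset the one-way ANOVA closed form
  `(MSB − MSW) / (MSB + MSW)` coincides with the REML random-intercept
  estimate, so we use it directly (and its parametric bootstrap
  re-estimates with the same closed form, which makes 1,000 replicates
  essentially free).
* `model_icc()` fits `score ~ covariates + (1 | dog)` with `lme4`; with no
  covariates this is the unadjusted repeatability R, with age, timepoint,
  sex and location it is the adjusted ICC, in which variance explained by
  systematic effects is removed before partitioning.  Confidence intervals
  are percentile parametric bootstraps (simulate from the fitted model,
  refit, re-estimate), 1,000 replicates by default, seeded.  The bootstrap
  respects the random-effects structure; the CI method behind published
  ICC tables for this battery is not stated, so agreement there is
  expected to be approximate.

`cohen_kappa()` implements (p_o − p_e)/(1 − p_e) with marginal-product
expected agreement; two constant, identical raters give κ = 1 by
convention (the degenerate p_e = 1 case).

## The aging model

`fit_aging_model()` fits, with `lme4`,

```
score ~ poly(age, 2) + timepoint + sex + location + (1 | dog)
```

with reference levels baseline / female / ACCC.  Age enters as a
second-degree *orthogonal* polynomial: the columns are centered,
orthogonal and unit-norm, so the linear and quadratic estimates are
near-uncorrelated and the basis (stored with the fit) can be reapplied to
new data.  The basis is computed on all modeled observations pooled across
timepoints, since the model uses age at test rather than age at entry.
Coefficients and Wald 95% intervals come from the REML fit;
the likelihood-ratio age test compares full-likelihood refits with and
without the two age columns (df = 2), the standard arrangement for
fixed-effect LRTs.

`age_effect_size()` reports partial R² `(R²_full − R²_red)/(1 − R²_red)`
and Cohen's f² `(R²_full − R²_red)/(1 − R²_full)`, both on the *marginal*
(fixed-effects) R² of the mixed model, `var(Xβ)/(var(Xβ) + τ² + σ²)`.
For mixed models there is no single canonical R², and published
partial-R²/f² pairs for this battery are not jointly consistent with any
one ΔR² definition; we therefore compute both formulas from one
explicitly stated R² flavor and document the choice rather than matching
any particular printed pair.

## The simulator

`simulate_canid_study()` exists so the entire pipeline can be validated
with known ground truth.  Each dog has a latent ability

```
a_it = b0 + b1·age + b2·age² + u_i + δ_t + ε_it,
u_i ~ N(0, τ²),  ε_it ~ N(0, σ²)
```

and trial outcomes follow logistic links from `a_it`: per-trial open-side
probability in Spatial Reversal (minus a perseveration penalty
`persev · persev_decay^(j−1)` that decays over the first trials of each
reversal block), per-trial search accuracy in Delayed Search (minus a
nondecreasing delay penalty per trial type, errors uniform over the three
unbaited locations), and per-trial success in Cylinder.  No-choice /
no-response events occur at small configured rates with protocol-correct
motivator repeats and discontinuation rules; fear aborts drop a task's
trials entirely.

Default population parameters reproduce the study conditions the battery
was developed under: 239 dogs; age mean 7 y, SD 4 y, truncated to
1–16 y with pre-truncation moments adjusted (closed-form truncated-normal
moment matching) so the realized moments hit the targets; location mix
ACCC 49% / CC 13% / SSP 33% (renormalized); 50% female; follow-up
retention 140/239 at six months and 118/239 at twelve, ability-independent
(missing completely at random).  Default practice effects are δ_m6 = 0.23
and δ_m12 = 0.04 SD, the battery's published estimates.

The latent and link parameters are the simulator's invention — the battery
has no published generative behavioral model — and were calibrated once,
then frozen: `b1 = 0.06`, `b2 = −0.011` per year (concave decline from
mid-life, age variance ≈ 27% of baseline latent variance), `τ = 0.65`,
`σ = 0.45` (age-adjusted latent ICC ≈ 0.68), logistic slope 1.4 on all
three tasks.  These choices make (a) the baseline latent SD ≈ 0.96, so the
standardized composite tracks latent ability with near-unit slope and
simulated fixed effects are recovered on their nominal scale; (b) the
composite's age-adjusted ICC ≈ 0.6 after task-level measurement noise; and
(c) the baseline composite roughly normal after Yeo-Johnson.

What the simulator does *not* emulate: real task dependence beyond a
single latent factor (real tasks share only part of their variance through
general ability), breed or training-history structure, ability-dependent
dropout (available as a knob but off by default), within-trial latencies,
and experimenter or coding error.  Passing recovery tests therefore shows
the pipeline is consistent and unbiased under a plausible generative
model — not that the battery's real-data estimates are correct.

## Numerical and testing choices

* Validation is strict: trial files are checked against every protocol
  invariant (block side alternation, trial-type counts, location balance,
  repeat references), and errors name the offending dog, timepoint and
  trial index.
* CSV serialization writes missing values as empty fields, booleans as
  lowercase true/false, and numerics at full precision (`%.17g`), so
  write-then-read round-trips are exact.
* Negative variance-component estimates are truncated at zero; bootstrap
  CIs are clipped to enclose the point estimate within [0, 1].
* The test suite validates scorers against independently written replay
  and counting oracles on 1,000 simulated protocol runs per task; ICC
  recovery uses 200 replicates of 300 dogs per true-ICC level; bootstrap
  coverage uses 100 replicates with 1,000-replicate CIs; the end-to-end
  practice-effect recovery uses 100 replicates of 300 dogs at three
  timepoints.  These sizes keep each property statistically sharp while
  the full suite runs in minutes.

## Limitations

* The composite model requires at least 10 baseline complete cases per
  task PCA and at least 3 complete task-score triples; it is meant for
  cohort-scale data.
* Adjusted-ICC and effect-size values depend on estimator flavor (ICC
  variant, mixed-model R² definition); comparisons with published tables
  should expect small systematic differences.
* The aging model assumes a common quadratic age trajectory with a random
  intercept only; no random slopes, attrition modeling, or breed effects.
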