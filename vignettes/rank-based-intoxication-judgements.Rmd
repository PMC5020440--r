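---
title: "Rank-based social norms for intoxication judgements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based social norms for intoxication judgements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ranknorms)
```

## The scientific question and the model

When people drink in busy night-time environments they can see how drunk
the people around them are.  The rank-based social-norms account — a
"decision by sampling" view of magnitude judgement — holds that a
drinker's sense of their own drunkenness derives not from their absolute
breath alcohol concentration (BrAC) but from where that BrAC *ranks*
among the drinkers they compare themselves to.  `ranknorms` implements
the statistical machinery for testing that account on street-survey data
and, because such raw survey data are rarely shareable, for exercising
the full analysis on simulated cohorts with known generative mechanisms.

A respondent belongs to one **reference group**: the set of respondents of
the same gender surveyed at the same location.  Respondents who blew a
BrAC of exactly 0 stay in the group as comparators — they are visible in
the environment — but are not themselves eligible for the judgement
analyses.  For a member of a group of size $n$ with $b$ comparators
strictly below and $a$ strictly above,

$$R = \frac{b}{n - 1} \in [0, 1], \qquad
SR(\eta) = \tfrac12 + \frac{b - \eta a}{2\,(b + \eta a)} .$$

$R$ is the relative rank; $SR(\eta)$ re-weights upward comparisons by the
comparison-bias parameter $\eta > 0$.  With tie-free data
$SR(1) \equiv R$; $\eta < 1$ means the more sober comparators dominate
the comparison sample, $\eta > 1$ the more intoxicated ones.

Each of four 1–10 ratings (perceived drunkenness, extremeness of
tonight's drinking, 15-year risk to long-term health, 15-year cirrhosis
risk) is analysed with an OLS ladder:

| Model | Predictors |
|---|---|
| 1 | BrAC |
| 2 | $R$ |
| 3 | BrAC, $R$, BrAC − group mean |
| 4 | Model 3 + session duration, after-11pm flag, gender, FAST, age |

Model 3 is the discriminating test: the rank account predicts that $R$
retains a positive coefficient whose CI excludes zero while the BrAC
coefficient collapses to zero, with the distance-from-group-mean term
ruling out the rival "comparison to the average" account.  Model 4 is a
sensitivity analysis.  Collinearity between BrAC and $R$ is intrinsic —
rank is a monotone transform of BrAC within each group — so every fit
reports auxiliary-regression VIFs, $1/(1 - R^2_j)$ from regressing
predictor $j$ on the others.

$\eta$ is estimated per outcome by grid search: `scan_eta()` recomputes
$SR(\eta)$ for every eligible respondent at each $\eta$ from 0.01 to 5 in
steps of 0.01 and refits the simple regression
$\text{outcome} \sim SR(\eta)$, keeping the $\eta$ with the greatest
$R^2$.  The grid regression is the plain Model 2 form; a
covariate-adjusted scan is available behind `adjust_covariates = TRUE`
but is not the default procedure.

## Assumptions

- Ratings are modelled as linear in the chosen predictor with additive
  homoskedastic Gaussian error; inference is normal-theory OLS.
- Reference groups are treated as the comparison sample actually used by
  respondents; group membership is exhaustive and exclusive
  (gender × location).
- Ranks for judgement respondents are computed within the *full* pool,
  never within the judgement subsample: `rank_brac()` is therefore run on
  the pool before subsetting, and `fit_judgement_model()` refuses data
  lacking the rank columns rather than silently re-ranking.
- Missing covariates are handled by listwise deletion, with in/out counts
  logged at each filtering step.

## The synthetic cohort: what it emulates

`cohort_config()` defaults encode the study conditions the analysis
expects:

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `pool_size` | 1862 | respondents | published pool size |
| `male_fraction` | 0.632 | — | published pool composition |
| `n_locations` | 4 | — | 8 gender × location groups |
| `brac_male`, `brac_female` | 52.3 (30.0), 43.0 (27.8) | μg/100 ml | published positive-BrAC gender moments |
| `location_offsets` | −8, −3, +3, +8 | μg/100 ml | between-location spread; see below |
| `zero_brac_fraction` | 0.05 | — | sober bystanders exist but their share is unpublished; 5% is a plausible city-centre figure |
| `judgement_subsample` | 400 | respondents | published usable judgement sample |
| `duration` | 5.36 (3.62) | h | published subsample descriptives, truncated at 0 |
| `p_after_11pm` | 0.60 | — | published proportion |
| `fast` | 6.18 (3.49) | score | clipped to the 0–16 instrument range |
| `age` | 26.28 (8.78) | years | truncated at 18 (licensed premises) |

Two generator choices deserve emphasis:

- **Moment matching.**  The published gender means/SDs describe the
  *observed* positive-BrAC distribution, which is normal truncated at
  zero.  Drawing from `N(52.3, 30)` truncated at 0 would inflate the mean
  by ≈ 2.8 μg/100 ml, so for every gender × location cell the generator
  solves for the latent $(\mu, \sigma)$ whose zero-truncated draw has
  exactly the target mean and SD (two-moment optimisation to
  $10^{-4}$ absolute accuracy, cached per cell).  Sampling uses the
  inverse-CDF transform, so output is a deterministic function of the
  seed.
- **Location offsets.**  Additive shifts of the cell target mean create
  the between-group variation that makes rank and absolute BrAC
  genuinely different measures.  The defaults give a strongly significant
  one-way location effect and a pairwise BrAC–rank VIF of ≈ 8 in
  400-person subsamples, the collinearity regime the analysis is designed
  to withstand.

Covariates are drawn independently of BrAC (the study reports no
dependence); `judgement_mechanism()` lets robustness studies inject
covariate effects into the ratings instead.  Ratings are generated
continuous by default so that coefficient recovery by OLS is unbiased;
`discretize = TRUE` rounds and clips to the 1–10 instrument scale for
realism at the cost of attenuation.  `target_r2` tunes the noise SD so
the systematic signal explains a requested variance share on the sampled
respondents — convenient for generating data at a published $R^2$.

What the generator does **not** emulate: the right skew of the real BrAC
distribution (the heaviest decile of real drinkers is heavier than a
truncated normal allows), social-group clustering from the
every-*k*-th-passer-by sampling, venue-level structure, and any
BrAC–covariate dependence.  Passing tests therefore demonstrate that the
estimators recover known mechanisms under the stated ideal conditions,
not that the published field estimates are correct.

## Numerical choices and degenerate inputs

- **Ties.**  `below` counts strictly lower, `above` strictly higher; tied
  members fall in neither count (the literal reading of the rank
  formula).  A mid-rank mode (`ties = "midrank"`) splitting ties between
  the two counts is provided for sensitivity analyses.
- **Self-inclusion.**  The respondent belongs to their own group: a pool
  of 1,862 in 8 groups has a mean comparison-set size of
  $(1862 - 8)/8 = 231.75$, which the group summaries reproduce for any
  partition.
- **Degenerate groups.**  A member tied with *every* comparator has no
  defined standing; both $R$ and $SR$ take the symmetric limit 0.5 and
  the event is logged.  Singleton groups yield `NA` ranks with a warning,
  and their members are excluded from rank-based fits.
- **Group-mean control.**  The regressor is the signed distance
  (own BrAC − own group's mean BrAC, all members included); since
  {BrAC, distance} and {BrAC, raw mean} span the same column space, a
  `group_mean = "raw"` flag switches parameterisation without changing
  $R^2$ or the rank coefficient (verified in the tests).
- **Grid argmax.**  $R^2$ comparisons on the $\eta$ grid use a $10^{-12}$
  tolerance; ties break toward the smallest $\eta$ and are logged.  No
  interpolation between grid points is attempted, and no uncertainty
  interval is attached to the selected $\eta$ (a seed-resampling spread
  is the recommended diagnostic).
- **Standardized β** are computed by refitting on z-scored outcome and
  predictors ($n-1$ SDs, binary predictors z-scored like continuous
  ones), so the one-predictor β equals the Pearson correlation.
- **Rank-deficient designs** abort with the names of the aliased columns;
  a *perfectly* collinear pair inside `compute_vif()` reports `Inf`
  rather than erroring, since an infinite VIF is informative.
- **Constant outcomes** get zero slopes and $R^2 = 0$ by convention.

## Problem sizes used in the shipped checks

The test-suite and `scripts/acceptance.R` simulations use the study's own
scales: pools of 1,862 with 400-person subsamples for coefficient
recovery (averaged over 100 replicate cohorts), 2,000 ratings (drawn with
replacement from the ~1,770 eligible members) for $\eta$ recovery
(median over 20 replicates), and a single 50,000-respondent pool for
generator calibration.  These sizes give Monte-Carlo error comfortably
inside the tolerances being checked while keeping a full run in the tens
of seconds.

## Known limitations

- Under the generator's common-shape truncated normals, the within-group
  rank is nearly a smooth (probit) function of the distance-from-group-
  mean regressor, so Model 3's rank coefficient carries a considerably
  larger VIF than the pairwise BrAC–rank figure suggests.  Joint
  identification of the rank mechanism at the published effect and noise
  magnitudes consequently succeeds in most but not all replicate
  cohorts; real survey data, with messier group distributions, leave the
  rank term more identifiable.  The test suite measures this rate
  directly.
- The $\eta$ profile is flat near its optimum (neighbouring $SR(\eta)$
  transforms are correlated above 0.99), so single-cohort estimates of
  $\eta$ scatter; medians over replicate cohorts are the meaningful
  quantity, and the package deliberately reports no within-sample CI.
- The four ratings are generated (and analysed) as conditionally
  independent given the linear predictor; real ratings from one
  respondent are correlated.
- OLS on 1–10 ratings ignores the bounded, ordinal nature of the scale;
  this mirrors the analysis the package implements rather than a
  modelling recommendation.
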