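---
title: "Emulating target trials of surgeon and hospital operative volume"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating target trials of surgeon and hospital operative volume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Volume-outcome studies ask whether patients undergoing a major operation --
here, elective pancreatectomy for malignancy in a Medicare-age population --
fare better with surgeons or hospitals that perform it often.  The answer an
observational analysis returns depends on which hypothetical randomized trial
it implicitly emulates.  This package implements four such target trials with
increasingly well-defined interventions, together with a synthetic-claims
generator whose true counterfactual risks are computable, so each design's
bias can be *measured* instead of argued about:

1. **Trial 1** assigns a surgeon annual volume between 0 and 25 (26 arms);
   hospital volume keeps its natural value.
2. **Trial 2** assigns surgeon volume 0--25 and hospital volume 0--45 jointly
   (26 × 46 = 1196 arms).
3. **Trial 3** is trial 2 with travel incorporated: patients farther than a
   driving-time threshold (1.5 h by default; 3 h and 6 h as sensitivity
   analyses) from every surgeon keep the *natural value of treatment* --
   their observed providers.
4. **Trial 4** adds a second randomization to a particular surgeon and
   hospital among those with the assigned volume, emulated by adjusting for
   measured provider characteristics and standardizing them over the
   providers available at each volume level.

```{r setup}
library(volemu)
```

## The structural model behind the generator

`scm_params()` fixes an explicit structural causal model.  Its defaults are
calibrated to the published cohort's marginals: 9136 patients, 1358 surgeons
(annual volume mean ≈ 3, zero-truncated negative binomial), 697 hospitals
(mean ≈ 6), comorbidity prevalences such as diabetes 45% and coronary artery
disease 47%, age quartiles near 69/73/78 years, and a 90-day mortality
calibrated to 7.5% via the model intercept.  The causal skeleton is:

* **Geography.** Locations are points on a plane; driving hours are Euclidean
  distance times a configurable factor.  Hospitals sit more centrally when
  their volume is high (`centrality`), surgeons sit at their primary
  hospital, and an optional *remote block* places a fraction of patients
  beyond any driving-time threshold, served only by dedicated low-volume
  outlying providers -- the positivity violation the thresholded designs
  exist for.
* **Providers.** Surgeon volume couples to the primary hospital's volume
  through a Gaussian copula (`surgeon_hospital_volume_corr`).  Each provider
  carries a latent quality, correlated with standardized log-volume at
  `quality_volume_corr`, whose residual spread may shrink with volume
  (`quality_sd_decay`: low-volume providers are the heterogeneous ones).
  Observed characteristics -- surgeon age, sex, multi-hospital practice;
  hospital cardiac ICU, ownership, teaching category, size -- are generated
  as noisy proxies of latent quality at strength `quality_proxy_strength`
  while matching the published provider-table marginals.
* **Selection.** Patients choose a surgeon-hospital pair by softmax over
  utilities: rising in log surgeon volume (capacity: with weight 1 and no
  other pressures, choice is proportional to caseload, which reproduces the
  size-biased gap between the provider-weighted volume mean of ~3 and the
  patient-weighted median of ~5), falling in driving time at rate
  `travel_decay`, and rising in the *within-volume quality residual* with a
  weight modified by measured severity (`severity_selection_strength`) and a
  latent frailty (`frailty_selection_strength`).  Using the residual rather
  than total quality encodes the savvy-patient story -- choosing the best
  provider *among comparable ones* -- without distorting the volume
  distribution itself.
* **Outcome.** 90-day death is logistic in the patient covariates, latent
  frailty, surgeon and hospital volume, both latent qualities, and the
  remote-stratum shift.  Setting the volume and quality coefficients to zero
  defines the null scenario (`is_null_scenario()`).

The generator emulates the administrative *structure* of claims data --
right-skewed volumes, travel-dependent selection, confounding by severity and
provider quality, clustering -- not its billing content: there are no
ICD/CPT codes, no survival times beyond the 90-day indicator, and
comorbidities are independent Bernoulli draws because only marginal
prevalences are published.  Passing tests therefore demonstrate properties of
the estimators under a known, plausibly structured world, not agreement with
any real cohort's numbers.

## Scenario presets

`scm_scenario()` packages the causal structures the four designs react to
differently; each is the package's operationalization of a qualitative claim
about volume-outcome research:

* `hospital_confounding` -- hospital volume protects (log-odds −0.025 per
  operation/year), surgeon volume does nothing, the two are correlated at
  0.7.  A surgeon-only analysis absorbs the hospital effect.
* `travel_confounding` -- a 25%-of-locations remote stratum with an
  unmeasured +1.5 log-odds mortality shift can only reach outlying providers
  with volumes 1 or 3, while within-threshold patients draw volumes from
  {2, 5, 12, 18, 25} independently of health.  Intervening on *everyone*
  (trial 2) extrapolates metro-calibrated predictions onto remote patients;
  the thresholded strategy (trial 3) leaves them at their natural value.
  The remote volumes are deliberately disjoint from the reachable ones so
  that, with the indicator treatment coding, the confounded cells never
  enter the reachable patients' standardized predictions -- the cleanest
  expression of "driving time is handled by the strategy, not by
  adjustment".
* `savvy_patient` -- quality affects death (−0.45 per SD each for surgeon
  and hospital), is only partly determined by volume (correlation 0.45, more
  residual spread at low volume), and healthier patients -- in measured and
  unmeasured ways -- select better providers within volume levels.  Trial 3
  conflates the selected quality distribution with volume; trial 4 removes
  the part explained by measured provider characteristics.  Because those
  proxies are imperfect (deliberately: real provider tables are), trial 4
  shrinks but does not erase the bias.
* `null` -- no causal path from volume or quality to death.  The null and
  savvy presets use discrete volume supports spanning the reporting grids
  (surgeons up to 25, hospitals up to 43) so that every reported arm has
  positivity; under the heavy-tailed default distributions the high-volume
  arms would be extrapolations and any estimator comparison would measure
  spline behaviour rather than design behaviour.

## Estimation

`emulate_trial()` composes eligibility (older than 65, no metastatic
disease, no preoperative chemotherapy, tallied by first failing criterion in
that order), arm assignment ("the strategy consistent with the observed
data", with observed volumes clamped to the grid for *labels* only -- raw
values always enter the model), a maximum-likelihood logistic outcome model,
and plug-in standardization to the overall population:

\[ \hat R(a) = \frac{1}{n}\sum_{i=1}^n \hat p_i(a), \]

with two design-specific modifications: beyond-threshold patients keep their
observed treatment in the prediction (trials 3--4), and trial 4 averages the
provider-covariate terms over the empirical distribution of providers whose
volume lies within ±1 of the arm (widened until nonempty) -- a double
standardization emulating random assignment to a provider among available
ones.  Because the model is additive in provider terms, that average
factorizes into patient-level offsets plus surgeon- and hospital-level
contributions, each compressed to at most 16 quantile points (a numerical
integration choice that is exact for ≤16 distinct values and accurate to
well below estimation noise otherwise).

Treatment enters the model as restricted cubic splines (3 df) by default,
with `indicators` (the designs' literal arm dummies) and `linear` forms as
configuration; the surgeon × hospital product term is optional.  The
scenario demonstrations use the form matching each scenario's structural
truth -- linear for the linear-in-volume hospital-confounding world,
indicators for the discrete-cell travel world, splines for the smooth
quality-composition world -- so that the measured quantity is design bias,
not functional-form error.  Predicted probabilities are never truncated;
separation (diverging non-intercept coefficients together with fitted
probabilities pinned at 0 or 1) is surfaced as an error naming the term,
with an optional ridge penalty (`model$ridge`) for degenerate fixtures.
Driving time is never a covariate in any trial's model: trial 3 handles
positivity by strategy definition, which the test suite asserts
structurally.

## The counterfactual oracle

`true_counterfactual_risk()` evaluates the estimand each design is judged
against: each patient's structural linear predictor with volumes set to the
arm, latent qualities marginalized over the generator's
quality-given-volume law (Monte Carlo; exact when quality coefficients are
zero), and -- for thresholded arms -- natural values for beyond-threshold
patients.  It reads only the generator's latent state (never the fitted
models), so estimator-versus-oracle comparisons are genuinely dual-route.

## Uncertainty

`cluster_bootstrap()` implements the nonparametric cluster bootstrap with
percentile 95% intervals (B = 1000 by default).  Hospitals are the default
resampling unit -- the coarsest cluster, the standard conservative choice
for nested data -- carrying their patients and surgeons (multi-hospital
surgeons belong to their primary affiliation); surgeon-level and
patient-level (diagnostic) resampling are options.  Duplicated clusters
receive fresh identifiers.  Resamples where an arm is inestimable (empty
indicator cell, separation) are recorded as missing and excluded from the
percentiles, with a warning above 20% exclusions.  For trials 1--3 the
bootstrap refits by row indexing against precomputed design and prediction
matrices, which is mathematically identical to re-running the estimator;
trial 4 re-runs the full estimator because its provider-standardization
distribution changes under resampling.  Percentile intervals were chosen
over normal approximations because risks near zero make symmetric intervals
invalid; BCa and studentized variants are out of scope.

## Problem sizes and numerical choices

The test suite exercises: null recovery at n = 5000 (80 hospitals, B = 100);
the three bias demonstrations at 50 replicates of n = 2000 (60 hospitals)
against the oracle at 400 Monte-Carlo draws; bootstrap coverage at 200
replicates of n = 1000 (50 hospitals, B = 200); the size-biased identity at
n = 10⁴ under selection-neutral settings (travel and quality pressures off),
where choice probability proportional to caseload makes the identity exact
by construction; and full-pipeline determinism at n = 600.  These sizes are
the package's chosen demonstration scale: large enough that directional
conclusions are outside Monte-Carlo noise, small enough to re-run routinely.
Replicates in which the estimator legitimately refuses to fit (a zero-death
volume cell at 2000 patients is not rare) are dropped and counted, never
silently imputed.

Tie-breaks and degenerate inputs are fixed explicitly: nearest-volume
matching breaks ties toward the smaller volume; eligibility exclusions
attribute each patient to the first failing criterion in the printed order;
a single-hospital bootstrap collapses to zero-width intervals; empty
eligibility input yields empty output with zero tallies.  All randomness
derives from one seed through named substreams (`sub_seed()`), so adding a
stage never perturbs another stage's draws.

## Known limitations

* The selection-model magnitudes (travel decay, quality attraction) are
  calibrated only to reproduce published marginals and a 7--8% mortality
  baseline, not to reproduce any published risk table numerically -- the
  real claims are not redistributable, so those numbers are not a valid
  target at this scale.
* Trial 4's correction is bounded by the informativeness of measured
  provider characteristics; with the default proxy strength it removes
  roughly a quarter to a third of the savvy-selection bias.
* Comorbidity independence and a single 90-day binary outcome are
  simplifications; both are configuration points rather than assumptions
  baked into the estimators.
* Time-varying volume interventions (a surgeon changing their own volume)
  are out of scope; `compute_trailing_volume()` exists so that
  operation-log data can be consumed, but the generator emits annual
  volumes directly by construction.
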