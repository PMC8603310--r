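---
title: "Methods: ideal observers for accent adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ideal observers for accent adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accentobs)
```

## The question the package operationalizes

Exposure–test experiments on accent adaptation manipulate, between
participants, whether listeners hear a non-native talker's syllable-final
/d/ during a lexical-decision exposure phase, and then collect 7-point
goodness ratings for the talker's /d/- and /t/-final minimal-pair words at
test. Whether exposure *should* help depends entirely on the statistics of
the speech: if the talker's /d/ distribution deviates strongly from native
expectations, learning it is valuable; if it is already near-native, even
perfect learning changes nothing. `accentobs` makes that argument
quantitative with an ideal observer: a Bayesian categorizer whose only
parameters are the means and covariances of the category cue distributions,
estimated from production data — never from the perception data it is asked
to predict.

## Model and assumptions

Categories are trivariate Gaussians over (vowel duration, closure
duration, burst duration), all in ms, with uniform priors of 0.5. The
posterior of the rated category under Bayes' rule is linked to goodness
ratings by an identity link, justified by the linear relation between
categorization proportions and goodness ratings observed for stimuli of
this kind; for display on the human scale, posteriors in [0, 1] are mapped
affinely onto the rating range (default [-1, 1], the span of z-scored
by-item mean ratings). The affine map cannot change any correlation between
model and human data, which the test suite checks to machine precision.

The idealizations to keep in mind:

* **Complete learning.** The /d/-exposure observer's /d/ category *is* the
  sample distribution of the 30 exposure tokens. Real listeners weight new
  evidence against prior expectations, so true adaptation is partial; the
  package deliberately brackets incremental belief updating.
* **Native /t/ for everyone.** Neither condition presents lexically labeled
  /t/, so both observers carry the native /t/ category. Cross-category
  generalization from the talker's /d/ is ignored.
* **No perceptual noise term.** Category variances are production
  variances; no extra perceptual/acoustic noise is added.

## Context normalization (C-CuRE)

Exposure and test words differ in phonotactic and prosodic context, so raw
cue values confound context with category. Each cue is regressed by OLS on
categorical context predictors (any `context_*` column, talker ids, ...);
the corrected value is the residual plus the grand mean, i.e. the part of
the cue not explained by context, on the original ms scale. Properties the
suite verifies: an intercept-only model makes correction the identity;
within every fitted context cell, corrected cue means collapse to the grand
mean; refitting on corrected data gives zero coefficients.

Choices here that were genuinely open:

* **Coding.** Dummy (treatment) coding with the sorted-first level as
  reference. Any full-rank coding gives identical fitted values — and the
  correction uses only fitted values — so this pins coefficient tables for
  reproducibility without affecting results.
* **Fit on native speech only.** The correction represents expectations
  formed by native experience, so context models are fit on native tokens
  and applied to all tokens (per language when both are present).
* **Unseen levels.** Strict by default (error); a `zero`-contribution
  fallback exists because the pipeline's non-native tokens can carry
  contexts absent from the native fitting set, and silent extrapolation
  would otherwise hide data errors.
* **No transform.** Correction operates on raw ms; no log transform is
  applied anywhere.

## Numerical choices

* Covariances are unbiased (n−1) estimates. At n = 30 the ML/unbiased
  difference is small, but it must be pinned for reproducibility.
* Default ridge is 0. With ~30 tokens in 3 dimensions the sample
  covariance is almost always well-conditioned, and silent regularization
  would bias exposure deltas. If the covariance is numerically non-PD the
  ridge escalates to `1e-6 · trace(cov)/3` (floor `1e-8`) and the applied
  amount is recorded on the category object; fully degenerate data
  (identical tokens) with ridge 0 is an error.
* All density work is in log space via the Cholesky factor of the
  covariance; posteriors use max-subtracted normalization. Duration
  covariances in ms² produce raw densities far below double-precision
  underflow, so this is a correctness requirement, not a nicety.
* Posterior probabilities sum to 1 within 1e−12; the suite checks the full
  posterior path against a brute-force oracle (explicit inverse,
  determinant and normalization) on 1,000 random observers.

## Rating analysis

Ratings are z-scored within participant (sample SD; constant raters get
z = 0 with a warning). Because /d/-exposure predicts more
*category-appropriate* ratings — higher /d/-goodness for /d/ items, higher
/t/-goodness for /t/ items — the default response in the exposure
regression is the goodness of the item's intended category: trials whose
rated block mismatches the item's category are sign-flipped
(`align = "category_match"`). `align = "none"` analyzes raw z-ratings.

Condition and experiment are coded as centered ±0.5 contrasts
(d-exposure and English = +0.5), so the condition coefficient equals the
condition difference in z units and the interaction is the
difference-of-effects across experiments. Two backends implement the
participant/item grouping structure:

* `"lmer"` — by-participant and by-item random intercepts via `lmerTest`
  (Satterthwaite df). Random slopes are not attempted: on desk-scale
  synthetic data they rarely converge.
* `"fixed"` — OLS with two-way cluster-robust SEs (participant and item
  clusters, Cameron–Gelbach–Miller), with a conservative fallback to the
  larger one-way clustered variance per term when the two-way estimator
  goes non-positive, and t-tests on `min(participants, items) − 1` df.
  This is the stable choice inside bootstrap replicates, where resampled
  data routinely defeat hierarchical fits.

`"auto"` (default) tries `lmer` and falls back; the backend actually used
is recorded in the result's grouping field. The trial-level model-fit
regression uses the block's posterior probability on the probability scale
(not the rescaled posterior rating): the two differ only by an affine map,
so significance is unaffected and the probability scale makes the
coefficient's units explicit. "Significant" means two-sided p < 0.05
throughout.

## Hierarchical bootstrap

To separate "different effect" from "different sample size", the larger
experiment is repeatedly down-sampled to the smaller one's size and
structure: participants are resampled with replacement within condition,
then trials with replacement within each sampled participant. Resampled
participants get fresh ids — without relabeling, a participant drawn twice
would collapse into one grouping unit and understate variance. Per sample,
the condition × experiment interaction is refit on the combined resample
and the condition simple effect within each experiment; the summary reports
exact proportions of samples with a significant interaction and, per
experiment, effects in the predicted direction and significant in either
direction. Replicate fits that fail are excluded and counted, never
imputed. Within a replicate, "significant" uses the replicate's own
regression p-value at α = 0.05 (the fixed backend's cluster-robust p by
default) — the main analytic assumption of this module, and configurable.
Items are not resampled by default: each sampled participant keeps their
own item inventory, which preserves the item structure the experiments
share.

With-replacement duplication of trials makes per-replicate tests mildly
anticonservative, so null-calibration proportions land near the top of the
nominal range rather than at α exactly; the suite checks calibration under
an exchangeable null (both conditions rated under the same observer, so
condition labels carry no information) and monotone power over injected
effects of 0, 0.2 and 0.4 z units.

## What the synthetic generator emulates — and what it does not

The generator draws production tokens from per-(accent, category)
Gaussians, adds additive context effects, truncates sub-ms draws at 1 ms
(durations cannot be negative; the count is logged, and a large count
flags a mis-specified scenario), and simulates ratings as
`slope · scaled posterior + N(0, noise_sd)`, discretized affinely onto the
7-point scale. Defaults mirror the experimental design being modeled: 30
exposure /d/ tokens, 30 native tokens per category, 15 test minimal pairs,
one non-native talker, 24 participants per condition, link slope 1 and
noise SD 0.3 (on the [-1, 1] latent scale — roughly a third of the scale's
half-range, enough to spread responses over several Likert points without
drowning the item structure).

Preset geometry is calibrated once, in SD units, in a single documented
block (`PRESET_PARAMS`): `english_like` non-native /d/ and /t/ are
identical on vowel and closure and 6 pooled SDs apart on burst (final
devoicing: the native vowel/closure cues collapse, voicing survives in the
burst); `swedish_like` non-native means sit within ~0.2 pooled SD of
native, comfortably inside the ≤ 0.5 SD construction ceiling, so exposure
statistics carry almost nothing the native categories lack; `null_effect`
makes non-native parameters bit-identical to native. Covariances are
diagonal-dominant with a mild (0.3) vowel–closure correlation; the true
cross-cue covariance structure of real recordings is not published, so
these are flagged as invented.

What passing tests on this generator do **not** show about real data: real
cue distributions are not exactly Gaussian and differ across talkers;
real listeners adapt partially and incrementally, use more cues than three,
and produce ordinal ratings with participant-specific response styles
beyond what within-participant z-scoring removes. The generator exists to
verify the pipeline's statistical machinery (recovery, calibration,
direction of predicted contrasts), not to reproduce any experiment's
effect sizes.

## Problem sizes

The test suite and acceptance script run at desk scale by design: 50
simulated experiments per preset for the exposure contrast, 200 bootstrap
samples per run (the method's default is 1,000), parameter recovery at
n = 10,000 tokens, oracle comparison on 1,000 random observers, and a
4 × 10⁶-point Monte-Carlo normalization check. These sizes give
Monte-Carlo error comfortably inside every asserted tolerance.

## Known limitations

* Categorical context predictors only; continuous covariates (e.g.
  speaking rate) would need the regression layer extended.
* No ordinal (cumulative-link) model of the 7-point scale; the identity
  link plus z-scoring is the deliberate, simplest-consistent choice.
* No incremental ideal-adaptor updating; the /d/-exposure observer is the
  complete-learning endpoint.
* The bootstrap compares exactly two experiments; more would need a small
  generalization of the interaction structure.
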