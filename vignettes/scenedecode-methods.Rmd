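---
title: "Linking time-resolved neural decoding to categorization behavior: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking time-resolved neural decoding to categorization behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenedecode)
```

# Overview

`scenedecode` implements a pipeline for asking when, over the course of a
neural response, stimulus representations become usable for a binary
categorization decision. Its empirical core is the *distance-to-hyperplane*
statistic: at each time point a linear classifier is trained to separate the
two categories from multichannel activity patterns, each individual
stimulus's held-out pattern is assigned a signed decision value, and the
absolute decision value — the pattern's distance from the category
boundary — is rank-correlated with that stimulus's reaction time. If
representations are formatted for decision-making, stimuli far from the
boundary should be categorized faster, producing a *negative* Spearman
correlation. The surrounding stages (noise normalization, pseudotrial
decoding, channel searchlight, representational similarity analysis with
noise ceilings, entropy-threshold readout of staged classifiers, and
nonparametric group statistics) support and extend that core.

Everything is exercisable without recordings: a synthetic-data module plants
a known category signal, a known distance-RT coupling, and known staged
model behavior, so each stage can be validated by parameter recovery.

# The data model

An `EpochSet` holds a `trial x channel x time` tensor with bin latencies in
milliseconds (stimulus onset at 0) and a per-trial metadata table
(participant, scene, binary category, task, correctness, reaction time).
Every operation preserves the invariant that row *i* of the table describes
slab *i* of the tensor. Decision values (`SceneDecisionValues`), staged
probabilities (`StageProbabilities`) and the whitening operator
(`WhitenOperator`) are S4 classes with validity checks; time courses and
maps are plain lists/data frames.

# The synthetic generator as a study design

`simConfig()` fixes the generative model; `genEpochs()`, `genRTs()` and
`genStageProbs()` derive all outputs deterministically from one seed
(per-participant noise streams come from a counter-based expansion of the
master seed, so results do not depend on iteration order).

Each trial is

$$ x_{t} = a(t)\, m_s\, w + \varepsilon_t, $$

where $m_s$ is the scene's latent signed margin (sign = category), $w$ a
unit-norm channel projection, $a(t)$ a raised-cosine amplitude confined to
the effect window, and $\varepsilon_t$ Gaussian channel noise with a
configurable spatial covariance (identity, diagonal, or exponential decay
$\Sigma_{ij} = e^{-r|i-j|}$), white over time. Margins are drawn as
$m_s = \mathrm{sign}(\text{category}) \cdot |\,\delta/2 + \mathcal N(0,
\sigma_m)\,|$; the absolute value keeps the margin sign constant within
category. Reaction times implement the linking hypothesis directly:

$$ rt_{p,s} = rt_\mathrm{base} - \lambda\,|m_s| + \mathcal N(0,
\sigma_{rt}), $$

clipped below at 150 ms (a plausibility floor for human button presses).
Staged classifier trajectories give the confidence in the true category as
$\mathrm{logistic}(g\,k\,|m_s|)$ at stage $k$, so confidence sharpens with
stage at a rate increasing with the margin — scenes far from the boundary
cross any entropy criterion earlier.

Default conditions describe a mid-sized recovery study: 20 participants,
20 scenes (10 per category), 16 channels, 120 bins of 5 ms, signal confined
to 95–195 ms, $\delta = 1.5$, $\sigma_m = 0.5$, unit noise with exponential
spatial correlation (rate 0.5), 20 trials per scene, $rt_\mathrm{base} =
500$ ms, $\lambda = 60$ ms per margin unit, $\sigma_{rt} = 30$ ms. The
behavioral constants sit near typical human categorization RT means and
between-participant spreads; the signal window matches the latency range
where category information typically peaks in human recordings; the
remaining effect-size constants were chosen once so that the planted effect
is strong but not degenerate (peak decoding in the low 90s rather than at
ceiling), and are not tuned thereafter.

What the generator does *not* emulate: overlapping evoked components,
temporally correlated (1/f) noise, artifacts, eye movements,
trial-to-trial latency jitter, incorrect trials, or any nonlinear
category structure. Passing recovery tests therefore demonstrates the
*pipeline's* correctness — estimator implementations, train/test hygiene,
calibration of the statistics — not that real recordings satisfy the
generative assumptions.

# Preprocessing

`baselineCorrect()` subtracts the per-trial, per-channel mean over a
latency window. `downsampleBins()` averages consecutive non-overlapping
groups of samples (trailing remainder dropped; bins labeled by group
centers). Acquisition-side low-pass filtering is not re-implemented: the
generator produces band-limited-equivalent (white, epoched) data and the
package treats filtering as an upstream assumption.

Multivariate noise normalization (`fitWhitener()` / `noiseNormalize()`)
estimates the channel covariance pooled over all trials and the entire
epoch, per participant, and multiplies every pattern by
$\Sigma^{-1/2}$ (unique symmetric positive-definite root via
eigendecomposition, eigenvalue floor $10^{-10}\lambda_\mathrm{max}$).
The covariance is regularized by Ledoit–Wolf shrinkage toward a scaled
identity with the standard data-driven weight; the weight is exposed and a
fixed value (including 0) can be forced. Two caveats are deliberate and
documented rather than hidden: the whitener is fit once per participant on
all data (not within cross-validation folds), which in principle leaks
marginal covariance information across the decoding split; and when the
true covariance *is* a scaled identity the data-driven weight approaches 1,
which is optimal, not a failure.

# Decoding

Both schemes operate per participant and time point on pseudotrials
(averages of same-condition trials; no trial contributes to two
pseudotrials in a repeat), with trial counts first equalized across scenes
by random downsampling to the per-participant minimum — re-randomized over
`repeats` resampling repeats (100 by default; recovery studies here use 20)
whose results are averaged arithmetically.

*Scene identity*: all pairwise scene classifications,
leave-one-pseudotrial-out (group size 4).

*Scene category*: each scene's trials split into halves; training halves
pooled within category into pseudotrials of 20 trials; the classifier is
fit on category labels; each scene's held-out half is averaged into **one**
test pattern, yielding per scene, time point and repeat one correctness
and one signed decision value. That one-pattern-per-scene choice is the
design decision that makes the decoding output plug directly into the
distance-to-hyperplane statistic.

The classifier is a linear max-margin (L1-hinge) SVM with fixed cost
$C = 1$ and no per-feature rescaling beyond upstream whitening, trained by
deterministic dual coordinate descent in compiled code with the bias as an
augmented regularized feature; for the small, whitened problems this solves
the classifier is interchangeable with libsvm (the test suite checks
decision-value agreement against `e1071`), while being fast enough to make
replicate-level recovery studies routine. Degenerate (constant) patterns
still yield a prediction; a decision value of exactly zero maps to the
first category.

# Distance to hyperplane

Distances are `|decision value|` regardless of classification correctness
(a signed-by-true-category variant exists behind a flag for sensitivity
analysis); the absolute value is taken after averaging decision values
over repeats (the opposite order is a documented alternative). Per
participant and time point, distances over scenes are Spearman-correlated
with the scene-level **median RT over participants** — not the
participant's own RTs — matching the statistic's definition; subsets
restrict to one category; cross-task pairings reuse the identical
computation with sources crossed and the pairing recorded. Constant inputs
yield `NA`, excluded from group means with counts reported.

# Searchlight

`buildNeighborMap()` takes Euclidean k-nearest channels (k = 4 by default;
a patch is the channel plus its four nearest neighbors) on provided 2-D
layout coordinates, with distance ties broken by channel index; no
geodesic scalp distance is attempted. `searchlightMap()` re-runs decoding
or the distance statistic on each patch at a single latency (typically the
whole-pattern peak). Because the resampling streams depend only on
participant and repeat, a full-scalp patch reproduces the whole-pattern
analysis at that latency.

# RSA and noise ceiling

EEG RDMs use the correlation distance (1 − Pearson r over channels)
between pseudotrials of 5 trials, averaged over all cross-scene
pseudotrial pairings and 100 random re-assignments (arithmetic mean of
distances, not of correlations); model RDMs standardize features across
scenes first (zero-variance features dropped). RDM comparison is Spearman
on strict upper triangles with average-rank ties. Per-layer model time
courses take the median over the model's stages. The noise ceiling's lower
bound correlates each participant's RDM with the leave-one-out mean RDM,
the upper bound with the all-participant mean (element-wise arithmetic
means).

# Entropy-threshold readout

`extractNetworkRTs()` returns, per scene, the first stage whose Shannon
entropy is $\le$ the threshold (inclusive crossing), or $S{+}1$ when never
reached. Entropy defaults to bits (base 2); the base is an explicit
argument everywhere because the conventional 0.01–0.1 threshold grid means
different confidence levels in bits versus nats, and the source convention
is not fixed. `selectThresholdCV()` selects the threshold per
leave-one-participant-out fold by maximizing the Pearson correlation
between network RTs and the median RT of the remaining participants
(constant-RT thresholds excluded; ties to the lowest threshold), then
reports the held-out participant's correlation for all scenes and each
category. `stageAdapter()` maps every-second-layer readouts of a
feedforward model onto stages so the same machinery applies.

# Group statistics

The sign-permutation test flips each participant's whole time course by
±1 (patterns shared across time, preserving temporal dependence) and ranks
the observed mean/SD statistic in the null distribution; sampled p-values
use the add-one convention to avoid zero, and an exhaustive $2^P$ mode
exists for small groups. FDR control is Benjamini–Hochberg step-up
(α = .01 for decoding, .05 elsewhere; right tail for decoding/RSA, left
tail for the distance statistic). Peak latencies get percentile bootstrap
CIs (participants resampled with replacement, 1000 times, ties to the
earliest bin; no BCa correction — a deliberate simplicity choice). Paired
resamples are used when comparing two curves' peaks.

# Numerical and validation choices

* Problem sizes in the shipped tests: recovery and null-calibration
  studies run the full 20-participant design at 20 decoding repeats and
  1000 permutations, over 20 (recovery) and 50 (null) replicate seeds;
  decoding-sanity and RSA checks use smaller designs (4–6 participants,
  6–8 scenes). These sizes were chosen as the smallest at which the
  planted effects and calibration properties are stable.
* Oracle tests pin primitives to independent implementations: entropy
  readout against an exhaustive stage scan, BH against a from-definition
  step-up, the sign-permutation test against full $2^P$ enumeration,
  Spearman against brute-force average ranks, the SVM against libsvm.
* Chance bands for decoding sanity use binomial quantiles with the number
  of *independent* test predictions (resampling repeats reuse trials and
  do not count).
* Degenerate inputs are contracts, not accidents: empty baseline windows,
  rank-deficient covariances without shrinkage, sub-minimum trial counts,
  constant correlation inputs and mixed-config reports all raise
  actionable errors or recorded `NA`s.

# Known limitations

Three properties surfaced by the recovery studies deserve emphasis,
because they are features of the methods as defined rather than of this
implementation:

* **Stimulus sampling limits null calibration of the d2h statistic.**
  With the RT–distance coupling removed but the category signal present,
  every participant's scene distances still share the latent margin
  structure, and all participants are correlated against the *same*
  realized median-RT vector. Inside the signal window this induces a
  common component across participants (inter-participant correlation of
  the per-participant ρ values around 0.15 in the default design), which
  the participant-level sign-permutation test cannot remove: its raw
  p-values are exactly uniform outside the signal window but
  overdispersed inside it. FDR-significant rates stay near nominal on
  average, but scene-level spurious couplings are genuinely detected as
  "significant" within single datasets. With 20 scenes this
  scene-sampling variability is substantial; inference therefore
  generalizes to the scene population only insofar as scenes are treated
  as a random effect, which the statistic (by definition, on group-median
  RTs) does not do.
* **Identity decoding is margin-limited under the rank-1 generator.** The
  planted signal is $a(t)\,m_s\,w$: all scene information lives in one
  spatial direction, so two same-category scenes with close margins are
  indistinguishable in principle, capping pairwise identity decoding
  below ceiling regardless of noise level. Category decoding exceeds 90%
  inside the window under a strong-signal configuration; identity
  decoding is validated as far above chance inside and at chance outside
  the window instead.
* **Whitening on signal-dominated data shrinks the signal.** The
  covariance is estimated from the entire epoch including the evoked
  signal; when noise is very weak the signal direction dominates the
  covariance and normalization suppresses it. This mirrors practice (and
  the leakage caveat above); the near-noiseless decoding sanity checks
  therefore run on unwhitened data.

Beyond that: the generator's whiteness over time makes time bins
independent, so temporal FDR behavior on real (autocorrelated) data will
differ. The d2h statistic is implemented only against group-median RTs;
the own-RT variant is out of scope. No cluster-based permutation
statistics, temporal generalization, source reconstruction, or network
training/feature extraction are provided — the model-facing modules
consume exported features and probabilities.
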