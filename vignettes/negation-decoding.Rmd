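---
title: "How negshift analyzes the effect of negation on scalar-adjective representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How negshift analyzes the effect of negation on scalar-adjective representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(negshift)
```

## The question and the hypothesis space

When a reader encounters "not good", what happens to the neural and
behavioral representation of "good"? Scalar adjectives ("bad"/"good",
"cold"/"hot") live on graded semantic continua with two antonym poles, which
makes them a precise testbed: negation could leave the adjective
representation untouched (**no effect**), scale it toward zero
(**mitigation**), flip its sign toward the antonym (**inversion**), or move
it to something orthogonal to the low-high axis altogether (**change**).

`negshift` implements the full analysis chain that adjudicates among these
four mechanisms from two kinds of time-resolved data:

* **mouse trajectories** collected while participants rate the meaning of
  phrases like "really not good" on a low-high scale, and
* **epoched multichannel sensor recordings** (MEG-style) time-locked to the
  adjective, classified timepoint by timepoint.

Because the real recordings are large and external, the package ships a
seeded synthetic-data generator whose ground truth is the mechanism itself.
Every stage of the pipeline is exercised, and its statistical behavior
verified, against that generator.

## The synthetic-data generator

### Design

The factorial phrase design crosses 9 modifier combinations ("### ###",
"### really", "really ###", "### not", "not ###", "really not", "not really",
"really really", "not not"; "###" marks an absent modifier) with the two
antonym poles; `n_trials_per_cell` controls the repetitions of each
combination-by-pole cell per participant. The no-modifier condition is kept
only as a baseline for the time-frequency contrast and excluded elsewhere.
A trial counts as *negated* when it contains "not" (so "not not" is grouped
with the negated phrases, the grouping used for the neural contrasts); a
switch (`negation_rule = "odd_not"`) implements the alternative
odd-number-of-negations grouping for sensitivity analyses.

### Behavioral model

Reaction times are lognormal (positive and right-skewed;
`rt_meanlog = log(1400)`, `rt_sdlog = 0.25` by default) with additive
offsets of +150 ms for negated and +80 ms for low-pole trials, so the
generative effects the ANOVAs should find are known exactly. Feedback is
flagged negative with probability 0.15. Final ratings (endpoints on
[-1, 1], +1 = high pole in unswapped coordinates) are Gaussian per
pole-by-negation condition: affirmative trials near the poles (±0.8),
negated trials pulled across the midline toward the center (∓0.35) and more
dispersed (SD 0.30 vs 0.15) — a mitigation profile with the increased
variability of negated interpretations built in.

### Trajectories

Each trajectory is a first-order pursuit process
\(x'(t) = g \cdot (\text{target}(t) - x(t))\) on the normalized scale
coordinate, sampled at ~60 Hz with Gaussian increments. Words appear at 0,
300 and 600 ms (250 ms per word + 50 ms interval), so the adjective onset is
600 ms into the trial. Affirmative trials pursue the trial's endpoint from
stage-1 onset (350 ms after adjective onset, gain 2.5/s). Negated trials
first pursue the adjective's own pole and only from stage-2 onset (700 ms,
gain 4/s) reverse toward the mitigated endpoint on the opposite side. This
produces the characteristic two-stage shape — initial deviation toward the
adjective, later movement toward the antonym — that the per-timepoint
regression must recover as an early positive and a late negative beta
cluster.

### Epochs

The sensor array is abstract (no forward physics, no channel geometry).
Trial \(i\), sensor \(s\), time \(t\):

\[
X_{ist} = \operatorname{sign}(\text{pole}_i)\, A(t)\, p_s\, m_i +
\varepsilon_{ist}, \qquad \varepsilon \sim \mathcal N(0, 1)
\]

where \(p\) is a fixed random unit sensor pattern, \(A(t)\) a half-cosine
bump supported on the pattern window (130-550 ms from adjective onset, the
lexical-semantic processing range) with peak amplitude `snr`, and
\(m_i = 1\) for affirmative trials. For negated trials \(m_i = \lambda\):
\(\lambda = 1\) (no effect), \(0 < \lambda < 1\) (mitigation, default 0.5),
\(\lambda = -1\) (inversion). Under **change**, negated trials instead use a
second unit pattern \(q \perp p\). An optional oscillatory burst
(`beta_burst`) is added to negated trials to emulate a band-limited power
increase under negation. Noise can be low-pass smoothed
(`noise_lowpass_hz`) to mimic filtered recordings; the default leaves it
white.

Epochs are generated directly on the 100 Hz analysis grid by default — the
decimation path from higher native rates (e.g., 1000 Hz) is implemented in
`preprocess_epochs()` and tested separately. One master seed drives
fixed-offset per-participant streams, so any participant subset reproduces
exactly.

**What the generator does not emulate:** realistic sensor covariance and
autocorrelated noise, artifacts, inter-participant variability in pattern
topography (all participants share \(p\)), non-stationary or drifting codes,
and realistic amplitudes (effect sizes in sensor units are free parameters).
Passing tests on this generator therefore validates the *statistical
machinery* — calibration, leakage-freedom, recovery of a known mechanism —
not the substantive conclusions one would draw from real recordings.

## Behavioral statistics

`filter_trials()` keeps positive-feedback trials whose RT lies within the
participant's median ± 2 SD, both computed over that participant's
positive-feedback trials (the SD population is not further specified in the
source procedure; using the same trial set as the median is the natural
reading). The rule is applied once: because the survivor SD shrinks, a
second application could trim further, so the pipeline never iterates it.

`rm_anova_2x2()` computes the within-subject decomposition via
`stats::aov()` with an `Error(participant/(A*B))` stratum, exact p-values
from the F distribution, and partial eta squared
\(\eta_p^2 = SS_\text{effect}/(SS_\text{effect}+SS_\text{error})\). For a
2×2 within design every F(1, n-1) equals the squared paired t of the
corresponding contrast — one of the oracle identities in the test suite.
Endpoint analyses feed per-participant cell means (location, including the
antonym × negation interaction that signals mitigation) and cell SDs
(the variability effect of negation) through the same machinery. Post hoc
paired comparisons of the four cells are Holm-corrected
(`stats::p.adjust`); Tukey's studentized range is deliberately not used —
with four cells and Holm's step-down control the paired tests answer the
same question with simpler assumptions. Phrase complexity (1 vs 2
modifiers) reuses the identical 2×2 machinery with complexity as factor A.

## Trajectory regression

Trajectories are linearly interpolated onto a fixed 200-point grid (100 Hz,
0-1990 ms); samples beyond the last observation hold the final value — the
response was registered, so the endpoint is the correct continuation.
Coordinates are normalized so the scale ends map to ±1 and
reversed-orientation blocks are flipped back (+1 = high pole). At each
timepoint, OLS of position on pole coded -1/+1 with an intercept gives a
beta whose sign reads directly: positive = toward the adjective's own pole,
negative = toward the antonym. All scalar dimensions are pooled per
participant and the intercept absorbs shared drift. Group inference uses
the sign-flip cluster test over 0-1.4 s from adjective onset, two-sided,
since both the early positive and late negative excursions are of interest.

## Temporal decoding

Preprocessing subtracts the per-trial, per-sensor baseline mean (-300-0 ms),
drops trials exceeding an absolute amplitude threshold, and decimates to
100 Hz. The decoder at each timepoint is an l2-regularized logistic
regression (inverse regularization C = 1, the estimator's conventional
default) with class-balanced weights, preceded by a standardizer and a PCA
projection retaining the smallest number of components explaining more than
99% of the variance. Two scope decisions:

* **PCA per training fold.** Fitting the projection on all epochs would let
  test-trial structure into the training transform; per-fold fitting avoids
  that leakage, and a dedicated probe (informative feature planted only in
  held-out trials) verifies chance-level AUC.
* **Channels as features, trials × timepoints as samples.** The projection
  is spatial, shared across timepoints, the established idiom for sensor
  arrays; one classifier is then fitted per timepoint.

Cross-validation is stratified (5 or 10 folds); held-out scores are pooled
across folds — each trial is predicted exactly once — before computing the
per-timepoint empirical ROC AUC (Mann-Whitney pair counting, ties 0.5) and
the mean predicted probability per true class.

The two designs that matter for adjudication: **approach (i)** trains on all
affirmative trials and tests on all negated trials (does the affirmative
low/high code transfer?); **approach (ii)** trains on affirmative and
negated trials pooled (90% per fold) and scores the held-out 10% separately
per condition, giving paired AUC series for a direct affirmative-negated
contrast on the same models. The chance baseline of the probability
estimates is the average over refits under permuted training labels
(100 seeded permutations); because this multiplies the cost of a
generalization analysis roughly a hundredfold it is switchable off
(`n_baseline_perm = 0`), and the cluster-level decision rule uses the AUC
evidence, which carries the same information.

The classifier itself is a Newton/IRLS ridge logistic solver
(RcppArmadillo) with an unpenalized intercept, backtracking line search on
the penalized deviance (the objective is strictly convex, so damped Newton
always descends, even warm-started from a saturated solution), and warm
starts across adjacent timepoints. It reproduces glmnet
(`alpha = 0, lambda = 1/(nC)`) to ~1e-8; glmnet itself is kept as the
independent oracle in the tests rather than the implementation because its
per-call overhead is prohibitive at ~10^6 fits per recovery study.

## Cluster-based permutation inference

`one_sample_cluster_test()` takes a participants × time matrix of effects
already centered on the null (AUC - 0.5, betas, power differences). Per
timepoint a one-sample t statistic is formed; contiguous runs above the
cluster-forming threshold (the t quantile at uncorrected α = 0.05 for
n - 1 df, the standard default, configurable) become clusters with mass =
the sum of t inside; the null is the maximum cluster mass under random
per-participant sign flips, giving family-wise control over the window.
P-values use the (1 + exceedances)/(1 + n_perm) estimator, so p ≥
1/(n_perm + 1). Two-sided tests report positive and negative clusters
separately against one max-|mass| null. For small groups an exact mode
enumerates all 2^n sign patterns. Two numerical points worth knowing:

* Sign patterns that mirror or reproduce the observed one create *exact
  ties* in the null; a relative slack (1e-9) keeps ties counted as
  exceedances regardless of floating-point noise, which keeps p-values
  scale-invariant.
* The minimum attainable two-sided p is \(2/2^n\): with fewer than 6
  participants no cluster can clear α = 0.05, whatever the effect.

Calibration is verified by simulation: 500 null datasets
(12 participants × 100 timepoints of white Gaussian noise) must produce a
family-wise rejection rate inside the 95% binomial interval around 0.05.

## Time-frequency analysis

`morlet_power()` convolves each trial and sensor with complex Morlet
wavelets of 3 cycles per frequency (Gaussian envelope SD
\(\sigma_t = n_{cycles}/(2\pi f)\), truncated at ±5 SD, unit energy) on
19 log-spaced frequencies from 3.9 to 37.2 Hz. Samples closer to an epoch
edge than half a wavelet are marked invalid (NA) instead of being silently
zero-padded; analyses therefore epoch wide (e.g., -800 ms) and crop later,
so the windows of interest are clean. Power is averaged per condition,
percent-baseline corrected ((x - b)/b, baseline -300 to -100 ms), averaged
over the bins inside the closed band (low beta 12-20 Hz, high beta
21-30 Hz) and over sensors, and the negated - affirmative difference is
tested one-tailed (greater) with the cluster machinery.

Two consequences of the 3-cycle choice: unit-energy normalization boosts
lower-frequency bins by \(\sqrt{\sigma_t}\), so a tone falling *between*
bins can peak one bin low (localization is guaranteed only to one bin
spacing); and the spectral SD is f/3 (~6.6 Hz at 20 Hz), so adjacent bands
are not spectrally isolated — a burst inside one beta band measurably leaks
into the other, and a one-sample t across participants will detect any
consistent leak regardless of its size. Band specificity is therefore a
matter of degree between neighboring bands (the injected band carries much
more cluster mass) and strict only across wide spectral gaps; the tests are
written accordingly.

## Mechanism adjudication

Per participant, approach (i) and approach (ii) yield three AUC time series;
group-level cluster tests in the 0-500 ms window (the adjective's
lexical-semantic processing range; windows are configurable) produce the
evidence flags, and "≈ chance" is operationalized as the absence of a
significant cluster at α — cluster significance being the pipeline's only
inferential currency. The decision rule:

| evidence | verdict |
|---|---|
| transfer both above and below chance | indeterminate |
| transfer below chance, or probabilities swapped | inversion |
| transfer above chance + negated < affirmative (or attenuated probabilities) | mitigation |
| transfer above chance, no affirmative-negated difference | no_effect |
| no transfer in either direction + affirmative decodable in pooled test | change |
| anything else | indeterminate |

One deliberate asymmetry: the **change** verdict does *not* require the
pooled-test negated AUC to be at chance. A linear classifier trained on the
pooled conditions provably learns a discriminant with positive loadings on
both the affirmative pattern \(p\) and the orthogonal negated pattern
\(q\) (the class-mean difference is \(f_{aff}\,p + f_{neg}\,q\)), so pooled
negated accuracy sits near
\(\Phi\!\big(f_{neg}\,\mathrm{snr}/\lVert f\rVert\big) \approx 0.8\) at the
default design — it carries no evidence against an orthogonal
representation. The diagnostic signature of change is the combination of
chance-level *transfer* with preserved affirmative decodability; the
negated flag is still computed and reported. The decision table is total
and deterministic over the full flag space (enumerated in the tests).

## Problem sizes and what the studies show

The recovery study simulates, per mechanism, 20 independent datasets of
10 participants × 20 trials per cell × 30 sensors at snr 1, decodes every
participant (10-fold pooled + generalization over a -100-600 ms epoch), and
adjudicates with 10,000-permutation cluster tests; the true mechanism must
be recovered in at least 90% of datasets. The residual errors are exactly the
cluster tests' α-level false positives (e.g., a spurious below-chance
transfer cluster turns one *change* dataset into *inversion*), so recovery
near 95% per mechanism is the calibrated expectation, not a shortfall.
Decoder calibration uses 50 label shuffles; FWER calibration 500 null
simulations; the trajectory signature runs at the full default design with
10,000 permutations. These sizes are the package's chosen desk-scale study
conditions and are reported alongside every quantity the acceptance script
writes.

## Known limitations

* The generator's noise is white and its class pattern shared across
  participants; real sensor noise is colored and topographies vary, so
  real-data AUCs and cluster extents will differ even when the mechanism is
  the same.
* Mechanisms are assumed stationary within the analysis window; a
  combination of mechanisms unfolding over time maps onto per-window
  verdicts (run `adjudicate()` with different windows), not onto the single
  default verdict.
* Only 1-D (time) cluster adjacency is implemented; spatial and
  spatio-temporal clustering, source reconstruction and source-space
  decoding are out of scope.
* The RT filter and the ANOVA assume one summary value per cell; unbalanced
  designs beyond the 2×2 (+ 2-level complexity) factorials are not
  supported.
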