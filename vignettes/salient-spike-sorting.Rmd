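---
title: "Salient-feature spike sorting: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Salient-feature spike sorting: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salientsort)
```

This vignette is the package's own account of the science it
implements: the statistics, the procedures, the parameters that matter,
the places where the design was genuinely open and what we chose there,
and what the synthetic experiments do and do not demonstrate.

## The problem

An implanted neural recording front-end detects extracellular action
potentials and must attribute each one to the neuron ("unit") that
fired it, in real time, under severe silicon constraints. The workable
division of labor is: an external machine receives a batch of spikes,
labels them, learns a *tiny* classifier, and writes that classifier's
parameters into on-implant registers; the implant then classifies each
incoming spike with a few integer comparisons. Everything in this
package serves that loop: the learned object must be small (a handful
of sample indices and interval bounds per class), and the online
decision must be expressible with integer comparators.

## Spike waveforms and the synthetic generator

A spike is a `K = 48`-sample window (1.6 ms at 30 k samples/s) aligned
so that the first threshold crossing sits at sample index 8 (0-based),
quantized to signed 8-bit amplitudes. The generator emulates this:

- **Templates** are biphasic — a Gaussian-shaped negative trough
  (depth 60–110 amplitude units, width 1.2–2.4 samples, latency drawn
  without replacement from a coarse grid over samples 9–23) followed by
  a slower positive rebound (30–60 % of trough depth, 6–12 samples
  later, width 3–6 samples). Drawing latencies without replacement
  keeps the 2–4 units on a channel morphologically distinct, as
  different neurons seen by one electrode are.
- **SNR** is defined as template peak-to-peak amplitude divided by
  twice the noise standard deviation. The convention is declared, not
  derived; any monotone alternative only relabels the axis.
- **Noise** is i.i.d. Gaussian per sample. In the multi-channel
  studies the noise floor is *shared by all units on a channel* — the
  background is the electrode's, not the neuron's — so per-unit SNR
  varies through spike amplitude. The channel SNR scale is drawn from
  a lognormal (median 3.5, log-sd 0.8, clipped to 0.5–15), giving
  per-unit SNRs spanning roughly 0.3–22 with a mean near 4.5, the
  regime reported for cortical array recordings.
- **Quantization** is mid-tread signed, full scale 1.2 × the largest
  template excursion, saturating (never wrapping).
- **Jitter** defaults to 0 samples; robustness experiments may set
  ±1 sample of alignment jitter.

What the generator does *not* emulate — and therefore what no test
here can establish about real data: overlapping spikes (collisions),
electrode drift, bursting-related amplitude attenuation, correlated or
non-Gaussian noise, and multi-electrode geometry. Passing the synthetic
suite shows the algorithms are implemented correctly and behave as
designed in their intended regime; it does not certify field
performance.

## Discrimination, saliency, homogeneity

For one feature (sample index) `k`, classes `i` and `j` with moments
`μ, σ` and priors `P`, the discrimination index is

$$d_{ij}[k] = \exp\!\left(\frac{|\mu_i[k]-\mu_j[k]|}
  {\sqrt{P_i\sigma_i^2[k]+P_j\sigma_j^2[k]}}\right) \ge 1 .$$

It is symmetric, equals 1 when means coincide, and grows exponentially
with the prior-weighted standardized mean gap. When both variances
vanish, the exponent is taken as 0 when the means agree and is clipped
at `E_max = 30` otherwise (`e^30 ≈ 1e13` dominates any finite
competitor without overflowing a double); the clip is flagged.

The saliency of class `i` on feature `k` combines *how far* the class
sits from all others (a weighted geometric mean of the `d_ij[k]`) with
*how evenly* it is separated from them — the homogeneity, a
geometric-to-arithmetic mean ratio that equals 1 exactly when all
distances agree (AM–GM):

$$\varsigma_i[k] =
  \frac{\left(\prod_{j\ne i} d_{ij}[k]^{P_j}\right)^{2}}
       {\sum_{j\ne i} P_j\, d_{ij}[k]} .$$

### The weighting choice

`class_saliency()` evaluates this formula literally by default. But
note what happens when the weights `P_j` are the global class priors:
their mass over the competitors is `S = 1 - P_i < 1`, and for two
classes the statistic behaves as `d^{2S-1}/S` — *constant* in `d` at
balanced priors and *decreasing* when the competitor's prior is below
one half. A feature-selection criterion built on it would then prefer
the least separating samples on two-unit channels. We therefore expose
a `renormalize` option — weights rescaled to sum to 1 over the
competitors — under which the saliency equals geometric-mean ×
homogeneity exactly and is strictly increasing in every `d_ij`, for
any number of classes. The profile/selection pipeline
(`build_profiles()`, `select_salient_features()`) defaults to the
renormalized weighting; the literal form remains available everywhere
for direct evaluation of the formula. Both modes coincide up to
normalization whenever the competitor priors already sum to 1.

### Greedy selection

The first selected feature is the saliency argmax; step `l` maximizes
`ς_i[κ] · ∏_{h<l} (1 - ρ_i(κ, k_h))` over the remaining features.
Open choices resolved here: `ρ` is the *absolute* Pearson correlation
(anti-correlated features are equally redundant) computed over the
spikes of class `i` only (the class-conditional reading of the
subscript; a pooled option exists); ties in every argmax break toward
the smallest feature index, making selection deterministic; standard
deviations use the `n − 1` estimator. The feature space is the raw
aligned samples — a deliberate match to the hardware, which can index
a sample but not compute a transform.

## Window discrimination

Each class is assigned one axis-aligned box over its own `L` salient
features (default `L = 2`); a spike matches a class iff every salient
sample value lies within the closed interval. Closed bounds match
comparator `≤` semantics and are stable under quantization. The
architecture only fixes what a window *is* — per-class interval bounds
in registers — not how it is fitted, so the fitting procedure is this
package's design:

1. **Initialize** at the class's 1st and 99th percentile per feature.
2. **Refine** coordinate-wise: candidate bounds are the class's order
   statistics; each `(lower, upper)` pair is scored by the one-vs-rest
   balanced accuracy `J = (TPR + TNR)/2` with the other coordinates
   held fixed; ties prefer the wider window; sweeps repeat to
   convergence (at most 10).
3. **Margin step.** `J` is piecewise-constant, flat wherever a bound
   moves through empty amplitude space, so the grid search alone leaves
   bounds pinned to the class's own training extremes — and held-out
   spikes in the distribution tails then fall off the window edge. The
   final step realizes the wider-window preference beyond the class's
   own values: each bound moves halfway toward the nearest competing
   spike beyond it (maximum-margin placement), or to the pooled data
   range when no competitor is in the way. Training `J` is unchanged
   by construction.

Multi-label conflicts resolve by normalized depth,
`min_l (1 − |x_l − c_l| / w_l)` over the window's dimensions
(zero-width dimensions count as depth 1), ties toward the smallest
class label; no match yields the explicit `UNCLASSIFIED` category,
which all accuracy metrics count as an error.

## Offline clustering

When training spikes arrive unlabeled, Euclidean k-means runs on the
raw 48-dimensional waveforms (no projection — the method's own feature
selection happens later, per class) with k-means++ seeding and the
best of 10 restarts by inertia; `k` is chosen from 2–4 (the plausible
per-channel unit counts, configurable) by maximal mean silhouette,
ties to the smaller `k`. Degenerate silhouette conventions: `0/0 → 0`
and singleton clusters score 0. Lloyd iteration is delegated to
`stats::kmeans`; seeding, restart selection, and the silhouette (whose
edge conventions the tests pin down) are implemented here.

## Evaluation metrics

Per-class CA is recall — the fraction of a class's test spikes given
its label. The chance level of a class is its empirical frequency in
the test set (the expected recall of proportional random guessing),
and

$$\mathrm{CA}_{\mathrm{CLI}} = \frac{\mathrm{CA} - \mathrm{Chance}}
  {1 - \mathrm{Chance}}$$

maps chance to 0 and perfection to 1 (negative below chance). Overall
accuracy is reported both spike-weighted and class-weighted. The
Gaussian naive Bayes reference classifier floors per-feature variances
at `1e-9` × the mean feature variance so quantized data cannot produce
singular likelihoods. The static-feature baselines (SDE, FSDE, DDsE,
ZCF) follow their one-line textbook definitions — extrema of the
waveform and its discrete differences, first zero crossings after the
trough — and are simplified reconstructions, not reimplementations of
the methods they echo.

## The fixed-point emulator

The on-implant sorter is modeled bit-accurately: 5-bit feature-index
registers, 7-bit signed bound registers, 3-bit class identifiers,
8-bit samples. Bounds quantize onto the grid of step
`full_scale / 2^{bound\_bits-1}` (step 2 in sample units at the
defaults) with the lower bound rounded down and the upper rounded up:
quantized windows *contain* their trained originals, so the
fixed-point path can gain spurious matches but never lose a true one.
With 8-bit samples against 7-bit bounds this is equivalent to ignoring
the sample's least-significant bit at the comparator. Classification
then runs with integer-only arithmetic, including conflict resolution,
which compares the depth fractions in exact integer rational form.
Two reconciliations the architecture leaves open are bridged
explicitly: 5-bit indices address only 32 of the 48 samples, so the
training pipeline's `emulator_compatible` mode (the default) restricts
feature selection to samples 0–31 — early samples around the trough,
where the discriminative mass sits; and 3-bit class identifiers suit
the ≤ 4 units per channel. The register banks for 512 stored classes ×
2 features then cost `512·2·5 = 5120`, `512·2·2·7 = 14336`, and
`512·2·3 = 3072` bits — 5, 14, and 3 kibit:

```{r memory}
memory_report()
```

## Numerical and procedural choices

- All generators and studies take explicit integer seeds; every
  randomized result in the package is bit-reproducible from them.
- Train/test splitting is stratified per class at 50/50 with a seeded
  shuffle.
- Argmax ties anywhere resolve toward the smallest index or label.
- `E_max = 30` clips degenerate-variance exponents.
- Quantization saturates; the emulator refuses non-integer grid steps
  rather than silently leaving integer arithmetic.

## Study sizes

The packaged experiments use 50 channels × 400 spikes for the
end-to-end sorting study, 100 runs × 200 spikes for planted-feature
recovery, and 200 channels × 300 spikes × 12 sampled features per
class for the saliency-accuracy diagnostic — sizes at which the
reported aggregates are stable to well under a percentage point across
seeds while a full run stays comfortably interactive.

```{r study, eval = FALSE}
st <- sorting_study(n_channels = 50, seed = 1)
mean(st$overall_ca); mean(st$agreement)
```

## Known limitations

- Axis-aligned windows cannot represent oblique class boundaries; the
  depth rule is a heuristic, not a posterior.
- The saliency statistic sees only mean differences: two classes
  differing purely in variance are invisible to it (and nearly so to
  the window discriminator).
- Clustering on raw waveforms degrades sharply below SNR ≈ 2; the
  silhouette criterion can merge similar units.
- The planted-feature and end-to-end results are conditional on the
  generator's template family and i.i.d. noise; see the generator
  section for what that excludes.
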