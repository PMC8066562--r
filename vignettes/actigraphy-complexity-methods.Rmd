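---
title: "Methods: complexity analysis of sleep actigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complexity analysis of sleep actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(actiplex)
```

This vignette is the package's own account of the models and conventions
it implements: what each stage assumes, which constants matter, what the
synthetic generator does and does not emulate, and where the design was
genuinely open and a choice had to be made.

## The analysis chain and its assumptions

The object of study is a night of body movement recorded by a worn
accelerometer, reduced to a 1 Hz non-negative magnitude series of 28,800
samples (8 h) anchored at sleep onset. Two views of the same night are
analyzed in parallel: the **raw** magnitude series (how strongly the body
moves) and the **thresholded** series, binarized at the per-recording
median (whether the body moves). Group contrasts in the thresholded view
are the scientifically interesting ones: movement *occurrence* carries the
irregularity signal.

The chain assumes: a fixed 1 Hz sampling grid; that gravity appears as a
near-DC component separable by a 0.0028 Hz high-pass; that sleep onset is
identifiable as the first 10 consecutive minutes below 0.1 G; and that a
night is long enough (8 h) for scale-300-s entropies and a 2-h DFA fit
range to be meaningful.

### Preprocessing

* Block averaging (32 → 1 Hz) takes plain means over non-overlapping 1-s
  blocks; a trailing partial block is dropped.
* The high-pass is a 4th-order Butterworth applied forward–backward
  (zero phase). Only the cutoff (0.0028 Hz) and purpose are dictated by
  the protocol; the design is ours. `signal::filtfilt` performs no edge
  handling, so the filter pads by odd reflection over ten filter time
  constants on both ends; a constant input then maps to ~1e-12 rather
  than to a visible edge transient.
* RMS across axes uses division by 3 (a literal root *mean* square), not
  the Euclidean norm. The two differ by √3, and every downstream statistic
  is invariant to positive scaling, so the choice is cosmetic but fixed.
* The onset anchor is the **start** of the first qualifying quiet run (the
  protocol is ambiguous between start and end; the start maximizes usable
  data). The "0.1 G/s" quiescence threshold is read as 0.1 G on the 1 Hz
  magnitude series.
* Median binarization is strict (`value > median` → 1), so ties — e.g. a
  sparse movement trace resting on a constant noise floor — binarize to 0,
  and at most half the samples can be 1.
* All moving averages, at every stage, are trailing valid-mode windows
  (output j = mean of input [j, j+w)); an output sample is stamped with
  the *end* of its window, which is how series at different scales are
  aligned before correlation.

### Stationarity screen

The first half-night's value distribution is compared with the whole
night's: bins are equal-probability quantile bins of the entire series
(invariant to monotone transforms; 5 bins for raw data, the two values
themselves for binarized data), observed counts come from the first half,
expected counts are (N/2) × whole-series proportions, and the Pearson
statistic is referred to χ² with bins−1 degrees of freedom. Because the
first half is *part of* the reference distribution, the statistic is
roughly half a true χ² and the screen is conservative: on i.i.d. input it
rejects at ~1e-3, not 5% (measured over 1,000 draws in the test suite).
It is used as the original protocol uses it — as a descriptive screen,
not an exact test. When a point mass (e.g. a constant noise floor) holds
so much probability that quantile bins collapse, the screen falls back to
a two-bin presence/absence split and says so.

### Determinism (false nearest neighbors)

The delay τ is the 1/e decay time of the autocorrelation (biased,
mean-removed, computed via FFT), taken as the cohort median per data
type. The input is moving-averaged over τ, embedded at dimensions
d = 1…10, and each point's nearest neighbor (Euclidean metric, Theiler
window of τ samples, distance ties broken to the smallest index) is
tested twice: ratio test (extension distance > 10 × neighbor distance)
and size test ((d+1)-dimensional distance > 2σ, σ the population SD of
the averaged series). The combined fraction counts failures of either
test. Neighbors are re-searched at every d. Pairs at zero distance —
routine for binarized data — cannot be judged by the ratio test; they are
skipped there (a conservative choice), remain eligible for the size test,
and are reported as a diagnostic count.

A known property of this exact construction, worth stating because it is
easy to misread as a bug: for Gaussian noise at N = 10,000 the combined
fraction does *not* stay above 0.2 at every dimension — it dips to
~0.17 around d = 5–6, where the ratio test has died out but typical
(d+1)-dimensional nearest-neighbor distances are still below 2σ. The
meaningful statement for stochastic inputs is that the fraction never
approaches zero (it stays above ~0.15 and rises again), in sharp contrast
to a deterministic orbit (Hénon map), which drops below 0.05 from d = 2.

### Irregularity (ApEn, SampEn, expSampEn)

All three measures share one counting convention: vectors are "close"
when their Chebyshev distance is ≤ r × SD (population SD, divisor N) of
the scale-averaged series, with m = 2 and r = 0.2; logarithms are
natural (nats). The protocol does not state the log base or self-match
convention, so these are fixed as follows, and this is the only pairing
under which the claimed identity holds exactly:

* **expSampEn(n)** = −log p(x_n | x_n⁻), with both the m-match count and
  the (m+1)-match count taken over the same template positions and
  *including* the self-match — every conditional probability is then in
  (0, 1], so expSampEn is finite and non-negative everywhere.
* **ApEn** is the time average of expSampEn (exactly; the classic
  Φ^m − Φ^{m+1} form differs only by O(1/N) edge terms).
* **SampEn** keeps its standard self-match-*excluding* pair-count
  definition, −log(A/B).

The multiscale protocol is a trailing moving average over 30, 100 and
300 s with the tolerance recomputed from the SD of each averaged series
(this is what makes the measures invariant under positive affine
transforms of the input, and it is *not* Costa-style block
coarse-graining). Computationally, the counting kernel compresses
duplicate templates (a binarized, moving-averaged night takes a few
thousand distinct (m+1)-tuples) and hashes the remainder on a grid of
cell size equal to the tolerance; both accelerations are exact, and the
test suite pins them to a brute-force R oracle at 1e-12.

### Long-range correlation (DFA)

DFA1: the profile is the cumulative sum of the mean-removed series
(single cumulation — the series itself is the increment process); windows
of size n are laid both from the start and from the end so the tail
contributes; a least-squares line is removed per window; F(n) is the RMS
residual over all covered points; α is the OLS slope of log₁₀F on log₁₀n
over 300–7,200 samples (5 min–2 h), on a 20-point log-spaced grid.
Validation anchors: α ≈ 0.5 on white noise, ≈ 1.0 on spectrally
synthesized 1/f noise, and α ≈ H on circulant-embedding fractional
Gaussian noise for H ∈ {0.6…0.9}, each within ±0.05–0.1 at N = 28,800.

### Nonlinearity (IAAFT surrogates)

Surrogates alternate a spectrum step (impose the original Fourier
amplitudes on the current phases) and an amplitude step (rank-remap onto
the original sorted values), from a seeded random shuffle, stopping when
the rank ordering stabilizes or after 100 iterations, and **ending on the
amplitude step**: the surrogate is a permutation of the original values
(distribution exact, spectrum approximate). Ensembles default to 20
members with per-member derived seeds. Welch spectra (Hann windows,
2,048-sample segments, 50% overlap — conventional values, not dictated by
the protocol) verify spectrum preservation; the relative periodogram error
on an AR(1) at N = 4,096 is well under 5%.

Two comparison modes exist: the cohort-level paired Student t-test of
original minus surrogate-ensemble mean (the protocol's test), and a
single-recording rank test (reject at 0.05 with 19–20 surrogates only if
the original is more extreme than every member). Calibration of the rank
test, measured in the test suite: for a *mild* static monotone transform
of a Gaussian AR(1) (we use exp(y/4), a gentle lognormal-like distortion
of the kind a measurement chain plausibly applies), the one-sided size is
~4% at N = 1,024 — inside the nominal band. For *strong* static
nonlinearities (y³, exp(y)) the test over-rejects badly (50–90%), and
this worsens with N: no permutation of a heavily skewed marginal can
attain the original spectrum, so the surrogates are systematically
whiter. This is intrinsic to IAAFT (an independent implementation
reproduces the same spectral error to within 1%), and it is a real
limitation to keep in mind when the analyzed series is strongly
non-Gaussian.

### Group statistics

Classic equal-variance Student t-tests throughout. Group comparisons are
one-tailed in the "group B lower" direction — the convention is forced by
the protocol's printed pair (T = 2.17 with 17+17 subjects, one-tailed
p = 0.019; two-tailed would print 0.038). Nights are averaged within
subject before any group test (the subject is the independent unit).
Pointwise tracks are 60-min trailing means of expSampEn, tested per time
point with **no multiple-comparison correction** — reproduced faithfully
from the protocol, with the obvious caveat that familywise error is
uncontrolled and the tracks are descriptive. State representatives are
the 90th/10th percentiles (linear interpolation between order statistics)
of the smoothed track. Spearman cross-measure tables correlate the
60-min-smoothed raw series, thresholded series and their expSampEn tracks
on their common time support, then average per pair across recordings.

## The synthetic actigraphy generator

Real overnight recordings of clinical cohorts are not shareable, so the
package generates its own study conditions:

* a two-state semi-Markov regime path (high-/low-irregularity) with
  **truncated-exponential dwells** (mean parameter 5,400 s, truncated to
  75 min–4 h). The truncation emulates ultradian sleep-state alternation
  and serves two structural purposes: no night is a single state (an
  untruncated exponential produces one ~0.5% of the time, and a
  single-state night of the regular group has a near-constant binarized
  profile whose SD-relative tolerance collapses, exploding expSampEn),
  and every dwell can contain 60-min smoothing windows lying wholly
  inside one state, so the low-irregularity representative is not
  contaminated by high-state values;
* movement events as a gamma renewal process: rate 0.20/s in the high
  state, 0.02/s in the low state; inter-event interval CV 1.0 in the low
  state for both groups, and in the high state 1.0 for group A versus
  0.3 for group B — the entire group effect, placed on the variability of
  movement *occurrence* in the high-irregularity state only;
* lognormal event magnitudes (meanlog log 0.05 G, sdlog 1 — heavy-tailed,
  as movement bursts are) on a constant 0.001 G noise floor, which keeps
  the median threshold a clean presence/absence split;
* per-subject lognormal trait multipliers, fixed across a subject's
  nights: sdlog 0.05 on the high-state rate, 0.4 on the low-state rate,
  0.1 on the dwell mean. Children differ far more in how much they move
  during quiet sleep than during active epochs; statistically, this
  heterogeneity is what keeps the low-state representative's group test
  at its nominal level despite small protocol-induced couplings (the
  night-wide tolerance and template library tie the two states together
  weakly, at the ~0.003 nat level).

Every generator function is a pure function of its arguments; cohort
seeds derive deterministically from the master seed and the (group,
subject, night) labels.

What the generator does **not** emulate: 32 Hz within-second dynamics
(the tri-axial up-sampler exists only to exercise the preprocessing
chain), circadian drift across the night, movement-duration structure
(events occupy one sample), sensor noise and artifacts, or any direct
model of sleep stages. Consequently, passing cohort tests demonstrates
that the *pipeline* recovers a known occurrence-irregularity deficit
under realistic length, phase structure and heterogeneity — not that real
TD/ASD cohorts behave like the generator.

One subtlety the generator exposed: at the default event density
(0.2/s ⇒ mean interval 5 s), SampEn computed directly on an isolated raw
binary segment with a segment-local tolerance is *not* lower for the
regular group — an m = 2 template spans 3 s and cannot resolve a
5-s-period pattern. The occurrence-regularity effect appears in the
quantity the protocol actually computes: the expSampEn track of the
scale-averaged thresholded series under the whole-night tolerance,
averaged over high-state epochs (lower for group B in 20/20 seeds).

## Validation problem sizes

The acceptance-style suite runs the analytic limits at the full study
length (N = 28,800, 10 seeds each), the oracle-equality checks at
N ≤ 2,000, IAAFT null calibration at N = 1,024 over 200 draws, and the
cohort pattern recovery on ten full-size cohorts (2 × 17 subjects ×
3 nights × 28,800 samples) — the duplicate-compressed entropy kernel
makes a full cohort cost ~3 s. The level of the representative-value
test under the null is checked on 200 reduced cohorts (12 subjects/group,
one 3-h night, scale 30 s): the level of a t-test does not depend on the
series length, and the reduced size keeps the 200-draw calibration to
under a minute. The end-to-end pipeline smoke test uses 4 subjects/group
with 2-h nights and proportionally shortened dwells and smoothing.

## Known limitations

* The FNN white-noise floor dips below 0.2 at intermediate dimensions
  (see above); "does not converge to zero" is the robust criterion.
* The IAAFT rank test over-rejects for strongly non-Gaussian marginals.
* The stationarity screen is conservative by construction (overlapping
  halves).
* No multiple-comparison correction on pointwise tracks, by protocol.
* The one-tailed convention presumes the direction (B below A) a priori;
  a two-sided analysis would halve nothing but honesty demands noting
  that the direction was fixed by the protocol being reproduced.
* DFA is first-order (linear detrending) only; crossover scales are not
  modeled, and the single fit range 5 min–2 h is applied to every series.
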