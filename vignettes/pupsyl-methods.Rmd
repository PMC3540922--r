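---
title: "Methods: models, thresholds and design choices in pupsyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in pupsyl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pupsyl` classifies mouse pup ultrasonic isolation syllables. This vignette
is the package's account of the underlying science: the models and their
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic data generator does and does not emulate, and the
places where the design was genuinely open and a choice had to be made.
Every empirical statement here is one the test suite or the acceptance
script computes itself.

## 1. Detection and contour extraction

**Model.** A syllable is a continuous unit of vocal emission bounded by
silence. Detection thresholds a short-time RMS envelope (default 0.5 ms
frames) at `threshold_db = 10` dB above the noise floor, with a
`hold_ms = 5` ms hold time: sub-threshold gaps shorter than the hold time do
not split a syllable, accommodating brief intra-syllable intensity dips. No
minimum syllable duration is imposed.

**Noise floor.** Commercial systems do not document their estimator; we use
the median frame RMS of the recording. This is robust for its intended
regime — long recordings with sparse vocal activity — and is *biased* when
more than half of the recording is vocal (the floor then sits on syllable
energy and nothing is detected). Recordings of exactly-zero silence are
handled specially: the floor is −∞ dB and every non-silent frame counts as
active.

**Spectrogram.** Hamming window, FFT length 1024, overlap 98.43% (hop
`round(1024 × 0.0157) = 16` samples), frequency axis truncated to 40–130
kHz. At the nominal 500 kHz sampling rate this gives ~0.49 kHz bin width
and 32 µs frame spacing. Linear magnitude is returned; the dominant
frequency is the argmax bin per frame, with ties broken toward the lower
bin so results are deterministic. No spectral interpolation is performed —
the downstream thresholds (20 kHz, 85 kHz) are far coarser than a bin.

**Nine measurement points.** The protocol measures the dominant frequency at
nine evenly spaced time points, but "evenly spaced" does not fix endpoint
handling. Default: interior midpoints, `t_i = start + (i + 0.5)/9 ×
duration`. This deliberately avoids the syllable onset/offset, whose low
amplitude is the documented source of spurious F₀ values. Endpoint-inclusive
spacing (`i/8`) is available via `placement = "endpoint"`.

**Bandpass replacement.** Contour values outside 41–129 kHz are replaced by
the previous in-band point. The published rule is undefined when the *first*
point is out of band; we back-fill from the first in-band value, so the
filter never manufactures out-of-band output and is idempotent. A contour
with all nine points out of band is flagged invalid and reported, never
silently dropped. Step counting operates on the *filtered* contour, since
the filter exists precisely because spurious values corrupt downstream
calculations.

## 2. Features and the bimodality machinery

Per syllable: start / middle / end frequency (points 1, 5, 9), mean of the
nine filtered points, bandwidth (max − min), directional FM (end − start,
signed), duration, and the step count — the number of adjacent-point
transitions strictly greater than 20 kHz in absolute value. The strict
inequality follows the published wording ("greater than 20 kHz"); an
inclusive option exists.

**Bimodality coefficient.** The literature names the statistic but not the
formula; we adopt the SAS/SPSS moment-based coefficient with finite-sample
corrections,

$$ b = \frac{g_1^2 + 1}{g_2 + \frac{3(n-1)^2}{(n-2)(n-3)}}, $$

with $g_1$ the bias-corrected sample skewness and $g_2$ the bias-corrected
excess kurtosis, because its uniform-distribution reference value 5/9 ≈
0.555 matches the published evidence threshold ("b > 0.55"). Asymptotic
anchors verified by the tests: uniform → 5/9, normal → 1/3, a 50/50
two-point mixture → 1.

**Boundary suggestion.** `suggest_boundary()` histograms a sample (default
bin width 2 kHz — fine enough to separate bands ~30 kHz apart, coarse enough
not to ride sampling noise), requires `b > 5/9` (otherwise it warns and
returns no boundary), finds the two highest-count peaks at least 3 bins
apart, and returns either their midpoint (`midway_peaks`, mirroring how the
20 kHz step criterion was chosen) or the emptiest bin between them
(`histogram_valley`). On the default synthetic repertoire the suggested
high/low boundary lands in 80–90 kHz, consistent with the published 85 kHz
CBA/CaJ value.

## 3. Two-step cluster analysis

The published analysis names the algorithm (SPSS TwoStep), its distance
(log-likelihood), its selection criterion (Schwarz's BIC) and its CF-tree
defaults (8 branches, depth 3), but none of the formulas. We implement the
Chiu et al. (2001)-style formulation:

- **Tightness** $\xi(v) = -n_v \sum_k \tfrac12 \log(\hat\sigma_k^2 +
  \hat\sigma_{vk}^2)$, where $\hat\sigma_k^2$ is the global variance of
  variable $k$ (a regularizer making singletons well-defined) and
  $\hat\sigma^2_{vk}$ the within-cluster population variance, both computed
  exactly from CF sufficient statistics $(n, \sum x, \sum x^2)$.
- **Distance** $d(a,b) = \xi(a) + \xi(b) - \xi(a \cup b)$: symmetric,
  non-negative, zero for identical singletons, with the closed form
  $d = \log(1 + \Delta^2/4)$ for two singletons $\Delta$ apart in one
  variable of unit global variance (used as a test oracle).
- **BIC** $-2\sum_c \xi(c) + 2pk\log n$ with $2p$ parameters (mean and
  variance per variable) per cluster.

**Pre-clustering.** The CF structure is height-collapsed: a flat leaf-entry
list with the capacity the published tree shape implies
(`max_branches^max_depth` = 512), absorbing each row into its nearest entry
when within the current threshold. The threshold starts at 0 (so only exact
duplicates merge) and is raised on capacity overflow to
`max(min pairwise distance, q25 of nearest-neighbour distances, 2 × previous)`
before re-inserting — the pure "smallest observed merge distance" rebuild
can merge a single pair per rebuild and degenerate to O(n·cap²). Everything
downstream (conservation of sufficient statistics, leaf purity, capacity
bound) is unaffected by the collapse; tests check those properties directly.
`disable` mode yields one singleton entry per row, making the subsequent
agglomeration *exactly* equal to an exhaustive brute-force hierarchy (tested
to machine precision at n ≤ 50).

**Choosing k.** The SPSS-style two-stage rule: (1) the smallest k whose BIC
improvement ratio relative to the first improvement drops below
`bic_ratio = 0.04`; (2) among k below that estimate, the ratio of successive
merge distances — if the largest ratio exceeds `dist_ratio = 1.15` times the
second largest its k wins, otherwise the larger of the two candidates. SPSS
does not publish its constants, so both are exposed in the clustering
config; exact agreement with SPSS on arbitrary data is therefore not
guaranteed (and is not claimed).

**The unimodality guard (own design).** With hard assignments, splitting
even a single Gaussian always improves this BIC by O(n) against a penalty of
O(log n) — a known overclustering property of TwoStep-type criteria — so the
two-stage rule alone can never return k = 1. Since the package's whole
thesis is that category boundaries must be justified by multimodality, we
close the gap with the same tool used for thresholds: the k = 2 partition is
projected onto the axis joining its two centroids (on standardized
variables) and k = 1 is returned when the projection's bimodality
coefficient is ≤ 5/9. Limitation: a multi-cluster arrangement whose top
split projects to a unimodal axis would also collapse; this requires a
near-symmetric geometry we have not observed with these variables.

**Other choices.** The step count enters as a continuous variable (matching
the published treatment); variables are *unstandardized* for clustering (the
distance normalizes through its variance terms) while the silhouette of
cohesion uses standardized Euclidean distance; tie-breaks are
lowest-index-first everywhere, so runs are reproducible. Final per-row
assignment is to the nearest final cluster by log-likelihood distance; for
boundary points this may differ from the merge-tree membership (both are
returned: `assignments`, `tree_assignments`). Outlier/noise-leaf handling is
omitted. The silhouette is the textbook mean of $(b_i - a_i)/\max(a_i,
b_i)$; singleton clusters contribute 0.

## 4. The calculator

Deterministic, total, applied in order: more than one step → `multi_step`;
exactly one → `one_step`; otherwise `high` iff mean contour frequency ≥
boundary, else `low`. Comparisons replicate the published wording exactly
(strict `<` for low, `≥` for high). Strain presets: CBA/CaJ 85 kHz, IRW 73
kHz, C57BL/6 70 kHz, all with the 20 kHz step criterion. Agreement between
labelings maps the smaller label alphabet into the larger by
maximum-agreement injective assignment (exhaustive; the published comparison
of anonymous cluster indices against named categories does not state its
mapping procedure, and the optimal mapping is the only non-arbitrary
choice).

## 5. The synthetic repertoire: what it emulates, what it does not

The generator's defaults are the package's stated world, chosen once from
the published repertoire structure:

- **Bands.** Non-stepped syllables start in a low band N(70, 4²) kHz or a
  high band N(100, 5²) kHz — consistent with the reported ~60–80 and
  ~90–120 kHz bands — and evolve as a random walk clamped to the 41–129 kHz
  analysis band.
- **Smooth modulation.** Adjacent-point deltas are N(0, s²) with the
  *per-syllable* scale s ~ Uniform(1, 5) kHz and |δ| capped at 15 kHz. A
  scale mixture rather than a fixed s = 3 is used because real non-stepped
  syllables range from near-flat to strongly modulated; pooling them yields
  a unimodal but leptokurtic directional-FM distribution. This matters
  quantitatively: a fixed s gives an essentially Gaussian FM distribution
  with b → 1/3, which would *contradict* the published b < 0.3; the scale
  mixture has analytic excess kurtosis ≈ +1.2 and lands near b ≈ 0.24. The
  choice was made on this analytic ground, not fitted to a test run.
- **Steps.** Jump magnitudes are N(40, 8²) kHz floored at 25 kHz. With the
  smooth cap (15) strictly below the 20 kHz criterion and the floor strictly
  above it, the generative step count is exact ground truth for 100% of
  syllables — the validator enforces these inequalities at spec time.
  One-step syllables jump upward once in the second half of the contour
  (low start, pre-jump plateau through the middle point, high end, matching
  the published c3 average contour); multi-step syllables (exactly two
  jumps by default, the published c2 mode) jump up in the first half and
  down in the second, so the middle point sits on the high plateau. The
  position constraints keep each generative category internally tight;
  fully uniform jump positions would make the middle-frequency variable
  bimodal *within* a category and the category count genuinely ambiguous.
- **Sizes and durations.** Defaults: n = 4000 (same order as the published
  per-age samples of ~3000–4600), equal category mix, durations uniform on
  20–120 ms, independent of category.

Consequences the tests verify rather than assume: pooled |transitions| are
bimodal with b ≈ 0.92 > 0.55; non-stepped mean frequencies are bimodal with
the midway boundary in 80–90 kHz; directional FM of non-stepped syllables
has b ≈ 0.24 < 0.3; two-step clustering selects k = 4 with silhouette ≈
0.65; calculator-vs-cluster coherence ≈ 99%.

What the generator does **not** emulate: harmonics and nonlinear phenomena
(the documented main cause of real misclassifications), movement noise,
amplitude structure beyond onset/offset ramps, per-age parameter drift, and
the soft cluster boundaries of real repertoires. A green test therefore
establishes the *pipeline's* correctness on a repertoire with the published
statistical skeleton — not performance on real recordings, where coherence
is expected to drop toward the published 94% (and 91–93% across strains).

**Audio synthesis** integrates cumulative phase so the instantaneous
frequency is exact, renders jumps as true discontinuities at the midpoint
between the two measurement points (a "spectro-temporal discontinuity", not
a glide), and applies 5 ms raised-cosine ramps plus silent padding. The
round-trip tolerance of 1.5 kHz covers the bin width (~0.49 kHz), frame
quantization, and boundary-detection jitter of the envelope framing.

## 6. Numerical and degenerate-input policy

Variances computed from sufficient statistics are clamped at ≥ 0; global
variances are floored at 1e-12; zero-variance variables standardize to 0 for
the silhouette and are reported as undefined by the collinearity screen
(|r| > 0.9 pairs warn but do not error, matching the published screen at
r = 0.9). Empty recordings and all-zero recordings detect zero syllables
(not an error); non-finite samples, all-out-of-band contours fed to
`summarize_syllable()`, fewer than 4 observations or zero variance for the
bimodality coefficient, and single-cluster silhouettes are errors. Rows with
missing clustering variables are rejected per-row and reported. All RNG use
is seeded through `repertoire_spec(seed =)`; identical spec + seed gives
byte-identical CSVs.

## 7. Known limitations

- The noise-floor estimator assumes mostly-silent recordings (see §1).
- Cluster-count agreement with SPSS's proprietary constants is approximate
  by necessity; the constants are exposed.
- The dominant frequency is tracked, not the fundamental: harmonically rich
  syllables will produce the same step-count errors documented for the
  original pipeline.
- The calculator takes the stated inequalities literally at boundaries
  (mean exactly 85 kHz → `high`); no near-boundary softening is attempted.
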