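---
title: "Methods: from helmet telemetry to midbrain white-matter change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from helmet telemetry to midbrain white-matter change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impactfa)
```

# The analysis chain

`impactfa` operationalizes a prospective season-long design: collegiate
players wear helmet accelerometers for every practice and game, undergo
diffusion MRI before and after the season, and the question is whether
the exposure they accumulate — in particular rotational loading —
explains the change in white-matter fractional anisotropy (FA) in the
midbrain segment of the corticospinal tract. The chain has five stages.

## 1. Exposure features

Each logged impact carries a linear acceleration (g), a rotational
acceleration (rad/s²), and an angular location (azimuth ∈ [−180°, 180°)
with 0° at the back of the head and +90° at the right side; elevation ∈
[−90°, 90°]).

* **Session summary** — counts, percentages, medians and means per
  session type (practice / game / other).
* **Cohort SD threshold** — `mean + 1·SD` of the pooled per-hit
  distribution. The SD is the *sample* SD (n − 1 denominator); with
  ~20,000 pooled hits the distinction is immaterial, but it is fixed and
  documented. A hit exactly at the threshold counts as suprathreshold
  (`≥`): boundary hits are exposure. Both choices are configurable.
* **Exclusive counts** — hits with rotational ≥ threshold *and* linear <
  threshold (and symmetrically), isolating each loading mode. The four
  cells (rot-only / lin-only / both / neither) partition the log, a
  property the test suite checks by brute force.
* **Decile sweep** — the nine interior decile boundaries (10th–90th
  percentiles) of the pooled distribution, used as alternative
  thresholds to show the dose-response relation is not an artifact of
  the 1-SD cut. Quantiles use linear interpolation (R type 7); any
  reasonable rule differs only at the 4th decimal with thousands of
  pooled hits.

## 2. The spatial fingerprint

A player's hits are histogrammed over 10° × 10° bins of azimuth and
elevation (36 × 18 = 648 bins) and normalized by the player's hit count,
so entries are proportions summing to 1. Conventions that needed fixing:

* bins are half-open `[edge, edge + 10°)`, with the top elevation edge
  (+90°) closed so the pole is representable;
* flattening is azimuth-major (`index = az_bin × 18 + el_bin`,
  zero-based), fixed and documented — any consistent order works, but
  one had to be chosen;
* out-of-range angles are canonicalized by wrapping azimuth and folding
  elevation over the pole (an elevation of 100° is the same physical
  direction as 80° at the opposite azimuth).

`bin_index()` is verified against an independent rectangle-enumeration
oracle on 10,000 random angle pairs. Fingerprints are built from all
hits by default; a force filter is available, since a plausible variant
restricts the fingerprint to suprathreshold hits only.

## 3. ROI FA extraction

Masks and FA volumes are assumed to live on a shared grid in a common
standard space — all registration happens upstream and is out of scope.
The tract-within-structure ROI is the voxelwise AND of a midbrain mask
and a corticospinal-tract mask; probabilistic atlas masks are binarized
at 0.5 (configurable) before intersection. Hemispheres are split by
world *x* (RAS: +x right); voxels exactly on the mid-sagittal plane are
excluded from both hemispheres to avoid double counting, and their count
is reported. Mean FA within a mask is the arithmetic voxel mean; an
empty mask is an error, because in this pipeline it signals a failed ROI
definition or registration, not a valid zero.

## 4. Univariate statistics

Pre/post comparisons use the paired *t* test and the Wilcoxon
matched-pairs signed-rank test, both two-tailed; zero differences are
dropped from the Wilcoxon test (Wilcoxon's original rule), and the exact
signed-rank null is used for tie-free samples below 50 pairs. The
mTBI-vs-control comparison is a pooled-variance two-sample *t* test
(Welch by flag). Dose-response uses Spearman rank correlation with
midrank ties; p-values come from the exact null distribution of the rank
statistic for n ≤ 10 without ties and from the *t* approximation
`t = ρ√((n−2)/(1−ρ²))` otherwise. The tau–FA association defaults to
rank correlation with a Pearson flag, and the output records which
estimator produced the number — the choice matters at n = 13 and neither
is asserted as canonical.

Degenerate inputs are reported, not hidden: constant vectors flag an
undefined correlation; all-zero differences report a no-effect row with
p = 1.

The laterality index `LI = (ΔR − ΔL)/(|ΔR| + |ΔL|)` is bounded in
[−1, 1], antisymmetric under hemisphere swap, invariant to positive
rescaling of both changes, and undefined (NA) when both changes are
exactly zero — a flag rather than a number, since 0/0 carries no
lateralization information.

## 5. Fingerprint → laterality ν-SVR

The multivariate stage asks whether the *spatial pattern* of hits
explains hemispheric asymmetry in white-matter change. With n players
and 648 features, the model is a linear-kernel ν-SVR trained with
leave-one-out cross-validation: for each player, the model is fit on the
other n − 1 and predicts the held-out player's laterality. The accuracy
statistic is the squared correlation r² between out-of-fold predictions
and observations. Inference is by permutation: laterality values are
shuffled against fingerprints, the full leave-one-out procedure is rerun
per shuffle, and `p = (1 + #{null r² ≥ observed}) / (1 + B)` — the
add-one estimator, so p is never exactly 0 and the minimal achievable
value is 1/(B + 1). Shuffles with degenerate (constant) predictions
count as r² = 0, which is conservative for the null.

Parameter choices:

* **ν = 20/37 ≈ 0.54.** The published analysis this mirrors reports "20
  support vectors" in 38-fold cross-validation; in ν-SVR, ν lower-bounds
  the support-vector fraction, so targeting ≈20 SVs out of 37 training
  rows gives ν ≈ 0.54. The realized SV count per fold is returned so the
  interpretation is auditable.
* **C = 10.** The regularization strength was genuinely open. Because
  fingerprint entries are proportions of order 1/500, the kernel matrix
  has tiny entries and C = 1 underfits badly: on noiseless planted
  linear maps at n = 40 the out-of-fold r² saturates near 0.85, while
  C = 10 reaches ≈ 0.96 with no measurable degradation of null
  calibration. C = 10 is therefore the default; it is a config knob.
* **Relevance map.** The published description — "feature weights …
  correlated across participants with observed laterality indices" — is
  ambiguous, because a weight *vector* exists per fold, not per
  participant. The implementation pairs each fold's weight at bin *j*
  with the laterality of that fold's held-out participant, correlates
  across folds, and reports the squared correlation, Bonferroni
  thresholding two-tailed p at α/648. This is one defensible reading,
  labeled as such; it reduces to a natural "how does this bin's learned
  weight co-vary with the outcome" statistic and recovers planted
  single-bin signals in tests.
* **Speed.** A linear kernel only sees dot products, so when p > n the
  rows are projected onto an exact rank-n basis (thin SVD); every fold's
  dual problem is unchanged, and primal weights are mapped back
  exactly. The solver is libsvm (via e1071), called through a thin
  wrapper that skips interface overhead in the permutation loop;
  per-fold results are verified against the public `e1071::svm()`
  interface in the test suite.

The critical-r² helper inverts the t–r relation: at α = 0.01 and 37 df
the critical r² is 0.17 after rounding; at the Bonferroni-corrected
0.05/648 and 36 df it is 0.36.

# The synthetic cohort generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream stage is validated by parameter
recovery. Defaults emulate a 38-player season:

| parameter | default | rationale |
|---|---|---|
| players | 38 | one season's complete datasets |
| hits/player | NB(mean 503, size 2.5) | ≈19,000 total; heavy between-player dispersion, as real exposure data show (starters vs reserves) |
| session mix | .59/.37/.04 | practice/game/other shares |
| linear acc | lognormal(log 25, 0.68) | median ≈25 g, mean ≈31.5 g, right-skewed |
| rotational acc | lognormal(log 1600, 0.63) | median ≈1600, mean ≈1950 rad/s² |
| azimuth | clusters at 0°/180°, sd 20° | impacts concentrate near the mid-sagittal plane |
| player effects | front/back mix ~ Beta(3,3), lateral offset ~ N(0, 25°), elevation offset ~ N(0, 12°) | players differ systematically in where they get hit; without this, fingerprints are pure multinomial noise and no spatial map could be recoverable even in principle |
| dose-response β | −1e-3 FA per suprathreshold rotational hit | plants integrity loss proportional to exposure |
| FA noise | 0.01 | moderate; planted effect detectable but not trivial |
| laterality map w* | ±0.5 lateral contrast | planted target ∝ right-minus-left hit share; noise sd 0.14 puts explainable variance near r² ≈ 0.6 |
| tau model | 30 − 50·FA_post + N(0, 2.9) | planted negative slope at strength r ≈ −0.6 in a 13-player concussed subgroup |

The right-hemisphere change is `ΔFA_R = β · #{rotational hits ≥ cohort
mean + 1 SD} + noise`. The laterality target is `⟨fingerprint, w*⟩ +
noise`, clamped to [−0.8, 0.8], and the left-hemisphere change is
*back-solved* so the laterality formula reproduces the target exactly:
for ΔR < 0, `ΔL = ΔR(1 + t)/(1 − t)` (and the mirrored form for
ΔR > 0). Back-solving, rather than simulating ΔL independently, makes
the planted fingerprint→laterality map exact up to noise so SVR-recovery
tests are well-posed. The clamp keeps the back-solved ΔL on a physical
FA scale; post FA values are clipped to [0, 1] in the rare tail cases
and change scores recomputed for internal consistency.

What the generator does *not* emulate: biomechanics (no finite-element
strain model — the dose-response is planted linearly, not derived from
physics); diffusion imaging (no tensors or raw DWI — FA values are drawn
directly); temporal structure within a season; and any correlation
between a player's exposure and their fingerprint shape beyond the
planted ones. Passing recovery tests therefore demonstrates that the
*analysis machinery* detects effects of the planted form at realistic
noise — not that such effects exist in any particular real cohort.

Per-player hit-count dispersion deserves a note: only the cohort total
is externally constrained, so the per-player distribution is a modeling
choice. Negative-binomial with size 2.5 makes suprathreshold counts
strongly exposure-driven across thresholds, which is both realistic and
what makes a decile sweep meaningful (at Poisson dispersion,
between-player count variation is so small that threshold sweeps mostly
measure binomial noise).

# Numerical and testing choices

* All randomness flows through explicit seeds (`withr::with_seed`), so
  cohorts and permutation nulls are bit-reproducible and the global RNG
  stream is never disturbed.
* Permutation runs refuse jobs above a configured fit budget
  (`n_permutations × n` fits, default 5e6) with guidance to scale down,
  rather than silently running for hours.
* Test problem sizes are chosen for desk-scale runs: oracle-equivalence
  suites use ≥1,000 random instances per operation; dose-response
  recovery uses 100 replicate cohorts at n = 38; permutation-null
  calibration uses 100 replicate null cohorts at n = 20 players with
  30° bins and 999 shuffles each (the binning coarseness affects only
  feature count, not the validity of the exchangeability argument);
  signal-detection uses a noiseless planted map at n = 40 with 999
  shuffles. A publication-scale null (100,000 shuffles at n = 38) is a
  config change away.
* The two cohort-derived force thresholds reported by the original
  study (50.7 g, 2782 rad/s²) depend on that cohort's unreleased raw
  data; the package reproduces the *procedure* (and its synthetic
  thresholds land in the same regime) but makes no claim of reproducing
  those numbers.

# Known limitations

* The SVR relevance map implements one reading of an ambiguous published
  construction (see above); an alternative — correlating per-participant
  *contributions* (weight × fingerprint entry) — is reasonable and could
  be added behind the same interface.
* Exact Spearman p-values are available only for tie-free samples;
  suprathreshold counts often tie, in which case the t approximation is
  used even at small n.
* ROI machinery assumes prior spatial normalization; there is no
  resampling, so masks and volumes must share a grid exactly.
* The laterality index is undefined when both hemisphere changes are
  exactly zero and unstable when both are near zero; with continuous
  noise this is a measure-zero event in simulation, but real FA changes
  rounded to few decimals can hit it — affected players are excluded
  from the SVR stage with a warning.
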