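---
title: "Mapping peritumoral mechanical instability from MR elastography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping peritumoral mechanical instability from MR elastography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peristab)
```

## The model and its assumptions

Magnetic resonance elastography reconstructs, per voxel, the complex
shear modulus of tissue: the storage modulus G′ (elastic energy storage,
kPa) and the loss modulus G″ (viscous dissipation, kPa). Their ratio,
the damping ratio tanδ = G″/G′, is the phase lag between stress and
strain under cyclic loading. `peristab` models the tumor–brain interface
as a boundary between two viscoelastic continua and asks where, in the
tissue just outside the tumor, elastic storage and viscous dissipation
fall out of balance *relative to the interface itself*.

The reference state is the **rim** r: the one-voxel-thick parenchymal
layer face-adjacent to the tumor. After excluding voxels with
non-positive moduli (reconstruction failures; exclusion is joint, so a
voxel invalid for either quantity leaves both medians), the rim medians
G″~r,med~ and (tanδ)~r,med~ define mechanical equilibrium. For each
valid voxel x of the peritumoral **shell** p — parenchyma within 0–6 mm
of the tumor boundary, excluding a 2 mm guard along the brain-mask
exterior (the "skull", operationalized as the mask complement since no
skull image enters the data contract) — the instability index is

$$I(x) = \ln\!\big(G''(x)/G''_{r,med}\big)\cdot
         \big(\tan\delta(x) - (\tan\delta)_{r,med}\big).$$

The logarithmic factor is the viscous contrast against the rim; the
second factor is the phase deviation. Their product makes I directional:
only *concurrent* deviations of dissipation magnitude and phase register
as positive instability, counter-directional deviations are negative
(mechanical difference without dissipative reinforcement), and either
factor alone leaves I near zero. The index is a scalar abstraction — it
carries no direction or anisotropy information — and it is
interface-referenced, so it is not a monotonic abnormality score.

Two modeling choices deserve emphasis. First, the denominator of the
log term is the rim median **loss** modulus: the term is a viscous
contrast, and the rim statistics computed are those of G″ and tanδ. A
sensitivity variant that divides by the rim median storage modulus is
available (`log_reference = "g_storage"` in `compute_case()`). Second,
the analysis treats distances physically: all region definitions use an
exact anisotropy-aware Euclidean distance transform in millimetres
(Felzenszwalb–Huttenlocher lower envelope with per-axis spacing), never
voxel counts, so anisotropic acquisitions are handled correctly.

## Per-case descriptors

On the shell, the package reports the median and 95th percentile of I,
the fractions above 0.02 and 0.05, Shannon entropy of the 32-bin
histogram on [0, 0.4] (base 2, so the ceiling is exactly 5 bits; with
the published entropy levels near 4, a natural-log convention would be
impossible since ln 32 ≈ 3.47), the integrated survival function
∫₀^0.3 P(I>t) dt (tail-AUC; computed in closed form as the mean of
min(max(I,0), 0.3)), and the negative fraction pneg.

Radial organization is summarized by mean-I profiles in half-open 2-mm
distance bands (2(k−1), 2k] up to 12 mm, restricted to parenchyma with
the same skull guard as the shell (the guard treatment beyond 6 mm is a
gap in the source protocol; applying it uniformly is this package's
resolution, and it is configurable). The radial-AUC integrates the band
means over the band centers (1, 3, …, 11 mm) by the trapezoid rule —
the least-assumption quadrature given that only an "area under the
curve" is specified; empty interior bands are linearly interpolated and
empty leading/trailing bands truncate the integral. The band statistic
is the mean (the profile of a field); a median variant would also be
defensible but is not the default.

Morphology and topology are evaluated in 2D on the axial slice with the
maximal tumor area (ties broken toward the lower index), on the
thresholded map I > τ with τ = 0.02 by default. The **domain for these
2D maps is the full 0–12 mm radial band** rather than the 0–6 mm shell:
at a 3 mm acquisition scale a 0–6 mm ring is barely one pixel wide, so
skeleton length density would saturate at ~1 for every case and branch
points could not rasterize at all; the published magnitudes of skeleton
densities (0.1–0.35) and isoperimetric ratios (≈9–18) are only
attainable on the wider parenchymal map. Amplitude statistics (median,
percentiles, entropy, tail-AUC, pneg) remain shell-based.

The isoperimetric ratio is reported in the complexity convention
P²/(4πA) — 1 for a perfect disc, larger for irregular boundaries — since
the textbook form 4πA/P² is bounded near 1 for pixelated regions and
cannot produce values of 9–18. The perimeter estimator is the exposed
pixel-edge count by default (which carries a known 4/π discretization
bias on smooth shapes); a Crofton estimator is available, and absolute
IPR values should only be compared within one estimator. Convexity is
the region area divided by the area of the convex hull of the
suprathreshold pixel centers (degenerate hulls give NaN).

Skeletons come from Zhang–Suen thinning followed by two repairs: removal
of residual fully occupied 2×2 blocks, and pruning of staircase corner
pixels (degree 2–3, neighbors forming a single 8-connected component,
at most two cardinal neighbors). Without the pruning pass, staircase
corners — which are not one pixel wide in the 8-connected sense —
systematically inflate branch counts. A branch point is a skeleton pixel
where at least three skeleton *segments* converge, detected by a
Rutovitz crossing number ≥ 3; the raw ≥ 3-neighbor rule is exposed as
`branch_rule = "neighbors"` but fires spuriously on pixels in diagonal
contact with a perpendicular arm (on a plus-sign it reports five branch
points instead of one). Skeleton length density is skeleton pixels over
region pixels; branch-point density is branch pixels over skeleton
pixels.

## Robustness machinery

The threshold sweep recomputes the slice topology metrics at
τ ∈ {0.015, 0.02, 0.025, 0.03} and additionally a *conditional*
radial-AUC (`radial_auc_tau`) over suprathreshold voxels only, which is
the variant that actually depends on τ (and increases with it, since
conditioning on I > τ raises the band means). Per-case medians across
the sweep feed the robustness comparisons. A light binary opening
(in-plane disc, 1.5 mm radius, minimum one pixel) before
re-skeletonization probes sensitivity to pixel-scale structure —
expect large relative changes for genuinely fragmented fields, since
opening erases sub-structuring-element filaments by design. Rim–shell
contrasts ΔG′ and Δtanδ (differences of positivity-filtered medians)
and Spearman correlations of topology metrics against size proxies
(shell voxel count, tumor slice area) complete the suite. Group maps can
be rescaled about the patch center to a common effective radius
R\* = 20 mm (R_eff = √(area/π) from the analysis slice); skeleton and
branch maps are *recomputed* from the rescaled occupancy rather than
rescaled themselves, because rescaling breaks one-pixel skeleton width.

## Statistics

Group comparison uses Kruskal–Wallis (tie-corrected H, χ² p on k−1 df)
per metric, all three pairwise two-sided Mann–Whitney U tests (exact
when n₁n₂ ≤ 400 without ties, otherwise normal approximation with tie
correction; U is the first group's statistic, i.e. the count of x > y
pairs plus half ties), Cliff's δ = 1 − 2U/(n₁n₂) with the conventional
magnitude bands (negligible < 0.147, small < 0.33, medium < 0.474,
large above), and the Hodges–Lehmann median of pairwise differences.
Benjamini–Hochberg adjustment is applied jointly across all
metrics × contrasts (m = number of metrics × 3; `bh_fdr()` accepts an
external m so a subset of a family can be adjusted consistently), with
significance at q < 0.05. Pairwise rows are computed for all metrics and
flagged with whether the omnibus test passed p < 0.05, rather than being
suppressed by the gate. The WHO II ordering question is addressed by a
seeded case-resampling bootstrap (within-group resampling, 10,000
iterations): the probability that the WHO II median falls strictly
between the other two group medians in either consistent direction, plus
percentile 95% intervals for the (WHO II − WHO I) and (GBM − WHO II)
median differences.

## The synthetic cohort

Patient elastograms are not redistributable, so the generator emulates
the study conditions: cohort sizes (10, 5, 13), a 64×64×32 grid at
3×3×3 mm (the acquisition scale at desk size), an ellipsoidal brain
(80×80×42 mm semiaxes), and lobulated tumors of 13–19 mm radius with
small in-plane center jitter per case. Baseline parenchymal moduli are
G′ = 2.5 kPa, G″ = 1.0 kPa — conventional brain MRE magnitudes, exposed
as parameters and not claimed as literature values.

Each diagnostic group maps to one archetype of peritumoral elevation of
dissipation, applied multiplicatively to G″ and tanδ (with G′ = G″/tanδ
derived, so elevations change dissipation and phase but not elasticity):

* **compact** (WHO I): isotropic exponential decay
  `rim_amplitude * exp(-d / decay_length_mm)` with amplitude 2.2 and
  decay 4 mm, gentle noise (CV 0.06) and 4 mm smoothing — a smooth,
  radially coherent halo whose thresholded map is a clean annulus;
* **irregular** (WHO II): the compact field restricted to a random
  140° angular sector (raised-cosine taper) plus two tendrils —
  partial interface disruption;
* **branched** (GBM): a shorter-range radial elevation (amplitude 1.3,
  decay 7 mm) under strong mottling noise (CV 0.20, 2.5 mm smoothing),
  plus eight bifurcating tendrils — planar random walks seeded on the
  tumor surface in the analysis plane (3 mm steps, 0.25 rad heading
  jitter, fork probability 0.35 per step into two arms diverging by
  ±0.5–0.9 rad), thickened to 2.5 mm half-width with their own
  amplitude 2.2. Tendrils need an amplitude above the rim reference
  level to register as positive instability over a decaying baseline,
  which is why the tendril amplitude is a separate parameter. The
  resulting thresholded maps are fragmented, holey masses whose
  skeletons form branched meshes.

Noise is multiplicative lognormal, drawn independently on (G″, tanδ)
and smoothed at the archetype's kernel; both moduli therefore carry
lognormal noise, while the two factors of I stay statistically
independent under the null — this is what makes the null phantom's
negative fraction sit at one half. Noise fields are variance-normalized
after smoothing, and a configurable dropout fraction (default 1%) zeroes
one modulus in scattered voxels to exercise the positivity exclusion.
Tumor interiors receive archetype-specific moduli (stiff for the
meningioma-like archetypes, soft and lossy for the GBM-like one).
Everything is deterministic given the per-case seed
(`base_seed + case index`, recorded in the manifest).

What the phantoms do *not* emulate: wave physics and inversion artifacts,
real anatomy (no ventricles, gyri, or skull image), registration error,
and partial-volume structure beyond simple smoothing. Passing tests on
this cohort therefore demonstrate that the pipeline measures what it
claims on fields with known structure — not that any clinical effect
size is reproduced.

## Numerical choices and degenerate inputs

* Distance bins are half-open (lo, hi]; voxel indices are 1-based on the
  R side, with the affine handling the 0-based NIfTI convention.
* The EDT is exact (not chamfer); random-mask tests pin it to a
  brute-force oracle at 1e-9 mm.
* Masks are thresholded at > 0.5 on load, tolerating fractional masks
  from upstream resampling; mask regridding is nearest-neighbor only.
* Empty suprathreshold maps yield NaN morphology with a warning, and the
  case still contributes (as zeros) to group probability maps. Empty
  rims, shells, or all-invalid fields are hard errors naming the case.
* Entropy excludes values outside [0, 0.4] (negatives are not clamped
  into the first bin); voxels at the upper edge fall in the last bin.
* The per-case-threshold metrics table repeats threshold-independent
  quantities across rows so that one tidy CSV (case × τ) carries the
  whole per-case record.
* Rim dilation uses face (6-)connectivity — the thinnest physically
  adjacent layer on anisotropic grids; 26-connectivity is available.
  Parenchyma erosion (1 voxel, applied to the *brain surface* before
  tumor subtraction, for the meningioma groups under the default
  `"by_group"` policy) would empty the rim if applied after the
  subtraction, which is why the order is fixed this way.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full cohort
(10 + 5 + 13 cases) on the default 64×64×32 grid, property checks over
20 seeds on a 32×32×16 half-size grid, oracle comparisons on 8³ masks,
and 10,000 bootstrap iterations — sizes chosen so the whole suite
completes in a few minutes on one core while leaving every statistical
conclusion comfortably powered.

## Known limitations

The topology invariant one might expect from the tendril mechanism —
more tendrils, higher skeleton length *density* — is false in general:
the density is a width ratio, and filaments wider than the background's
fragments dilute it. The total skeleton length is the monotone quantity,
and that is what the generator's invariant test asserts. Branch-point
densities at 3 mm resolution are small integers over small skeletons and
are the noisiest metric in the suite; pin-hole artifacts (dropout voxels
inside an otherwise solid annulus) give even compact cases occasional
nonzero branch counts, mirroring the small nonzero values reported for
benign groups on real data. Finally, all 2D topology is slice-based by
design; no 3D skeletonization is attempted, and multi-frequency
dispersion analysis is out of scope.
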