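---
title: "Methods: label-free embryo profiling with embryoqp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free embryo profiling with embryoqp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`embryoqp`, the parameter choices that matter, the numerical conventions,
and what the synthetic validation can and cannot show. It is the package's
design record; the README shows the user-facing workflow.

## Phase, dry mass, and calibration

Quantitative phase imaging measures the optical path-length delay
φ(**r**) in radians. Dry mass follows from the linear phase–density
relation

$$M = \frac{\lambda}{2\pi\gamma}\iiint_V \varphi(\mathbf{r})\, d^3\mathbf{r},$$

implemented as a masked voxel sum times the voxel volume
(`dry_mass()`). Two calibration constants enter:

* `wavelength_um` (default 0.488 µm, a standard 488 nm laser line);
* `gamma_um3_per_pg` (default 0.2 µm³/pg, i.e. 0.2 ml/g, the canonical
  protein refractive increment). Absolute dry-mass densities scale with
  1/γ, so cross-study comparisons of absolute ρ require knowing γ; all
  *contrasts* (TE vs ICM, class differences) are invariant to it.

Negative dry mass can arise in noise-dominated regions; the value is
returned unchanged and flagged rather than clipped, because clipping would
bias cohort statistics.

### Four-frame reconstruction and gradient integration

The acquisition model is `I_n = A + B cos(g + nπ/2)`, n = 0..3, for the
phase gradient `g` along the shear axis; `reconstruct_gradient()` recovers
`g = atan2(I3 − I1, I0 − I2)` in (−π, π]. Pixels with zero modulation carry
no information and are set to 0 under a flagged mask. Integration to phase
(`integrate_gradient()`) is spectral inverse differentiation per line:
divide the 1-D DFT by `i·2πu` (u in cycles/sample), zero the DC term,
invert, and remove the global mean. Zeroing DC makes the operator
band-limited: the constant component of the gradient (a global ramp in
phase) is deliberately discarded, which is the behaviour we assert in the
tests. The Nyquist bin uses the conventional negative-frequency layout. The
shear axis and a sign flip are configuration options since acquisition
geometry varies between instruments.

## Two-stage 3D instance segmentation

Stage one operates per z-section on the nucleus channel
(`segment_slice()`):

1. median filter (19 px square window at the 11 px/µm reference sampling;
   edge-replicated) and min-max normalization to [0, 1]. The median
   commutes with affine rescaling, so the slice is normalized before
   filtering to satisfy the constant-time median implementation without
   changing the result. A constant slice cannot be normalized and is
   returned empty, flagged.
2. dual thresholding: foreground iff value > 0.2 (hard) **and** value >
   local mean × (1 + (0.5 − sensitivity)) with sensitivity 0.55 over a
   145 px window. The local-threshold formula is this package's explicit
   definition (the reference environment's adaptive routine is
   undocumented); it preserves the qualitative contract that higher
   sensitivity admits more foreground, and sensitivity 0.55 gives the
   slightly permissive factor 0.95. Local means use an integral image with
   replicate padding.
3. opening (3×3 disc, the smallest symmetric element), removal of
   components below 400 px², watershed on the Euclidean distance map to
   separate touching nuclei (EBImage's implementation; the merge
   `tolerance`, default 2 distance-map units, plays the saddle-depth role
   of a minimum peak separation), and removal of objects that are *both*
   below 60 px equivalent diameter and below 0.8 solidity. The conjunction
   reading is deliberate: the filter targets small-and-ragged
   over-segmentation artifacts, and a pure diameter cut would delete
   genuine polar cross-sections of ~5 µm nuclei.

All pixel-domain parameters rescale with the calibration
(`seg2d_params(lateral_px_per_um = ...)`), lengths linearly and areas
quadratically, so the same physical cut-offs apply at any sampling.

One stack-level guard supplements the per-slice contract: because min-max
normalization amplifies background-only sections (above and below the
embryo) into full-range noise, `segment_stack()` marks sections whose
median-filtered dynamic range is below 0.3× the stack maximum as empty.
Stacks whose every section carries signal are unaffected.

Stage two links per-section objects into 3D nuclei:

* greedy nearest-centroid linking within a 50 px radius; candidate pairs
  are assigned in order of increasing distance, each object and trajectory
  at most once, exact ties to the lower trajectory id. Gaps up to 5 µm are
  bridged (the object may vanish from a section and resume); longer gaps
  define a new nuclear boundary. Bridged sections stay background — no
  labels are interpolated — so volumes reflect observed sections only.
* stacked-nucleus splitting (`split_stacked()`). Boundary candidates are
  strict local minima of the slice-area profile that dip below 0.6× the
  smaller neighbouring area maximum, confirmed by a coincident signal in
  the distance-from-first-centroid profile: a weak local extremum within
  ±1 slice (a flat profile, as for coaxially stacked nuclei, qualifies) or
  a step of more than 1 µm across the minimum (the signature of a
  laterally offset stacked nucleus, whose distance profile is
  plateau–plateau rather than extremal). Additionally, a bridged axial gap
  of ≥ 2 empty sections inside one trajectory is treated as a boundary
  outright: the junction caps of stacked nuclei often fall below the 2D
  area filter, producing exactly such a gap, whereas a nucleus interior
  never yields two consecutive empty micrometres. Single-section dropouts
  still bridge. Splitting recurses, so several stacked nuclei separate;
  any split leaving a side shorter than the minimum z-depth is rejected.
  The 0.6 dip factor, the ±1 coincidence window and the 1 µm step are this
  package's choices — the boundary *signals* (area and distance profiles)
  are the established ones, but no thresholds are standard.
* 3D filters in the anisotropic pixel domain, before resampling: voxel
  volume within [5000, 250000] (at the reference calibration), z-depth
  ≥ 3, extent (volume / bounding box) ≥ 0.14. The filters are independent
  predicates, hence order-free. Surviving nuclei are labelled in order of
  first z appearance so that the maximum z-projection doubles as a nucleus
  count map.
* isotropic resampling by the factor `lateral_px_per_um × z_step_um`
  (11 at the reference calibration): labels nearest-neighbour, phase
  linear, output sections at `k/f` in original-slice units so the original
  sections are grid points and `(nz−1)·f + 1` sections result. A
  non-integer factor is rounded and the effective z-step metadata
  adjusted.

## Nucleus features

Volume is the voxel count times the voxel volume. Surface area is the area
of the marching-tetrahedra triangulation (Freudenthal subdivision, which
tiles space consistently) of the zero level of the *signed Euclidean
distance field* of the mask, lightly Gaussian-smoothed (σ = 0.6 voxels).
This estimator was chosen over a direct binary isosurface because faceted
binary surfaces overestimate a digitized sphere's area by ~27% (sphericity
0.79 instead of 1); the signed distance field is piecewise linear across
the boundary, and smoothing it removes discretization scalloping while
leaving flat faces — where the field is exactly linear — unchanged.
Accuracy on digitized spheres of radius ≥ 8 voxels is 1–2% (sphericity
0.98–0.99); a voxel cube measures ≈ 0.85 against the ideal
(π/6)^{1/3} ≈ 0.806 because any smoothed estimator rounds corners — the
"mesh tolerance" asserted in the tests (±0.06). Nuclei are smooth bodies,
so sphere-regime accuracy is what matters downstream. Objects a few voxels
across have their surface underestimated and can exceed sphericity 1;
records with Sp > 1 are excluded (they also arise from under-segmented
clusters in real data) and the count is reported.

Compartments: the embryo centre is the centroid of nucleus centroids, each
nucleus's normalized radius is its centre distance divided by the maximum
over nuclei, and radius > 0.7 ⇒ trophectoderm (TE), ≤ 0.7 ⇒ inner cell
mass (ICM), exactly 0.7 inclusive-inside; a single nucleus has radius 0.
Centroid-of-centroids and max-distance normalization are package
definitions; a fitted sphere would differ slightly for very asymmetric
embryos.

The dry-mass-density map paints each nucleus with its mean ρ, blurs with
σ = (1, 1, 3) voxels (x, y, z), and normalizes by the volume maximum.

## Scattering amplitude spectrum and bw3dB

The embryo is modelled as identical repeating units: a radius-1-voxel
digital ball (centre + 6 face neighbours) at each nucleus centroid on a
cubic lattice (default 256³, matching a 256-point FFT per axis). A single
isotropic scale maps the source volume's largest physical extent onto the
grid, preserving aspect; the frequency axes are `2πu/voxel` rad/µm, which
is the package's explicit convention for the "rescaled" frequency space.
The power |F(**q**)|² of the unnormalized forward DFT is shell-averaged
into 256 radial levels: the first bin holds DC alone, the rest partition
(0, k_max] evenly. `bw3dB` is the smallest k at which the radial average
first falls to half its peak, linearly interpolated between levels; if the
profile never crosses half-peak the maximum k is returned flagged. Because
bw3dB is a ratio statistic it is invariant to the FFT normalization
convention, and the power spectrum is invariant to global translation of
the arrangement. Peak power grows as N² for non-overlapping arrangements
(DC equals the squared field sum); overlapping stamps merge by union and
are logged. Compact arrangements (growth-arrested embryos) produce wider
spectra than dispersed ones of the same N — the package's Monte-Carlo test
verifies the relation on 20 paired arrangements at grid 64, where it is
already decisive.

## Feature-based grading

Per-nucleus input rows are (bw3dB, nucleus count, ρ, S, Sp) — the feature
selection is frozen (it derives from a correlation analysis on real data:
one of each pair with |r| > 0.6 dropped, nucleus count kept despite its
−0.7 correlation with bw3dB), not re-derived from synthetic cohorts. The
network is 5→10→2→2, ReLU hidden, softmax output; training minimizes
cross-entropy + λ‖W‖² (λ = 1e-6, weights only) by full-batch L-BFGS run in
5-iteration segments with the validation loss evaluated between segments.
Early stopping: 20 evaluations without validation improvement, or gradient
norm / training-loss change below 1e-9; the parameters at minimum
validation loss are returned. Features are z-scored with training-split
statistics — the quasi-Newton optimizer is ill-conditioned on raw mixed
scales (bw3dB ~0.06 vs nucleus count ~60) — applied identically at
prediction. Glorot-uniform initialization with zero biases; a fixed seed
reproduces identical weights. The seed is configuration with a fixed
default; no test-set-informed seed selection is performed.

Max-voting: the embryo takes the majority class of its per-item
predictions; the confidence `cp` is the mean score over majority items. An
exact tie resolves to S and is flagged — down-grading is the acceptable
error mode, since the cost of discarding a healthy embryo is lower than
transferring a sick one. The sparse z-subset protocol subsamples per-slice
predictions to a requested spacing and refuses (without `force`) spacings
above 10 µm or fewer than 7 selected slices; 6 slices are specifically
avoided because an even split is inconclusive.

## Similarity metrics

PSNR is `10·log10(range²/MSE)` with an infinity sentinel at equality.
Multi-scale structural similarity uses the standard published exponents
(0.0448, 0.2856, 0.3001, 0.2363, 0.1333) over 5 dyadic scales, an
11-pixel Gaussian window with σ = 1.5, stabilizers C1 = (0.01 L)²,
C2 = (0.03 L)², the luminance term at the coarsest scale only, and
2×2 mean-pool downsampling; images too small for the scale count reduce it
with a warning and renormalized exponents. Negative terms (anti-correlated
structure) are handled by exponentiating magnitudes and tracking signs.
Pearson loss is `(1 − r)²` over pixels (constant images are an error, not
a zero). The combination loss is `2·L1 + 1·(1 − MS-SSIM) + 0.5·(1 − r)²`;
expectations are computed per image and averaged by the caller when
batching.

## Gated statistics

Every feature is gated by per-group Lilliefors tests at 5%: only if all
groups pass is the feature treated as normal. Non-normal branch:
Kruskal–Wallis at α = 0.001 with Dunn's post-hoc (tie-corrected rank
variance) under Holm adjustment. Normal branch: Levene's variance check
(reported), one-way ANOVA and pairwise Welch t tests under Holm. The
TE/ICM density comparison is Kruskal–Wallis at α = 1e-4. Constant or tiny
(< 4) groups are degenerate and routed non-parametrically. The gated
procedure's type-I error is verified on 1000 simulated null features
(mixed normal and exponential, three groups of 30).

## The synthetic generator

`generate_embryo()` renders three phenotypes with exact ground truth:

* **blastocyst (healthy / intermediate)** — 60 / 45 nuclei (cohort draws:
  N(60, 8) clamped to [45, 80], N(45, 8) to [30, 65]) of radius
  2.6–4.2 µm; 55% / 50% placed on an outer shell at 0.80–0.92 of the
  embryo radius (guaranteeing normalized radius > 0.7 for the TE
  invariant), the rest in a core inside 0.55 R; shell nuclei carry mean
  density 0.0625 pg/µm³ against 0.05 in the core (25% contrast, the
  blastocyst signature) with 5% inter-nucleus variability; fragmentation
  probability 0.02 / 0.10.
* **growth-arrested (sick)** — 22 nuclei (N(22, 5) in [12, 32]) of radius
  2.4–3.8 µm placed throughout a compact 20 µm ball, uniform density
  0.07 pg/µm³ (arrested embryos concentrate dry mass), fragmentation
  probability 0.45. Fragmented nuclei render as connected chains of 2–4
  overlapping small spheres inside the nominal radius, producing the
  low-sphericity mode and volume spread of degraded nuclei.

Phase contribution per nucleus voxel is `2πγρ/λ`, so integrating the
noiseless phase over a nucleus recovers its dry mass exactly up to
voxelization (≤ 2% for radius ≥ 4 µm). The cytoplasmic background is a
low super-Gaussian plateau (0.01 rad, order-8 falloff at 1.05 R): nearly
uniform inside the embryo, because a radially peaked background would add
phase preferentially to core nuclei and fabricate a TE/ICM density
contrast that real, roughly uniform intra-embryo backgrounds do not show.
Additive Gaussian noise (default 0.02 rad, putting nucleus SNR near 6) is
applied independently to the phase and nucleus channels; no quantitative
noise model for the instrument is published, so the default is set for
segmentation stress-testing, not noise fidelity. Placement enforces a
2 µm surface separation by rejection sampling with a diagnostic failure
after bounded retries; cohort embryo radii scale with the cube root of the
nucleus count so draws always fit. Identical (config, seed) produces
bit-identical volumes; the generator saves and restores the caller's RNG
state.

What the generator does *not* emulate: optical wave propagation, speckle
or halo artifacts, DIC shear image formation, chromatin texture, or
realistic fluorescence point-spread functions. Passing the synthetic
checks therefore demonstrates the correctness of the computational
pipeline under controlled geometry — not instrument-level performance on
real embryos.

## Validation cohorts and problem sizes

The test-suite and acceptance-script cohorts are sized for a single CPU:

* segmentation recovery: 30 embryos (default class mix, 12–80 nuclei) at
  4 px/µm lateral sampling and 1 µm z-step, with all stage parameters
  rescaled to that calibration; fragmentation is disabled in this cohort
  because a fragment cluster below the physical volume filter is dropped
  *by design* (the same cut-offs remove it from real data), which makes
  "one nucleus, one object" ill-defined for fragmented nuclei. Count
  recovery and matched-centroid error are asserted on intact-nucleus
  geometry; fragmentation behaviour is exercised separately in the
  class-structure and grading tests.
* grading: 80 embryos (defaults incl. fragmentation) at 2.5 px/µm and
  0.4 µm z-step (isotropic after the ×1 resample), features computed from
  the generator's exact instance labels — segmentation quality is
  assessed by its own cohort — with the scattering grid at 128; stratified
  40/10/30 train/validation/test split by embryo.
* scattering Monte-Carlo at grid 64; single-model identities at 128; the
  256 default is kept for production use.
* statistics calibration: 1000 null features, three groups of 30.

## Known limitations

* Absolute dry-mass densities include whatever background phase lies
  inside the nucleus mask (as they do in real measurements); ground-truth
  density recovery is therefore validated on cytoplasm-free
  configurations, and absolute ρ comparisons across instruments require a
  known γ.
* The surface estimator's corner rounding (cube case above) biases
  sphericity upward for genuinely polyhedral bodies; irrelevant for
  nuclei, relevant if the package is reused for crystalline objects.
* The grading model is trained and evaluated on synthetic cohorts whose
  class separations are configured; the reported accuracies certify the
  pipeline and the voting machinery, not clinical performance.
* TIFF output uses 32-bit integer samples with an affine-transform JSON
  sidecar (the TIFF writer available here does not emit float samples);
  round-trip quantization is ~1e-9 of the dynamic range.
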