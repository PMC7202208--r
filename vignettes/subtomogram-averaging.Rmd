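---
title: "Subtomogram averaging of membrane-embedded particles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtomogram averaging of membrane-embedded particles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomosta)
```

tomosta is a desk-scale implementation of the subtomogram-averaging (StA)
workflow used to solve structures of large membrane proteins *in situ* by
cryo-electron tomography — the motivating case being a ~2.2 MDa C4-symmetric
calcium-release channel sitting in a curved native sarcoplasmic-reticulum
membrane. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices the implementation makes.

## The imaging model

A single-axis tilt series samples Fourier space on a fan of central planes.
With a tilt range of ±60°, a wedge of directions — one third of all Fourier
lines — is never measured: the *missing wedge*. tomosta models this
directly in Fourier space with `wedge_mask()` (tilt axis along y, beam
along z): a voxel is retained when the line angle of its (kx, kz)
projection lies inside the collected range. A hard ±60° mask retains
exactly 2/3 of the Fourier voxels inside the Nyquist sphere; the fraction
is counted there because the angle distribution over the full Fourier cube
is biased by the corners. Masks get a Gaussian soft edge (default 1 Fourier
voxel) and are Hermitian-symmetric by construction, including on the
Nyquist planes of the even-sized grid where the conjugate voxel wraps onto
the same plane.

Radiation damage is modelled as the standard frequency-dependent exposure
decay: each tilt's amplitudes are attenuated by
`exp(-cumulative_dose / (2 Nc(f)))` with the empirical critical-exposure
curve `Nc(f) = 0.245 f^-1.665 + 2.81` (f in 1/Å, dose in e⁻/Å²). Because a
subtomogram mixes all tilts, the per-tilt attenuations are aggregated —
weighted by per-tilt dose over the dose-symmetric acquisition order — into
a single radial profile (`dose_filter()`). The default `tilt_scheme()` is
41 tilts from −60° to +60° in 3° steps at 1.1 e⁻/Å² per tilt with an 18
e⁻/Å² untilted image (total 62 e⁻/Å²), acquired dose-symmetrically so the
untilted, most information-rich image receives the least prior exposure.

## The phantom and what it does (not) emulate

`phantom_spec()` describes an analytic, exactly C4-symmetric "mushroom":
a square cytoplasmic slab (220 Å wide, 60 Å tall) carried ~45 Å above the
bilayer by a cylindrical transmembrane stem, plus four ~40 Å lumenal
extension rods — the geometry of a ryanodine-receptor-like channel at the
package's working resolutions. The membrane is a spherical-shell cap
(default radius 50 nm, thickness 40 Å) whose sphere centre sits on the
symmetry axis on the lumenal side, or a flat sheet
(`membrane_R = "flat"`). Defaults use a 64³ box at 5.4 Å/voxel, the
2×-binned equivalent of the 200³ / 2.7 Å acquisition geometry; the test
suite also uses 48³ at 7.2 Å and 32³ at 10.8 Å, which keep the same
345.6 Å physical box.

`render_particle()` is the forward model: rotate/shift the ground truth
(intrinsic Z–X–Z Euler angles, degrees; shifts in Å), apply the aggregate
exposure filter, apply the wedge, then add white Gaussian noise scaled so
that signal power / noise power equals the requested SNR.
`simulate_ensemble()` adds population structure: class labels drawn from
stated occupancies, per-class geometric deformations (peripheral-domain
radial scale, vertical stretch, membrane-radius jitter), membrane-bound
poses (uniform in-plane rotation, tilt from the membrane normal folded
from a centred normal with 10° default spread), Gaussian shifts (6 Å
default), and a random, persistent half-set assignment.

What the phantom does *not* emulate: contrast transfer (no CTF model — out
of scope), colored noise, neighbouring particles and gold fiducials,
per-particle tilt-scheme variation, and conformational variability beyond
the parametric deformations. Passing tests therefore demonstrate that the
algorithms recover planted structure under an idealized but
geometrically-faithful forward model, not that they are robust to every
artefact of real tomograms.

## Constrained alignment

`constrained_cc()` computes normalized cross-correlation only over Fourier
voxels inside both the particle's wedge and the resolution band, which
removes the systematic score deficit a missing wedge causes against a
fully sampled reference.

`align_particles()` searches a global rotation grid — a cone of directions
(default half-angle 16°, step 8°) crossed with in-plane angles (step 8°
over [0°, 90°) when C4 symmetry is on, since poses differing by 90°
in-plane are equivalent; reported in-plane angles fall in that canonical
sector). The reference is rotated; the particle keeps its wedge. Scoring
works on the band-limited Fourier subset (a 36 Å band on a 64³ box is
~4,000 coefficients), and the translation search uses the Fourier
cross-correlation theorem on a small cube just large enough to hold the
band, so the full grid is scored exhaustively in milliseconds per particle.
The winning rotation gets a full-resolution translation pass with
quadratic sub-voxel peak interpolation; peaks on the shift-limit boundary
are flagged in the record. We chose this exhaustive subset-based search
over a hierarchical coarse/fine scheme because at desk scale it is both
faster and free of coarse-stage commitment errors.

The band limit matters: alignment at 36 Å uses only reliable
low-frequency signal and avoids overfitting noise; 22 Å is used for
conformational classification where finer detail carries the signal.

## Weighted averaging and wedge compensation

`weighted_average()` rotates each particle into the reference frame
(`backtransform()`), re-masks it with its rotated wedge, and accumulates

- numerator: Σᵢ wᵢ mᵢ(Rk) Fᵢ(k), and
- weights: Σᵢ wᵢ mᵢ(Rk) D(k),

where wᵢ = max(ccᵢ, 0) (a particle scoring non-positively is junk by
construction and contributes nothing), mᵢ is the rotated wedge mask and D
the exposure filter. The re-masking is essential: trilinear resampling
leaks a little energy outside a particle's sampled region, and without
matching numerator support to the accumulated weights that leakage would
be amplified by orders of magnitude in barely-sampled voxels. The division
itself is Wiener-style, `num·den / (den² + ε²)` with ε = 10⁻³ × max(den):
identical to num/den where coverage is substantial, decaying to zero in
never-sampled voxels instead of amplifying noise. C4 symmetrization (an
exact index permutation, so idempotent to machine precision) and the
configured band limit are applied to the result.

## Half-set refinement and resolution

`halfset_refine()` implements the size-dependent protocol: datasets of
more than 500 particles are split (seeded, persistent, never swapped) and
each half is aligned and averaged against its own evolving reference with
no cross-talk; the Fourier shell correlation between the final half-maps
is read at a threshold (default 0.143, the independent-half-set
convention; 0.5 is available — no threshold is asserted as canonical) with
linear interpolation between 1-voxel shells. The alignment band limit does
not band-limit the half-maps themselves, so the FSC can measure agreement
beyond it. Datasets of 500 or fewer particles fall back to
single-reference refinement with a hard 36 Å band limit on the
reconstruction, and the reported "resolution" is that band limit — a
deliberate understatement, since no independent half-map estimate exists
there. Refinement starts from a user-supplied initial reference (in the
original workflow this role is played by a manually built starting
average).

## Multireference classification

`multireference_classify()` alternates assignment-by-best-constrained-cc
with per-class weighted averaging at the classification band limit (22 Å
default) under C4, with poses held fixed. References are seeded by random
phase jitter of the global average (seeded, hence deterministic).
Because alternating optimization of this objective (mean best-class
correlation) has local optima where two planted classes collapse onto one
reference, the implementation runs `n_start = 5` seeded restarts and one
split-and-merge refinement per restart — merge the most-similar reference
pair, split the largest class along its own internal structure via a local
two-class run, keep the result only if the objective improves. A class
emptying mid-run is reseeded once from the worst-scoring members of the
largest class, then allowed to die. Convergence is < 1% assignment changes
or 10 iterations. `prune_classes()` removes classes strictly below a
1% occupancy default or on a manual exclusion list (the gold-bead case),
and `occupancy_table()` reports counts and fractions.

## Eigenvolume PCA

`align_class_averages()` aligns the (fully sampled — no wedge needed)
class averages to their common average by translation plus a small
in-plane rotation search against leave-one-out means, with sub-voxel peak
interpolation; leave-one-out matters because a volume correlated against a
mean containing itself is biased toward its current pose.
`eigenvolume_decompose()` performs voxel-wise PCA on the Gram
(class-count-sized) matrix — 36 classes versus ~10⁵ voxels makes the
covariance route pointless. The first raw principal component tracks
overall density amplitude and is dropped by convention; modes are
renumbered from the second raw component, and a diagnostic stores the
dropped component's correlation with per-class total intensity so its
triviality can be verified rather than assumed. *Informativity* is the
variance along a mode divided by the variance of mode 1 — by construction
1 for mode 1 and non-increasing. Classes are not weighted by occupancy in
the PCA or in the half-map averages (an occupancy-weighted variant would
change the question being asked — variance over conformations versus over
particles; the unweighted form matches the class-average-level analysis).
`mode_halfmaps()` sorts classes by eigencoefficient and averages the lower
and upper halves (odd counts drop the median volume to keep the groups
equal). `mode_spatial_correlation()` tests whether conformation clusters
in space: Moran's I of eigencoefficients over a k-nearest-neighbour graph
of tomogram positions with a seeded permutation null.

## Membrane curvature

`fit_membrane_radius()` measures the local curvature of the membrane in an
average map by the flatness-optimization construction:
`spherical_resample()` samples the map on spheres of candidate radius R
centred on the C4 axis at distance R below the membrane midplane (the
osculating sphere's centre must lie on the symmetry axis of a
C4-symmetric average), and a membrane lying on the candidate sphere maps
to a constant-radius sheet. The flatness functional — the choice is ours,
as the construction only names the goal — is the variance across angular
columns of each column's density-weighted radial centroid (in voxels²),
with three guards: a membrane-height band (default ±60 Å around the
nominal membrane z) so the receptor body cannot masquerade as membrane, a
central exclusion radius (default 100 Å, the stem footprint), and a
contrast-based detectability test that raises an error when more than half
the columns show no membrane. The radius grid (default 20–200 nm in 10 nm
steps) is refined around its best point by golden-section search to 1 nm,
and a flat (infinite-radius) sentinel — the same functional in Cartesian
columns — competes with the spherical fits; curvature is reported as 1/R,
or 0 when flat wins. `classify_membrane_patches()` runs the fit with the
sphere centre on either side of the membrane and reports signed curvature
(positive = concave toward the cytoplasm) and concave/near-flat/convex
fractions, near-flat meaning |R| > 150 nm.

On noise-free phantoms the fit recovers planted radii of 35–100 nm to
within a few percent; at SNR 1 (after 36 Å low-pass, emulating an average
map) recovery stays within 10%.

One limitation deserves emphasis. A near-horizontal membrane has almost
all of its Fourier content within ~20° of the kz axis — inside the
missing wedge. Wedge compensation in the average can only restore
directions some particle actually sampled, and membrane-bound particles
with a narrow tilt-from-normal spread leave a residual missing *cone*
around kz that genuinely reshapes the reconstructed membrane: on
desk-scale averages simulated with a 10° tilt spread the apparent radius
biases low by tens of percent, an artefact of the map, not of the
estimator (the same fit on the unfiltered phantom is accurate to a few
percent). Curvature should therefore be read from maps whose membrane
signal is not cone-limited — final compensated averages from data with a
wide orientation spread, or deposited-quality maps — and that is how the
package's own validation uses it.

## Numerical choices

- **Grid and conventions.** Cubic, even boxes; rotation centre at 0-based
  voxel N/2; coordinates in Å from that centre; 0-based voxel positions
  with x the fastest axis in tables; intrinsic Z–X–Z Euler angles in
  degrees; `out(y) = vol(R⁻¹(y − shift))` for `rotate_shift()`.
- **Interpolation.** Trilinear everywhere, adequate at the 36/22 Å targets
  and cheap; out-of-grid samples fill with the volume mean to avoid
  spurious low-frequency edges. 90° rotations and the z-mirror are exact
  index permutations.
- **Band edges.** `bandpass()` uses a raised-cosine edge lying entirely
  inside the band, so power outside the stated cutoff is exactly zero and
  total power never increases; `high_res = 2·voxel_size` (Nyquist) is a
  vacuous cut.
- **Wedge boundary.** The retained interval is half-open at the lower tilt
  boundary so boundary lattice lines (e.g. the ±45° diagonals) are counted
  once.
- **FSC.** 1-Fourier-voxel shells centred on integer radii; all-zero
  shells report 0; a curve starting below threshold reports `Inf` with a
  warning ("worse than the lowest measured shell"); a curve never crossing
  reports Nyquist.
- **Degenerate inputs.** Identical volumes into the PCA yield an empty
  mode list with a warning; constant coefficient vectors make Moran's I
  return a degenerate flag; a constant map raises a membrane-detection
  error.
- **Determinism.** Every stochastic step takes a seed; `run_pipeline()`
  derives named per-stage substreams from one global seed, and reruns with
  equal configuration reproduce the particle tables bit-identically.

## Problem sizes

The package's standard experiment scales, used throughout the tests and
the acceptance script, are chosen so each stage answers its scientific
question in minutes on one CPU: alignment recovery with 100 particles at
box 64 (SNR 10); averaging gain and the half-set branch rule with up to
600 particles at box 48 (SNR 0.5); classification with 200–400 particles
at box 32 (SNR 0.5); PCA with 12–36 class-average-sized volumes; curvature
on box-64 maps. SNR 0.5 is a realistic per-subtomogram regime for a
particle of this size; SNR 10 isolates the geometry of the angular search
from the noise question.

## Known limitations

No CTF; white noise only; classification assumes fixed poses (no
per-class realignment); per-particle (as opposed to per-class)
eigencoefficients are not estimated; curvature assumes the membrane
crosses the box roughly horizontally near the stated membrane height; the
small-dataset branch reports a band limit, not a measured resolution, by
design.
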