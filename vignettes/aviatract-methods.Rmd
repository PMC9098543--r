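---
title: "Methods: diffusion models, tractography and two-level fiber clustering in aviatract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion models, tractography and two-level fiber clustering in aviatract}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind each pipeline stage, the
parameters that matter, the numerical choices, and the places where the
design was genuinely open and a decision had to be made. It states no
empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The synthetic phantom: what it emulates, and what it does not

The phantom stands in for an ex vivo single-shell HARDI acquisition of a
small avian brain: 75 diffusion directions plus 5 *b* = 0 volumes at
*b* = 4500 s/mm² on a 0.2 mm isotropic grid. Signals follow the standard
multi-tensor model

S(g, b) = S0 · Σᵢ fᵢ · exp(−b gᵀDᵢg),

with three tissue compartments. The mean diffusivities are GM 3.0·10⁻⁴,
WM 2.3·10⁻⁴ and CSF 6.5·10⁻⁴ mm²/s. These mantissas reproduce the three
observed tissue modes of fixed tissue at ultra-high field, placed on the
10⁻⁴ mm²/s scale: on that scale b·D spans 1.0–2.9 and the shell carries
real contrast, whereas a 10⁻⁹ mm²/s reading would make the acquisition
contrast-free, which is physically untenable for an attenuation-based
protocol. White matter uses an axially symmetric tensor with a 5:1
eigenvalue ratio at fixed trace 3·ADC (FA ≈ 0.77), which produces the
sharp single-lobe ODFs the tracking stage assumes; voxels claimed by two
tubes mix one tensor per direction at equal volume fractions. Rician
noise is the magnitude of the complex-noised signal, |S + n₁ + i·n₂|
with n₁, n₂ ~ N(0, S0/SNR), and SNR is defined at *b* = 0. Outside the
brain mask the noiseless signal is zero, so the noised background is
Rayleigh — exactly the background the noise estimator expects.

What the phantom does **not** emulate: EPI distortion and eddy currents
(the targeted multishot ex vivo protocol shows almost none, so the
pipeline deliberately has no correction stage), partial-volume mixtures
at tissue interfaces other than tube crossings, anatomically realistic
geometry, and spatially varying S0 or T2. Tests passing on the phantom
therefore validate the *algorithms* under their stated assumptions, not
performance on real scans.

Geometry conventions: mm coordinates throughout, voxel (i,j,k) (1-based)
owns the half-open box [(i−1)·vs, i·vs) per axis and is centered at
(i−0.5)·vs; the voxel-to-mm affine is diagonal. The brain mask excludes a
one-voxel border so that tracking has a boundary to stop at and the
background exists for noise estimation.

## Gradient scheme

Directions minimize the electrostatic energy Σ 1/|xᵢ−xⱼ| + 1/|xᵢ+xⱼ|
(antipodal pairs identified), by BFGS over unconstrained coordinates
normalized inside the objective, from a seeded jittered hemispheric
Fibonacci start. The hemispheric start matters: a full-sphere start can
place two points on one axis, an unstable equilibrium that descent
escapes slowly. Typical 75-direction sets reach a ≈16° minimum pairwise
axis angle.

## Denoising

Non-local means with a Rician second-moment correction, per 3-D volume
(the simplest defensible reading of "applied to the raw data"; no 4-D
joint patches). Weights are exp(−msd/h²) with msd the mean squared patch
difference over the valid patch overlap. Defaults patch radius 1, search
radius 3 and h = 1.5·σ̂ are standard NLM practice; the filter's source
publication gives no parameter values, so all three are exposed. σ̂ comes
from the MAD of background *b* = 0 intensities, with a fallback to the
spread of the repeated *b* = 0 volumes when the mask covers the grid.
With σ = 0 the filter is a convex combination and hence non-expansive on
the intensity range; with σ > 0 the bias correction may push values
below the input minimum, which is intended.

## Local models

**DTI** is the log-linear least-squares fit of ln S = ln S0 − b gᵀDg over
all volumes, with signals clamped at 10⁻⁶·max(S) before the log. The
design matrix is validated for rank 7 at construction. Eigenvalue maps:
ADC = mean λ, AD = λ₁, RD = (λ₂+λ₃)/2, FA = √(3/2)·‖λ−λ̄‖/‖λ‖; negative
eigenvalues are clamped to zero and counted.

**Analytical Q-ball**: the signal normalized by the mean of the five
*b* = 0 volumes is fit on the real symmetric ("modified") spherical
harmonic basis restricted to even degrees, order 8 (45 coefficients),
with Laplace–Beltrami regularization λ = 0.006 — the L-curve optimum for
this protocol class. The Funk–Radon transform is analytic in this basis:
ODF coefficients are the signal coefficients scaled by 2π·P_l(0). Basis
ordering is (l ascending; m from −l to l, cosine terms on negative m);
the basis is orthonormal, so any consistent ordering is internally
equivalent, but the convention is recorded in the field's `basis` tag.

**GFA** is std/rms of the ODF sampled on a dense antipodally symmetric
tessellation (724 points = 362 axes, built from a symmetrized Fibonacci
spiral; no icosahedral subdivision yields exactly 724 vertices and only
the density matters). ODF samples are min-shifted to ≥ 0 first, because
the truncated Funk–Radon transform can produce small negative lobes.

**Peak extraction** uses non-maximum suppression on the tessellation
(25° neighborhood, relative threshold 0.25 of the global maximum),
followed by a shrinking tangent-plane ascent on the continuous SH
expansion. The refinement matters: the tessellation alone quantizes
directions at up to ≈4–5°, the refined peak of a noiseless single-fiber
voxel is within a fraction of a degree.

## Tractography

Streamline-regularized deterministic tracking. From each seed (8 per
mask voxel by default, uniform within the voxel), integration runs
forward and backward at 50 µm steps; the first step follows the global
ODF maximum at the seed. At each subsequent step the candidate direction
is the ODF peak — from trilinearly interpolated SH coefficients, for
continuity of the field — closest to the previous direction within a 30°
aperture, and the update blends it with inertia:

d = normalize((1−w)·d_odf + w·d_prev),  w = clamp(1 − GFA/θ, 0, 1).

The blending law is this package's concrete definition of the
"anisotropy-based regularization": the source method is cited in the
literature without a printed formula, and this form makes the published
regularization factor θ = 0.12 — the population 98 % cumulative-GFA
threshold — the exact anisotropy level at which regularization vanishes.
In white matter (GFA well above θ) tracking follows the ODF; in
near-isotropic tissue it propagates straight, reproducing the published
behavior of tracking without an anisotropy stopping criterion.
Termination: mask exit, no in-cone peak, or the 100 mm length cap; only
lengths in [0.1, 100] mm are kept. Aperture applies to peak *selection*,
not to the blended update — the regularized step may bend less, never
more. Ties between equidistant peaks break by larger ODF value, then
lexicographically smaller direction. The tracker is compiled (C++), as
is usual for this workload.

## Intra-subject clustering (Step 1)

Fibers are split by region — majority label among LH/RH/CBL, with any
fiber touching both hemispheres classed interhemispheric — and then into
**eight** equal-width length ranges inside the population 2–98 % length
window. Eight follows the parameter table of the source protocol; a
figure caption elsewhere mentions ten ranges, and the table value was
adopted as the unambiguous one. Equal-width (not equal-count) bins are
used; the protocol does not say which, and equal width keeps bin
boundaries interpretable in mm.

Per (region, range) group: a density mask keeps voxels crossed by ≥ 5
distinct fibers; k-means on voxel centers cuts the mask into parcels of
27 voxels on average (k = round(n/27), labels made a nearest-center
fixed point); the parcel connectivity matrix counts fibers visiting both
parcels of a pair; average-linkage clustering of D = 1 − M/max(M) is cut
at height 0.9 (the protocol names hierarchical clustering but no cut
rule; 0.9 merges everything but near-disconnected parcel groups and is
exposed in the configuration). A fiber joins the cluster holding the
largest fraction of its trajectory if that fraction is ≥ 31 %, with the
fiber discretized at its own points — the tracking step is already
uniform, so resampling would change nothing but runtime. Clusters under
5 members are dropped. Each cluster is represented by its **centroid**:
the member fiber minimizing the mean symmetric mean-closest-point (MCP)
distance to the others, ties to the lower index.

A protocol table also lists "average/minimum cluster size" of 6000/300
voxels; these are interpreted as optional caps on the density-mask size
per clustering unit and are off by default, since the running text is
unambiguous that parcels have 27 voxels.

## Inter-subject clustering (Step 2)

Centroids from all subjects — already in a common space; registration is
out of scope and synthetic cohorts share one space — are resampled to 21
equidistant points. The pairwise distance is the smaller over both point
orderings of the mean point-to-point distance, corrected as

d = max(0.01 mm, d_raw · nf/(nf + min(lenₐ, len_b))),

with nf = 4.0 mm. The correction's closed form is again this package's
definition (the cited normalization is not printed in the protocol): it
satisfies the stated behavior — the constraint relaxes as the shorter
centroid grows — and halves the raw distance exactly when the minimum
length equals nf. Affinities are exp(−d²/1600 mm²), zeroed beyond
CAMD = 2.0 mm. HDBSCAN runs on the corrected distances (zero-affinity
pairs at a far sentinel), with min cluster size = max(2, ⌈0.5·n⌉) so a
cluster must already draw on half the cohort; a post-pass removes
members farther than 0.4 mm from their cluster medoid — the protocol
lists a "maximum distance after exclusion" without defining the
operation, and medoid pruning is the implementation here, disableable.
Finally the ≥ 50 % cohort-presence filter keeps population bundles.

HDBSCAN itself (mutual reachability, MST, condensed tree, excess-of-mass
selection with the root excluded) is implemented in the package because
no R implementation is available in the supported environment; it is
pinned against the scikit-learn reference implementation in the test
suite, including the convention that `min_samples` counts the point
itself.

The (nf, CAMD) optimization scans a 10×10 grid over [1, 100] mm ×
[0.1, 4.0] mm, re-clustering at each point, and returns the argmax of
the produced-cluster count (counted after the exclusion pass, before the
presence filter) together with the full surface; the protocol reports
only that the count landscape determined the optimum.

## Atlas and group comparison (Step 3)

A bundle's ROI constraint selects inter-subject clusters whose centroid
passes through every include region (≥ 1 point each — pass-through
selection, no fraction threshold, matching the described semi-automatic
procedure) and avoids all exclude regions. Group comparison uses
Welch's unequal-variance t-test per region on fiber densities (fibers
per in-mask region voxel); the protocol says only "T tests", and Welch
is the safer default when line variances may differ.

## Numerical and reproducibility choices

- Percentiles (GFA 98 %, length 2/98 %) interpolate the empirical CDF at
  rank 1 + (n−1)p — R's default quantile convention, implemented
  explicitly and oracle-tested.
- Every stochastic stage draws from a stream derived from one root seed
  and a stage name; the full pipeline is bit-reproducible.
- Average-linkage merge heights are made monotone with `cummax` before
  cutting (floating-point ties can invert them by ~1e−16).
- TRK files carry the diagonal voxel-to-mm affine and mm coordinates
  (float32); TCK is always mm; NIfTI I/O goes through RNifti.

## Problem sizes in tests and the acceptance run

Desk-scale conditions were chosen once: phantoms on 32³ grids (tests)
and a 6-subject cohort on a 24³ grid at SNR 30 with 2 seeds per voxel
(acceptance script); planted-recovery fixtures use 50–60 fibers per
bundle, inter-subject cohorts 6 subjects with 0.2 mm centroid jitter.
These sizes keep every property measurable (hundreds of bundle voxels,
thousands of streamlines) while a full run stays in the minutes range on
one CPU. Acquisition-side defaults (75+5 volumes, b = 4500, 0.2 mm,
order 8, λ = 0.006, the tracking and clustering tables) are the study
conditions themselves and are never scaled.

## Known limitations

- The phantom's piecewise-pure tissue model understates partial-volume
  effects; tracking fidelity at tube surfaces is accordingly optimistic.
- Region labels in synthetic runs are geometric half-spaces, not
  anatomy; ROI constraints in `run_pipeline` derive from the planted
  tubes.
- Registration to a template is out of scope; inter-subject clustering
  assumes centroids are already co-registered (identity in synthetic
  settings, or a user-supplied affine).
- Only deterministic tracking is provided; probabilistic and global
  variants are explicitly out of scope.
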