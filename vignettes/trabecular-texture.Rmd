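---
title: "Methods: volumetric local binary patterns and bone morphometry in trabtex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumetric local binary patterns and bone morphometry in trabtex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabtex)
```

## Scope and data model

`trabtex` quantifies local texture and conventional structure in gray-level
micro-CT volumes of bone. A volume is a 3D scalar array with an isotropic
voxel size in micrometres; by convention the **third array axis is the
distal–proximal axis**, and every orientation statistic is defined against
it. This convention matters: elevation is reported in [0°, 90°] with 90° =
longitudinal (aligned with the third axis) and 0° = transverse. Flipping the
sign of any axis does not change elevation (the principal axis is sign-free
and azimuth is ignored), but permuting the third axis with another one does —
the CLI offers an axis-permutation flag for data exported in other layouts.

## The volumetric LBP operator

For a voxel `c`, 26 sampling points are placed at `c + r·u_i`, where the
`u_i` are the normalized offsets of the 3×3×3 neighborhood in a fixed
lexicographic order and `r` is the sphere radius in voxels. Samples are
trilinear; a neighbor is a *marker* when its sampled value is ≥ the centre
value, and the 26 marker bits form the pattern code. Voxels closer than
`ceiling(r)` to a volume face are never evaluated (no extrapolation), and a
voxel is *eligible* only if at least one sampled neighbor exceeds a fixed
intensity threshold, which confines the statistics to bone rather than
marrow space.

Numerical choices:

* **Tie tolerance.** Trilinear weights only sum to 1 up to floating
  rounding, so the marker comparison uses a relative slack of 1e-9. Without
  it a constant volume would not reliably produce the all-marker code; with
  it, codes on continuous-valued data are unaffected (a sample would need to
  sit within 1e-9 of the centre value to flip).
* **Gray-scale invariance.** Codes depend only on value *order*, so any
  increasing affine map of intensities leaves them unchanged provided the
  eligibility threshold is mapped along. This is asserted as a property test.
* **Operating on grayscale.** The operator is applied to the gray-level
  volume, not the binarized one: interpolation presumes continuous values.
  Binary input is accepted but gives degenerate, mostly-invalid patterns.

Pattern-level outputs are the Shannon entropy of the code distribution
(`E = −Σ P_i log2 P_i`, in bits; 0 for a single-pattern volume such as a
monotone ramp), the number of distinct codes, and the count-weighted mean
number of markers. Histograms are stored sparsely — the code space has 2^26
cells but real volumes occupy a few hundred.

### Choice of sampling radius

The default radius is **1.0 voxel**, the smallest sphere whose samples are
interpolated from the immediately surrounding voxels; it is the natural
scale for pattern entropy and marker counts. For *orientation* work a radius
of **1.5 voxels** is preferable and is what the validation suite and the
acceptance script use: with only 26 fixed directions, the achievable
principal axes of small marker sets cluster near a few symmetry angles
(45°, 54.7°, 65.9°, ...), and at radius 1.0 this quantization biases the
mean elevation of obliquely oriented structures by up to ~6° (a 60° rod
lattice reads ~54°). Sampling at 1.5 voxels diversifies the marker
configurations enough to bring all tested orientations (0°, 30°, 60°, 90°)
within one 5° bin. The radius remains a first-class parameter everywhere.

## Orientation statistics

A pattern's direction is the first principal axis of its marker positions on
the sampling sphere (eigen-decomposition of their 3×3 covariance after
centring on the marker centroid); elevation is `asin(|axis·ẑ|)` in degrees.
Patterns without a consistent orientation are excluded:

* fewer than 3 markers (`min_markers`, default 3) — no axis is defined;
* more than 24 markers (`max_markers`, default 24) — the pattern is nearly
  isotropic;
* **centroid rule** (default on): the mean distance of markers to their own
  centroid exceeds the mean distance of the non-markers to that centroid.
  This operationalizes "markers located farther from the centroid than
  non-markers" and discards dispersed, ring-like marker sets. The reading is
  one of several defensible ones; it is exposed as a switch so the rule can
  be disabled or retuned.
* **degenerate axes**: when the two leading eigenvalues agree within a
  relative 1e-9 there is no unique principal axis and the voxel is marked
  invalid. This catches planar/symmetric marker sets that would otherwise
  return an arbitrary eigenvector.

Elevation is computed once per distinct code and looked up, so the per-voxel
field costs one code evaluation plus a table lookup.

The **ALCM** accumulates, over every ordered pair of 26-adjacent valid
voxels, the pair of binned elevations; counting both orders makes it
symmetric, and it is normalized to total 1. Bins are 5° wide (18 bins over
[0°, 90°]) by default. Neither the bin width, the adjacency ("one
voxel-size radius" — taken as the 26-neighborhood, with a 6-adjacency
option), nor the normalization is uniquely determined by the method's
published description; all three are parameters, and the defaults are the
package's documented assumptions. Homogeneity `H = Σ ALCM(i,j)/(1+|i−j|)`
is 1 exactly when all co-occurring pairs share a bin and decreases
monotonically as mass moves off-diagonal.

## Binarization

Two stages: voxels below a fixed pre-threshold (default 60 on the 8-bit
scale, rescaled proportionally for 16-bit data unless given explicitly) are
background; surviving voxels are foreground iff their value reaches the
local midrange `(min+max)/2` over a window centred on them. Defaults: ball
window ("radius" suggests spherical) of radius 5 voxels, with an 11³ cube
option; windows are clipped at the volume boundary; ties count as
foreground, which keeps constant regions solid and makes the output
invariant to co-shifting intensities and threshold. The window is applied in
3D by default with a slice-wise 2D option, since the original vendor
implementation's dimensionality is not documented.

## Morphometry

* **BV/TV** — foreground fraction within the ROI.
* **BS/BV** — triangulated isosurface area over foreground volume. The
  surface is extracted at the 0.5 iso-level by marching tetrahedra (each
  cell split into 6 tetrahedra around its main diagonal, crossings linearly
  interpolated along edges). Raw binary fields pin every crossing to edge
  midpoints and overestimate curved surfaces by ~25–30%, so the binary mask
  is first smoothed with a σ = 1 voxel Gaussian; on a radius-10-voxel ball
  this lands within ~2% of the analytic 3/r. No boundary padding is added:
  phases cut by the volume faces stay open there, so a slab spanning the
  volume contributes only its two faces.
* **Tb.Th / Tb.Sp** — local thickness by maximal inscribed spheres
  (distance-transform radii, spheres painted in decreasing order), run on
  the foreground or background phase; the 2D section mode uses discs.
  Conventions worth knowing: radii are centre-to-centre distances to the
  nearest background voxel, so an even-height slab is exact while an
  odd-height slab reads one voxel thick(er) — a parity artifact shared by
  distance-transform implementations; the phase is treated as continuing
  beyond the volume faces, so structures cut by the boundary are not
  artificially thinned; and the reported mean is **volume-weighted**
  (every phase voxel contributes), so a tapering plate averages
  `Σh²/Σh`, not the footprint mean of `h`.
* **Tb.N** — `BV/TV ÷ Tb.Th`, the model-independent plate formula; vendor
  packages may use other structural models, so values are comparable rather
  than identical.
* **Fractal dimension** — box counting over dyadic box sizes (1, 2, 4, ...)
  spanning at least three octaves, least-squares slope of log count against
  log(1/size). Volumes must allow ≥ 4 dyadic sizes (minimum dimension 8).
* **Plate thickness** — mean local thickness of bone restricted to the
  plate ROI. Plate and trabecular compartments are supplied as two masks;
  no automatic plate segmentation is attempted.

Structure model index, connectivity (density), trabecular pattern factor and
degree of anisotropy are deliberately not implemented; the pipeline report
reserves their field names so externally computed values can be merged.

## Statistics

Multiple samples from one donor are pseudoreplicates. The correlation
routine weights each sample by the reciprocal of its donor's sample count,
computes the weighted Pearson r against the severity grade, and takes the
two-sided p-value from a t statistic with `n_donors − 2` degrees of freedom
— the donor count, not the sample count, carries the information. The exact
mechanics of "equal donor weighting" admit two readings; the package
implements the weighted-sample form (which preserves within-donor spread) as
the default and donor-mean aggregation behind `method = "donor_mean"`. The
defining contract — duplicating a donor's samples leaves r unchanged — is a
property test. CV% is `100·sd/mean` over repeated measurements.

## The phantom module

Phantoms are the package's ground-truth harness, rasterized by distance
thresholding in continuous space so analytic volume fractions hold to
discretization error:

* `rod_lattice` — parallel cylinders on a square lattice perpendicular to
  the rod axis, axis elevation free in [0°, 90°]; `bv_tv = πr²/s²`. The
  perpendicular lattice is rotated by 0.48 rad so rod centres are
  incommensurate with the voxel grid — sub-voxel phases then average out
  and voxel counts track the analytic area to well under 1%, instead of the
  ~3% lumps a grid-aligned lattice shows.
* `plate_stack`, `sphere_pack` — slabs and simple-cubic sphere packings
  with analytic `bv_tv`.
* `ramp` — strictly increasing intensity along the third axis; exactly one
  LBP code over the interior, entropy 0.
* `two_phase_noise` — smoothed seeded Gaussian noise thresholded at a
  quantile; irregular two-intensity structure at a requested volume
  fraction.

Validation phantoms for orientation use `blur_sigma_vox = 1`, emulating the
scanner point-spread function at typical micro-CT sampling (FWHM ≈ 2.4
voxels ≈ 65 µm at 27.8 µm voxels). This is also what makes the phantom a
genuinely gray-level image — on a hard two-level volume most interior codes
are the degenerate all-marker pattern. Degradation adds Gaussian noise after
the blur, clipped to the input intensity range, with all randomness driven
by a single integer seed and the global RNG state left untouched.

What the phantoms do **not** emulate: beam hardening, ring artifacts,
partial-volume effects beyond Gaussian blur, anatomically realistic
trabecular networks, or tissue-mineral-density calibration. Passing the
phantom suite therefore demonstrates correctness of the operators and
recoverability of geometry under idealized imaging, not robustness to every
scanner artifact.

## Validation problem sizes

The test suite validates operators against independent brute-force oracles
on random volumes up to 15³ (bit-exact histogram and ALCM counts, angles to
1e-9), orientation recovery on 64³ rod lattices at 0/30/60/90°, morphometry
on analytic balls, slabs, cylinders, stepped wedges and a 64³ three-level
Menger-sponge fixture, and the statistical contracts on simulated donor
tables (null check at 200 donors). These sizes were chosen so the full suite
exercises every code path on a laptop-class machine in well under a minute
while keeping discretization effects below the asserted tolerances.

## Known limitations

* Elevation from 26 fixed directions is quantized; at radius 1.0 expect up
  to ~6° bias for oblique structures (see the radius discussion above).
* Local thickness inherits the half-voxel parity artifact and reports
  volume-weighted means.
* BS/BV depends mildly on the pre-smoothing σ; σ = 1 voxel is calibrated
  for structures a few voxels thick and will round off genuinely sub-voxel
  surface detail.
* The 16-bit pre-threshold rescaling assumes the vendor's 8-bit value was a
  fraction of full scale; pass an explicit threshold when calibration is
  known.
* TIFF export is integer-only (8/16-bit); float volumes round-trip through
  NIfTI.
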