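# trabtex

Volumetric local-binary-pattern (3D LBP) texture analysis and conventional
morphometry for micro-CT volumes of subchondral and trabecular bone.

## The problem

Osteoarthritis remodels the bone beneath the cartilage: the subchondral plate
thickens, the trabecular lattice densifies, and the *local* organization of
bone becomes more heterogeneous. Conventional morphometry (BV/TV, Tb.Th,
Tb.Sp, ...) summarizes global structure; it does not describe the randomness
or the orientation of local patterns. `trabtex` provides both families of
descriptors for researchers quantifying bone structural adaptation from
gray-level micro-CT stacks, together with a synthetic-phantom module that
ships analytic ground truth for every measure.

## The method

**3D local binary patterns.** Around every voxel, 26 neighbors are placed on
a sphere (the normalized directions of the 3×3×3 neighborhood) and their gray
values are obtained by trilinear interpolation. Neighbors with a value equal
to or higher than the centre are *markers*; the marker indicator bits form a
26-bit pattern code. Only voxels with at least one neighbor above a fixed
intensity threshold enter the analysis, so empty marrow space is ignored.
Pattern heterogeneity is the Shannon entropy of the code distribution,

&nbsp;&nbsp;&nbsp;&nbsp;E = −Σᵢ Pᵢ log₂ Pᵢ ,

zero when the volume contains a single local pattern. The number of distinct
patterns and the mean marker count are reported alongside.

**Pattern orientation.** For each valid pattern (3–24 markers, marker set not
more dispersed around its centroid than the non-markers), the first principal
axis of the marker positions gives the pattern's direction; its *elevation*
is the angle against the transverse plane along the distal–proximal (third
array) axis — 90° = longitudinal, 0° = transverse; azimuth is ignored. An
angle-level co-occurrence matrix (ALCM) counts, over all 26-adjacent voxel
pairs, how often elevation bin *i* neighbors elevation bin *j*, and the
homogeneity of elevation is

&nbsp;&nbsp;&nbsp;&nbsp;H = Σᵢⱼ ALCM(i, j) / (1 + |i − j|) ,

equal to 1 when neighboring voxels always share an elevation bin.

**Segmentation and morphometry.** Binarization follows a two-stage recipe: a
fixed pre-threshold (60 on the 8-bit scale) followed by a local adaptive
threshold at the mean of the window minimum and maximum (5-voxel-radius ball
by default). Morphometry covers BV/TV, BS/BV (marching-tetrahedra isosurface
area), Tb.Th and Tb.Sp (maximal-inscribed-sphere local thickness), Tb.N
(BV/TV ÷ Tb.Th), box-counting fractal dimension, and subchondral plate
thickness, with a 2D mode for histological sections.

**Statistics.** Donor-equally-weighted Pearson correlation (each sample
weighted 1/nᵢ so multi-sample donors are not pseudoreplicated; degrees of
freedom from the donor count) and CV% precision analysis.

## Worked example

A rod-lattice phantom (rods at 60° elevation, radius 3 voxels, spacing 12,
PSF-like blur of 1 voxel) analysed end to end:

```r
library(trabtex)
spec <- phantom_spec("rod_lattice", size_vox = c(64, 64, 64),
                     elevation_deg = 60, element_radius_vox = 3,
                     spacing_vox = 12, blur_sigma_vox = 1, seed = 42)
ph <- generate_phantom(spec)
ph$truth$bv_tv
#> [1] 0.1963495

nb  <- spherical_neighborhood(1.5)
roi <- eligibility_mask(ph$volume, nb, 60)
lbp_summary(lbp_histogram(ph$volume, roi, nb))
#> <lbp_summary> entropy 6.5887 bits, 519 distinct patterns, mean markers 11.232

orientation_summary(ph$volume, roi, nb)
#> <orientation_summary> mean elevation 56.95 deg, entropy 2.7534 bits,
#>   valid fraction 0.737, homogeneity 0.5231

morphometry_summary(adaptive_binarize(ph$volume, binarization_params()))
#> <morphometry_summary> BV/TV 0.184, BS/BV 22.18 /mm, Tb.Th 0.1569 mm,
#>   Tb.Sp 0.3083 mm, Tb.N 1.17 /mm, FD 2.474
```

The recovered mean elevation (56.95°) sits within one 5° bin of the generated
60°; BV/TV of the binarized volume (0.184) tracks the analytic πr²/s² of the
lattice (0.196; the residual gap is blur + adaptive-threshold edge loss); and
Tb.N (1.17/mm) matches the analytic rod count 1.18/mm carried in
`ph$truth`. A single-orientation phantom like this one scores high
homogeneity; mixing orientations lowers it — the direction used to track
disease-related disorganization.

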