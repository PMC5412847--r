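Package: trabtex
Title: Volumetric Local Binary Pattern Texture Analysis for Trabecular Bone Micro-CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Texture and morphometric analysis of micro-computed-tomography volumes of
    trabecular and subchondral bone. Implements volumetric (3D) local binary patterns on a
    26-neighbor spherical sampling with grayscale interpolation, pattern histograms and
    Shannon pattern entropy, per-pattern elevation angles via principal-axis analysis with
    validity filtering, angle-level co-occurrence matrices and homogeneity of elevation, a
    two-stage binarization (fixed pre-threshold followed by local midrange adaptive
    thresholding), conventional bone morphometry (bone volume fraction, specific bone
    surface via triangulated isosurfaces, local thickness by maximal inscribed spheres,
    trabecular number, box-counting fractal dimension, plate thickness), parametric
    synthetic phantoms with analytic ground truth, and donor-equally-weighted correlation
    and coefficient-of-variation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
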