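---
title: "Quantifying core-shell tumor spheroids from two-channel confocal stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying core-shell tumor spheroids from two-channel confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A core-shell multicellular tumor spheroid (MCTS) is an in vitro aggregate in
which an inner population of cancer cells (the core) is enclosed by a layer
of a second, separately labelled population (the shell). Two confocal
channels describe such a spheroid: a nuclear stain (DAPI-like) marking every
cell's nucleus, and a cytoplasmic dye carried only by the shell-seeded
cells. The questions a core-shell formation experiment asks are
quantitative: how thick is the shell, how completely does it cover the
core, how large is the core, how many cells sit in each compartment, and
how much do the two populations mix?

`coreshell` answers these questions from a single two-channel z-stack per
spheroid. Every stage is verifiable: a synthetic phantom generator renders
spheroids with exactly known geometry and content, and the test suite
demands that each analysis recover those ground-truth parameters.

## Pipeline overview

```{r}
library(coreshell)
stack <- read_stack("spheroid.ome.tif")        # spacing from OME-XML
report <- run_pipeline(stack, pipeline_config())
report$line_summary$mean_shell_thickness       # um
report$line_summary$coverage_percent
report$compartments$shell_farred_fraction
```

The stages, in order:

1. **Isotropic resampling.** Confocal stacks are anisotropic (e.g.
   0.4393 x 0.4393 um pixels, 0.9 um optical sections). The z-axis is
   linearly resampled to `target_z_spacing` (default 0.45 um), giving
   approximately isotropic voxels so that distances, structuring elements
   and digital lines behave uniformly in all directions.
2. **Smoothing.** A separable Gaussian of `smooth_sigma` (default 0.5 um,
   sub-nuclear) suppresses shot noise without merging adjacent nuclei.
3. **Local adaptive threshold.** A voxel is foreground when its intensity
   exceeds the mean over a box neighbourhood whose side is, per axis, the
   stack dimension divided by `threshold_divisor` (default 8), scaled by
   `1 + sensitivity`. The box mean makes the decision invariant to affine
   intensity rescaling at `sensitivity = 0`. The rule is strict
   (`>`): a voxel in the exactly-constant interior of a very large bright
   plateau ties with its own window mean and is left to the hole-filling
   step below; with realistic noise and windows larger than nuclei this
   case does not arise.
4. **Cleanup.** 26-connected components smaller than `min_object_volume`
   (default half a nucleus volume, with `nucleus_radius` defaulting to
   4 um) are removed. Cavities (6-connected background not reachable from
   the stack border) are filled in the nuclear mask. The shell mask is
   *not* hole-filled: the dye-negative voxels between labelled shell cells
   are genuine signal voids, not cavities. Two shell masks are kept: the
   raw thresholded mask, used for all voxel-fraction statistics, and the
   speckle-filtered mask, used for line analysis and mask construction
   (isolated sub-nuclear positive specks carry no structural evidence and
   would otherwise trigger spurious "first positive" hits).
5. **Whole-spheroid volume.** The union of the two masks is closed with a
   ball of `whole_closing_radius` (default 5 um; it must exceed half the
   largest inter-nucleus gap), hole-filled, and reduced to its largest
   component (one spheroid per well).
6. **Nuclei separation.** The Euclidean distance transform of the nuclear
   mask (computed in physical units, so it stays correct on anisotropic
   grids) is negated and flooded: seeds are the regional minima after an
   H-minima transform of depth `hmin_depth` (default 1 um — below the
   typical nucleus radius, above discretisation ripple), implemented by
   grayscale reconstruction restricted to the mask. A peak shallower than
   `h` relative to the background level is suppressed entirely. A second
   pass removes seeds whose basins are smaller than `refine_fraction`
   (default 0.70) of the median basin volume and re-floods, limiting
   over-segmentation; exactly one refinement pass is applied. Flooding
   order ties are broken first-in-first-out in lexicographic voxel order,
   so labellings are bit-reproducible.
7. **Morphometry.** Volume is the voxel count times the voxel volume;
   sphericity is `psi = pi^(1/3) * (6 V)^(2/3) / A`; the equivalent
   diameter is `(6 V / pi)^(1/3)`. The surface area estimator is described
   below. Cell number is the total nuclear-mask volume divided by the
   median watershed nucleus volume — robust to touching nuclei that the
   watershed fails to split, since the median is taken over basins.
8. **Radial line analysis.** The core centre is the nuclear-intensity
   weighted centre of mass over nuclear-positive, shell-negative voxels.
   5000 quasi-uniform directions (a spherical Fibonacci lattice) are cast
   from the centre; the last in-mask voxel along each ray is a surface
   point with radial distance `r`, and the voxels connecting centre to
   surface are enumerated with a 3D Bresenham digital line (26-connected,
   monotone per axis, endpoints exact). Along each line, shell thickness is
   the count of shell-positive voxels times the direction-corrected voxel
   length and the core radius is the count of leading negatives before the
   first positive times that length. Coverage is the percentage of lines
   containing any positive voxel. Concentric 5-um layers around the centre
   provide an orthogonal, distance-based profile of the shell fraction.
9. **Compartments.** The union of leading-negative segments over covered
   lines (the core "shadow") is closed with `core_closing_radius`
   (default 6 um: the inter-line gap at a ~35 um core with 5000 lattice
   directions is about 2 um, so the default carries a 3x margin),
   hole-filled, intersected with the whole mask and reduced to one
   component; the shell is the set complement within the whole mask, so
   the two compartments partition the spheroid exactly. Voxel fractions
   and nuclei counts (compartment nuclear volume over the median nucleus
   volume, so boundary-straddling nuclei count fractionally) are reported
   per compartment, including the shell split into dye-positive and
   dye-negative sub-volumes and the pooled positive/negative totals.

## Numerical choices

**Direction-corrected voxel length.** A digital line of `n` voxels
spanning a physical distance `r` assigns each voxel the uniform step
`r / n`, so per-line steps sum exactly to `r` regardless of orientation.
Non-contiguous positive voxels all count toward thickness; a line with no
positive voxel contributes zero thickness to the all-line mean, is flagged
uncovered, and is excluded from core-radius aggregation (it carries no
boundary evidence). Both the all-line and covered-only thickness means are
reported.

**Surface area.** Counting exposed voxel faces overestimates curved
surface area by up to 50%, and isosurface meshes of *binary* data
(marching cubes or tetrahedra, with or without prior smoothing of the
indicator) either inherit a +9-27% staircase excess on curved surfaces or
round away sharp edges when smoothed. The estimator used here weights
every exposed voxel face by `|n_a|`, the matching component of the local
unit surface normal, estimated from a Gaussian-smoothed
(`normal_smooth_sigma = 0.7` voxels) signed Euclidean distance field with
a half-voxel interface correction. The weighting is exact for planar
surfaces of any orientation; the tests pin it against closed forms (a
digitised ball must reach sphericity 0.97 or higher at 0.45 um voxels, a
cube must match `(pi/6)^(1/3)` within 2%). A marching-tetrahedra mesh of
the signed distance field supplies the mesh-enclosed volume, asserted to
agree with the voxel-count volume within 3%. Sphericity can exceed 1 by a
small mesh tolerance on near-perfect balls.

**Surface sampling.** "Equally spaced" surface points are realised as a
deterministic spherical Fibonacci lattice with poles included
(`z_k = 1 - 2k/(n-1)`), so two points are antipodal and the
nearest-neighbour angular spacing varies by less than a factor of two
across 5000 directions. Lattice directions are reproducible run to run;
exact-uniformity correction weights are out of scope.

**Spherical convention.** The polar angle is elevation above the x-y
plane, in [-pi/2, pi/2]; the azimuth is measured in the x-y plane from +x,
in [-pi, pi]. z increases away from the coverslip, so a coverage deficit
at the well bottom appears at polar angles near -pi/2. Angular trends are
binned at pi/10 (azimuth) and pi/20 (polar) by default, reporting per-bin
mean, standard deviation and count; empty bins are kept with an explicit
no-data marker.

**Degenerate inputs.** Empty masks pass through cleanup; an all-constant
channel thresholds to an empty mask with a warning; an empty
nuclear-minus-shell difference mask makes the centre fall back to the
unweighted centroid with a warning; a seeding that suppresses every seed
raises an error directing the caller to lower `hmin_depth`; refinement
that would drop all seeds keeps the largest and warns; lines with a
positive voxel at the origin contribute nothing to the core shadow.

## The phantom generator

`phantom_spec()` + `render_geometry_phantom()` /
`render_image_phantom()` emulate the data this pipeline consumes: one
spheroid per stack — a ball of unlabelled core volume surrounded by a
shell of labelled cell volume — sampled at 0.45 um isotropic voxels by
default, with geometric defaults set to the mean published spheroid
morphology used as the benchmark fixture (34.3 um core radius, 23.2 um
shell thickness).

Design choices, made once:

* Shell coverage is imposed as a single polar spherical cap about
  `cap_axis` (default -z, the well bottom, where real deficits occur); the
  cap half-angle follows from the coverage fraction by the closed-form
  cap-area identity, which gives exact ground truth for coverage and for
  angular-trend tests.
* Nuclei are axis-aligned ellipsoids with semi-axes drawn from a truncated
  normal (mean 4 um, sd 0.4 um by default; truncated at two standard
  deviations), placed by rejection sampling with bounding spheres
  separated by a two-voxel gap so that rendered nuclei never touch. The
  generator fails loudly, reporting the achieved count, if the requested
  packing is infeasible.
* Shell-channel labelling is per-voxel independent: shell voxels are
  positive with probability `shell_label_purity`, core voxels with
  probability `core_contamination`. This is the harshest version of
  imperfect labelling (real contamination is cell-sized and clustered);
  sub-nuclear speckle filtering handles it, and the realized fractions are
  recorded in the ground truth.
* Background offset is fixed at 5% of the dynamic range; blur
  (`psf_sigma`) is applied before noise (`gaussian` or `poisson`); all
  randomness derives from `rng_seed`, and a fixed spec renders
  bit-identical stacks.

What the phantoms deliberately do **not** model: depth-dependent
attenuation, spectral bleed-through, refractive-index mismatch, intensity
gradients within nuclei, and cell-shaped (rather than voxel-i.i.d.) label
mixing. Passing the recovery suite therefore demonstrates the correctness
of the measurement machinery, not robustness to every optical artefact of
real clearing and imaging.

## Known limitations

* The core-shadow closing acts as an upper envelope over the per-line
  first-positive radii. With voxel-i.i.d. labelling the deepest of `n`
  lines penetrates `~log(n)/log(1/purity)` voxels past the true boundary,
  so reconstructed cores carry a small outward bias — about one percent of
  the positive-voxel fraction at the benchmark scale, but proportionally
  large for cores only a dozen micrometres across. The tests assert tight
  recovery at full scale and only order-of-magnitude agreement at toy
  scale.
* Sub-voxel i.i.d. contamination combined with optical blur can merge into
  clusters that survive the speckle filter; the pipeline is validated with
  blur on clean-label phantoms and without blur on stochastic-label
  phantoms.
* The cell-count estimator assumes the median watershed basin approximates
  a single nucleus volume; strongly size-dispersed populations bias it.
* One spheroid per stack is assumed throughout (largest-component
  selection).

## Problem sizes

The test suite exercises toy grids (about 30-130 voxels per axis) for unit
and oracle tests, and full benchmark-scale phantoms (about 280 voxels per
axis at 0.45 um, 5000 lines, 293 nuclei) in the acceptance suite; the
acceptance script `scripts/acceptance.R` re-runs the full-scale recoveries
from scratch and writes the recovered coverage, thickness, radii,
compartment fractions and cell count as JSON.
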