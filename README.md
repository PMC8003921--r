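# coreshell

Quantitative 3D image analysis of **core-shell multicellular tumor
spheroids** (MCTS) from two-channel confocal z-stacks.

Core-shell spheroids place one cell population (the core) inside a layer of
a second, separately labelled population (the shell), mimicking the spatial
architecture of solid tumors better than mixed co-cultures. Assessing how
well such a construct formed is a measurement problem: given a nuclear
channel (all cells) and a shell channel (cytoplasmic dye in shell-seeded
cells only), quantify the shell thickness, the core radius, how completely
the shell covers the core, and the voxel and cell content of each
compartment.

`coreshell` implements the full analysis:

* **Segmentation** — z-interpolation to isotropic voxels, physical-unit
  Gaussian smoothing, local adaptive (box-mean) thresholding, small-object
  removal and hole filling, all in true 3D.
* **Nuclei** — two-pass seeded watershed on the Euclidean distance
  transform with H-minima-stabilised seeds; cell number estimated as total
  nuclear volume over the median single-nucleus volume.
* **Morphometry** — volume *V*, surface area *A*, equivalent diameter
  (6*V*/π)^(1/3), and sphericity

  Ψ = π^(1/3) (6 V)^(2/3) / A,

  1 for a perfect sphere (surface area from orientation-weighted boundary
  faces, validated against closed-form sphere and cube areas).
* **Radial line analysis** — spherical coordinates (radial distance *r*,
  polar/elevation angle φ ∈ [−π/2, π/2], azimuth θ ∈ [−π, π]) about the
  intensity-weighted core centre; 5000 quasi-uniform surface points; 3D
  Bresenham voxel lines from centre to surface; per-line shell thickness
  (positive voxels × direction-corrected voxel length), core radius
  (leading negatives × the same), coverage percentage (lines with any
  positive voxel), concentric 5 µm layer profiles, and angular trends in
  π/10 / π/20 bins.
* **Compartments** — core "shadow" from the leading-negative line
  segments, morphological closing into a core mask, shell as the exact
  complement, and per-compartment voxel fractions plus nuclei counts
  (including the shell split into dye-positive and dye-negative volume).
* **Phantoms** — a synthetic spheroid generator with machine-readable
  ground truth (geometry, coverage cap, per-nucleus placements, label
  mixing, blur, noise), so every stage is verified by parameter recovery
  without any external data.

## Worked example

Render a synthetic core-shell spheroid (14 µm core, 10 µm shell, 90 %
coverage, 34 nuclei) and analyse it end to end:

```r
library(coreshell)

spec <- phantom_spec(core_radius = 14, shell_thickness = 10, spacing = 0.9,
                     coverage_fraction = 0.9,
                     n_core_nuclei = 10, n_shell_nuclei = 24,
                     nucleus_radius_mean = 2.6, nucleus_radius_sd = 0.15,
                     rng_seed = 6)
ph <- render_image_phantom(spec)

cfg <- pipeline_config(nucleus_radius = 2.6, n_surface_points = 1500,
                       target_z_spacing = 0.9)
report <- run_pipeline(ph$stack, cfg)
report
#> <spheroid_report>
#>   volume       52320 um^3
#>   sphericity   0.878
#>   cells        34
#>   coverage     91.27 %
#>   shell thick  8.862 um
#>   core radius  13.79 um
```

The recovered values sit on the construction: 34 cells (seeded 34),
coverage 91.3 % (constructed 90 %), shell thickness 8.9 µm (10 µm minus
threshold erosion of the blurred rim), core radius 13.8 µm (constructed
14 µm). The concentric layer profile shows the core-shell transition —
near zero shell signal inside 10 µm, saturated beyond 15 µm:

```r
head(report$layers[, c("layer", "r_inner", "r_outer", "ratio")], 5)
#>   layer r_inner r_outer     ratio
#> 1     0       0       5 0.0000000
#> 2     1       5      10 0.0000000
#> 3     2      10      15 0.2984297
#> 4     3      15      20 0.9957617
#> 5     4      20      25 0.9996609
```

and the compartment accounting recovers the seeded 10 core / 24 shell
nuclei as 9.4 and 24.8 with a dye-positive shell fraction of 0.989:

```r
c(report$compartments$nuclei_core, report$compartments$nuclei_shell)
#> [1]  9.388175 24.796919
```

Real stacks enter the same way via `read_stack("spheroid.ome.tif")`
(voxel spacing from OME-XML, a JSON sidecar, or an explicit `spacing`
argument). A thin command-line wrapper lives at
`inst/cli/coreshell-cli.R` (`simulate` and `analyze` subcommands).

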