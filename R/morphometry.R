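# Whole-spheroid morphometry: solid-volume construction, volume / surface
# area / equivalent diameter / sphericity, cell-count estimation and
# shell-channel voxel ratios.

#' Combine channel masks into one solid spheroid mask
#'
#' Takes the union of the nuclear and shell-channel masks, morphologically
#' closes it with a ball of `closing_radius` (dilation followed by erosion,
#' bridging inter-nucleus gaps), fills enclosed cavities and keeps the
#' single largest 26-connected component (one spheroid per stack).
#'
#' @param dapi_mask,farred_mask [binary_mask()]s on the same grid.
#' @param closing_radius ball radius in micrometres (default 5); must
#'   exceed half the largest inter-nucleus gap to produce a solid volume.
#' @return A solid [binary_mask()].
#' @export
whole_volume_mask <- function(dapi_mask, farred_mask, closing_radius = 5) {
  stopifnot(inherits(dapi_mask, "binary_mask"),
            inherits(farred_mask, "binary_mask"))
  check_same_grid(dapi_mask, farred_mask)
  u <- dapi_mask$data | farred_mask$data
  if (!any(u)) stop("both masks are empty", call. = FALSE)
  d <- dim(u)
  sp <- dapi_mask$spacing
  closed <- mask_close(u, sp, closing_radius)
  closed <- array(cpp_fill_holes(as.logical(closed), d), d)
  lab <- cpp_label_components(as.logical(closed), d, 26L)
  nlab <- max(lab)
  if (nlab > 1L) {
    counts <- tabulate(lab[lab > 0L], nbins = nlab)
    closed <- array(lab == which.max(counts), d)
  }
  binary_mask(closed, sp)
}

#' Morphometric measurements of a solid mask
#'
#' Volume is the foreground voxel count times the voxel volume. Surface
#' area uses orientation-weighted boundary-face counting: every exposed
#' voxel face contributes its geometric area times `|n_a|`, the matching
#' component of the local unit surface normal, estimated from a lightly
#' smoothed signed Euclidean distance field. The weighting is exact for
#' planar surfaces of any orientation and suppresses the staircase
#' overestimate (up to +50% for naive face counting, +9-27% for meshes of
#' binary data) that would corrupt sphericity. A marching-tetrahedra mesh
#' of the signed distance field provides the mesh-enclosed volume as an
#' internal consistency check. Equivalent diameter is `(6 V / pi)^(1/3)`
#' and sphericity is `psi = pi^(1/3) (6 V)^(2/3) / A` (1 for a perfect
#' sphere; a documented tolerance of a few percent above 1 can occur from
#' the area estimator on near-perfect balls).
#'
#' @param mask a non-empty solid [binary_mask()].
#' @param normal_smooth_sigma Gaussian sigma in voxel units used to smooth
#'   the signed distance field before estimating surface normals
#'   (default 0.7; validated against closed-form sphere and cube areas).
#' @return list of class `morphometry`: `volume_um3`, `surface_area_um2`,
#'   `mesh_volume_um3`, `equivalent_diameter_um`, `sphericity`.
#' @export
measure_morphometry <- function(mask, normal_smooth_sigma = 0.7) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop("mask is empty", call. = FALSE)
  d <- dim(mask$data)
  if (mask_touches_boundary(mask$data)) {
    warning("mask touches the grid boundary; surface area will be ",
            "underestimated")
  }
  vol <- mask_volume(mask)
  sdf <- signed_distance(mask)
  sm <- sdf
  if (normal_smooth_sigma > 0) {
    for (axis in 1:3) {
      s_vox <- normal_smooth_sigma
      r <- max(1L, ceiling(4 * s_vox))
      k <- exp(-0.5 * ((-r:r) / s_vox)^2)
      sm <- cpp_convolve_axis(sm, d, k / sum(k), axis - 1L)
    }
  }
  area <- cpp_face_area(as.numeric(sm), as.logical(mask$data), d,
                        mask$spacing)
  mm <- cpp_march_measure(as.numeric(sdf), d, mask$spacing, 0)
  eq_d <- (6 * vol / pi)^(1 / 3)
  psi <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  structure(
    list(volume_um3 = vol, surface_area_um2 = area, mesh_volume_um3 = mm[2],
         equivalent_diameter_um = eq_d, sphericity = psi),
    class = "morphometry"
  )
}

# Half-voxel-corrected signed Euclidean distance field, positive inside.
# Distances to voxel centres overshoot the true interface by about half a
# voxel on each side; subtracting 0.5*min(spacing)*sign restores a unit
# slope across the boundary (exact for axis-aligned faces on isotropic
# grids, approximate otherwise).
signed_distance <- function(mask) {
  d <- dim(mask$data)
  f <- cpp_edt(as.logical(mask$data), d, mask$spacing) -
    cpp_edt(!mask$data, d, mask$spacing)
  f - 0.5 * min(mask$spacing) * sign(f)
}

#' @export
print.morphometry <- function(x, ...) {
  cat("<morphometry> V = ", signif(x$volume_um3, 4), " um^3, A = ",
      signif(x$surface_area_um2, 4), " um^2, d_eq = ",
      signif(x$equivalent_diameter_um, 4), " um, psi = ",
      signif(x$sphericity, 3), "\n", sep = "")
  invisible(x)
}

#' Estimate cell number from nuclear volume
#'
#' Approximates the cell count as the total segmented nuclear volume
#' divided by the median volume of a single nucleus.
#'
#' @param dapi_mask segmented nuclear-channel [binary_mask()].
#' @param median_nucleus_volume median single-nucleus volume in um^3 (> 0),
#'   from [median_nucleus_volume()].
#' @return list with `estimate` (real-valued ratio) and `count` (rounded).
#' @export
estimate_cell_count <- function(dapi_mask, median_nucleus_volume) {
  stopifnot(inherits(dapi_mask, "binary_mask"))
  if (!is.finite(median_nucleus_volume) || median_nucleus_volume <= 0) {
    stop("median_nucleus_volume must be > 0", call. = FALSE)
  }
  est <- mask_volume(dapi_mask) / median_nucleus_volume
  list(estimate = est, count = round(est))
}

#' Shell-channel positive voxel ratio in a region
#'
#' Number of shell-channel-positive voxels inside the region divided by the
#' total number of region voxels.
#'
#' @param farred_mask shell-channel positive [binary_mask()].
#' @param region_mask non-empty region of interest [binary_mask()].
#' @return fraction in \[0, 1\].
#' @export
farred_voxel_ratio <- function(farred_mask, region_mask) {
  stopifnot(inherits(farred_mask, "binary_mask"),
            inherits(region_mask, "binary_mask"))
  check_same_grid(farred_mask, region_mask)
  n_region <- sum(region_mask$data)
  if (n_region == 0L) stop("region mask is empty", call. = FALSE)
  sum(farred_mask$data & region_mask$data) / n_region
}

# ---- internal morphology ----------------------------------------------------

# ball dilation / erosion / closing via distance thresholding (exact
# Euclidean ball structuring element, anisotropy-aware)
mask_dilate <- function(data, spacing, radius) {
  if (radius <= 0) return(data)
  d <- dim(data)
  dist_to_fg <- cpp_edt(!data, d, spacing)  # distance to nearest TRUE
  array(data | dist_to_fg <= radius, d)
}

mask_erode <- function(data, spacing, radius) {
  if (radius <= 0) return(data)
  d <- dim(data)
  dist_to_bg <- cpp_edt(as.logical(data), d, spacing)
  array(data & dist_to_bg > radius, d)
}

mask_close <- function(data, spacing, radius) {
  mask_erode(mask_dilate(data, spacing, radius), spacing, radius)
}

mask_touches_boundary <- function(data) {
  d <- dim(data)
  any(data[1, , ]) || any(data[d[1], , ]) ||
    any(data[, 1, ]) || any(data[, d[2], ]) ||
    any(data[, , 1]) || any(data[, , d[3]])
}
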