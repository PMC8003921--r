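# Center-to-surface line analysis in spherical coordinates: core centre
# localisation, concentric-layer profiling, quasi-uniform surface sampling,
# 3D Bresenham traversal, per-line shell metrics and angular trends.
#
# Convention: the polar angle phi is the elevation above the x-y plane
# (asin(z/r), range [-pi/2, pi/2]; -pi/2 points at the well bottom) and the
# azimuth theta = atan2(y, x), range [-pi, pi].

#' Intensity-weighted core centre
#'
#' The core centre is the nuclear-intensity-weighted centre of mass over
#' voxels that are nuclear-positive but not shell-channel-positive
#' (subtracting the shell mask removes the shell's nuclei from the
#' weighting). If that difference mask is empty, the unweighted centroid of
#' the whole nuclear mask is used with a warning.
#'
#' @param dapi_intensity 3D numeric array of nuclear-channel intensities.
#' @param dapi_mask nuclear-channel [binary_mask()].
#' @param farred_mask shell-channel [binary_mask()].
#' @return Named numeric length-3 (x, y, z), physical micrometres.
#' @export
find_core_center <- function(dapi_intensity, dapi_mask, farred_mask) {
  stopifnot(inherits(dapi_mask, "binary_mask"),
            inherits(farred_mask, "binary_mask"))
  check_same_grid(dapi_mask, farred_mask)
  dapi_intensity <- as_volume(dapi_intensity)
  region <- dapi_mask$data & !farred_mask$data
  if (!any(region)) {
    warning("nuclear mask minus shell mask is empty; falling back to the ",
            "unweighted nuclear-mask centroid")
    region <- dapi_mask$data
    if (!any(region)) stop("nuclear mask is empty", call. = FALSE)
    w <- rep(1, sum(region))
  } else {
    w <- dapi_intensity[region]
  }
  idx <- which(region)
  co <- arrayInd(idx, dim(region))
  sp <- dapi_mask$spacing
  tot <- sum(w)
  c(x = sum(w * (co[, 1] - 1) * sp[1]) / tot,
    y = sum(w * (co[, 2] - 1) * sp[2]) / tot,
    z = sum(w * (co[, 3] - 1) * sp[3]) / tot)
}

#' Shell-channel ratio in concentric layers
#'
#' Assigns every in-spheroid voxel to a concentric layer
#' `floor(distance / layer_width)` by its distance from the core centre and
#' reports the shell-positive voxel fraction per layer. Layers with zero
#' voxels are absent from the output.
#'
#' @param whole_mask solid spheroid [binary_mask()].
#' @param farred_mask shell-channel positive [binary_mask()].
#' @param center core centre, physical micrometres (inside the mask).
#' @param layer_width layer width in micrometres (default 5).
#' @return data.frame: `layer` (0-based index), `r_inner`, `r_outer` (um),
#'   `n_voxels`, `n_positive`, `ratio`.
#' @export
concentric_layer_ratios <- function(whole_mask, farred_mask, center,
                                    layer_width = 5) {
  stopifnot(inherits(whole_mask, "binary_mask"),
            inherits(farred_mask, "binary_mask"))
  check_same_grid(whole_mask, farred_mask)
  if (layer_width <= 0) stop("layer_width must be > 0", call. = FALSE)
  if (!point_in_mask(center, whole_mask)) {
    stop("center does not lie inside the mask", call. = FALSE)
  }
  d <- dim(whole_mask$data)
  r <- radial_distance_field(d, whole_mask$spacing, center)
  inm <- whole_mask$data
  layer <- floor(r[inm] / layer_width)
  pos <- farred_mask$data[inm]
  n_vox <- tapply(rep(1L, length(layer)), layer, sum)
  n_pos <- tapply(as.integer(pos), layer, sum)
  lev <- as.integer(names(n_vox))
  data.frame(
    layer = lev,
    r_inner = lev * layer_width,
    r_outer = (lev + 1) * layer_width,
    n_voxels = as.integer(n_vox),
    n_positive = as.integer(n_pos),
    ratio = as.numeric(n_pos / n_vox),
    row.names = NULL
  )
}

#' Quasi-uniform unit directions (spherical Fibonacci lattice)
#'
#' Deterministic lattice of `n` near-equally-spaced directions: elevations
#' `z_k = 1 - 2k/(n-1)` (poles included, so `n = 2` gives antipodal
#' directions) with azimuths advancing by the golden angle.
#'
#' @param n number of directions (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (n == 1L) return(matrix(c(0, 0, 1), 1, 3))
  k <- seq_len(n) - 1
  z <- 1 - 2 * k / (n - 1)
  z <- pmin(1, pmax(-1, z))
  rho <- sqrt(1 - z^2)
  golden <- pi * (3 - sqrt(5))
  th <- k * golden
  unname(cbind(rho * cos(th), rho * sin(th), z))
}

#' Sample surface points along lattice directions
#'
#' For each of `n_points` lattice directions, marches a ray from the centre
#' and records the last in-mask voxel before the ray leaves the grid; that
#' voxel is the surface point and `r` is the physical distance from the
#' centre to its voxel centre. Rays still inside the mask at the grid edge
#' are clamped with a warning.
#'
#' @param whole_mask solid spheroid [binary_mask()].
#' @param center core centre in physical micrometres (inside the mask).
#' @param n_points number of directions (default 5000).
#' @return data.frame: `theta`, `phi` (direction angles, radians), `ux`,
#'   `uy`, `uz` (unit direction), `vx`, `vy`, `vz` (surface voxel, 1-based)
#'   and `r` (um).
#' @export
sample_surface_points <- function(whole_mask, center, n_points = 5000) {
  stopifnot(inherits(whole_mask, "binary_mask"))
  if (n_points < 1) stop("n_points must be >= 1", call. = FALSE)
  if (!point_in_mask(center, whole_mask)) {
    stop("center does not lie inside the mask", call. = FALSE)
  }
  d <- dim(whole_mask$data)
  sp <- whole_mask$spacing
  dirs <- fibonacci_directions(n_points)
  hits <- cpp_cast_rays(as.logical(whole_mask$data), d, sp,
                        as.numeric(center), dirs, 0.25 * min(sp))
  if (any(hits[, 4] == 0L)) {
    stop("some rays found no in-mask voxel; is the centre inside the mask?",
         call. = FALSE)
  }
  vox <- hits[, 1:3, drop = FALSE] + 1L
  on_edge <- vox[, 1] == 1L | vox[, 1] == d[1] |
    vox[, 2] == 1L | vox[, 2] == d[2] |
    vox[, 3] == 1L | vox[, 3] == d[3]
  if (any(on_edge)) {
    warning(sum(on_edge), " ray(s) reached the grid boundary while still ",
            "inside the mask; surface points clamped")
  }
  pos <- sweep(vox - 1, 2, sp, "*")
  delta <- sweep(pos, 2, as.numeric(center), "-")
  r <- sqrt(rowSums(delta^2))
  ang <- direction_to_angles(dirs)
  data.frame(theta = ang$theta, phi = ang$phi,
             ux = dirs[, 1], uy = dirs[, 2], uz = dirs[, 3],
             vx = vox[, 1], vy = vox[, 2], vz = vox[, 3], r = r)
}

#' 3D Bresenham digital line
#'
#' Voxel path between two voxel indices: a 26-connected, per-axis monotone
#' digital line including both endpoints, of length
#' `max(|dx|, |dy|, |dz|) + 1`.
#'
#' @param start,end integer length-3 voxel indices (1-based).
#' @return n x 3 integer matrix of voxel indices (1-based).
#' @export
bresenham_3d <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != 3L || length(end) != 3L) {
    stop("start and end must be length-3 voxel indices", call. = FALSE)
  }
  cpp_bresenham(start - 1L, end - 1L) + 1L
}

#' Shell metrics along one centre-to-surface line
#'
#' The direction-corrected voxel length is `r / n`, the uniform physical
#' step attributed to each of the line's `n` voxels (per-voxel steps sum
#' exactly to `r`). Shell thickness is the number of shell-positive voxels
#' on the line times that step (non-contiguous positives all count); the
#' core radius is the number of leading negatives before the first positive
#' times the step. Lines with no positive voxel have thickness 0, are
#' flagged uncovered, and report `NA` core radius (excluded from core
#' statistics).
#'
#' @param path n x 3 integer matrix of voxel indices (1-based), ordered
#'   from the centre (first row) to the surface (last row).
#' @param farred_mask shell-channel positive [binary_mask()].
#' @param r physical line length in micrometres.
#' @return list: `shell_thickness`, `core_radius`, `covered`, `n_voxels`,
#'   `step`, `first_positive` (index into the path, NA if uncovered).
#' @export
line_metrics <- function(path, farred_mask, r) {
  stopifnot(inherits(farred_mask, "binary_mask"))
  if (is.null(dim(path)) || nrow(path) == 0L) {
    stop("empty line path", call. = FALSE)
  }
  d <- dim(farred_mask$data)
  lin <- path[, 1] + d[1] * (path[, 2] - 1L) + d[1] * d[2] * (path[, 3] - 1L)
  pos <- farred_mask$data[lin]
  n <- length(pos)
  step <- r / n
  npos <- sum(pos)
  if (npos == 0L) {
    return(list(shell_thickness = 0, core_radius = NA_real_,
                covered = FALSE, n_voxels = n, step = step,
                first_positive = NA_integer_))
  }
  fp <- which.max(pos)
  list(shell_thickness = npos * step,
       core_radius = (fp - 1L) * step,
       covered = TRUE, n_voxels = n, step = step,
       first_positive = as.integer(fp))
}

#' Full centre-to-surface line analysis
#'
#' Samples `n_points` surface points, traces the Bresenham line from the
#' centre voxel to each surface voxel and evaluates the shell metrics along
#' every line.
#'
#' @param whole_mask solid spheroid [binary_mask()].
#' @param farred_mask shell-channel positive [binary_mask()] (typically
#'   speckle-filtered; see [morphological_cleanup()]).
#' @param center core centre in physical micrometres.
#' @param n_points number of lines (default 5000).
#' @return Object of class `radial_lines`: list with `lines` (data.frame of
#'   per-line theta, phi, r, n_voxels, step, shell_thickness, core_radius,
#'   covered, first_positive), `paths` (list of voxel-index matrices),
#'   `center` and `spacing`.
#' @export
radial_line_analysis <- function(whole_mask, farred_mask, center,
                                 n_points = 5000) {
  stopifnot(inherits(whole_mask, "binary_mask"),
            inherits(farred_mask, "binary_mask"))
  check_same_grid(whole_mask, farred_mask)
  surf <- sample_surface_points(whole_mask, center, n_points)
  sp <- whole_mask$spacing
  cvox <- pmin(pmax(round(as.numeric(center) / sp) + 1L, 1L),
               dim(whole_mask$data))
  n <- nrow(surf)
  paths <- vector("list", n)
  thick <- numeric(n)
  core <- numeric(n)
  covered <- logical(n)
  nvox <- integer(n)
  step <- numeric(n)
  firstpos <- integer(n)
  for (i in seq_len(n)) {
    p <- bresenham_3d(cvox, c(surf$vx[i], surf$vy[i], surf$vz[i]))
    m <- line_metrics(p, farred_mask, surf$r[i])
    paths[[i]] <- p
    thick[i] <- m$shell_thickness
    core[i] <- m$core_radius
    covered[i] <- m$covered
    nvox[i] <- m$n_voxels
    step[i] <- m$step
    firstpos[i] <- if (is.na(m$first_positive)) NA_integer_
                   else m$first_positive
  }
  lines <- data.frame(
    theta = surf$theta, phi = surf$phi, r = surf$r,
    n_voxels = nvox, step = step, shell_thickness = thick,
    core_radius = core, covered = covered, first_positive = firstpos
  )
  structure(list(lines = lines, paths = paths, center = as.numeric(center),
                 spacing = sp, dim = dim(whole_mask$data)),
            class = "radial_lines")
}

#' @export
print.radial_lines <- function(x, ...) {
  s <- aggregate_lines(x)
  cat("<radial_lines> ", s$n_lines, " lines, mean r ",
      signif(s$mean_radius, 4), " um, mean shell thickness ",
      signif(s$mean_shell_thickness, 4), " um, coverage ",
      signif(s$coverage_percent, 4), "%\n", sep = "")
  invisible(x)
}

#' Per-spheroid summary of the line analysis
#'
#' Coverage is the percentage of lines containing at least one
#' shell-positive voxel. The thickness mean over all lines counts uncovered
#' lines as zero; a covered-only thickness mean is reported alongside. The
#' core-radius mean is over covered lines only (uncovered lines carry no
#' core-boundary evidence).
#'
#' @param lines a `radial_lines` object or its `lines` data.frame.
#' @return list: `n_lines`, `n_covered`, `coverage_percent`, `mean_radius`,
#'   `mean_shell_thickness`, `mean_shell_thickness_covered`,
#'   `mean_core_radius`, plus standard deviations (`sd_radius`,
#'   `sd_shell_thickness`, `sd_core_radius`).
#' @export
aggregate_lines <- function(lines) {
  df <- if (inherits(lines, "radial_lines")) lines$lines else lines
  if (nrow(df) == 0L) stop("no lines to aggregate", call. = FALSE)
  cov <- df$covered
  list(
    n_lines = nrow(df),
    n_covered = sum(cov),
    coverage_percent = 100 * sum(cov) / nrow(df),
    mean_radius = mean(df$r),
    sd_radius = sd(df$r),
    mean_shell_thickness = mean(df$shell_thickness),
    sd_shell_thickness = sd(df$shell_thickness),
    mean_shell_thickness_covered =
      if (any(cov)) mean(df$shell_thickness[cov]) else NA_real_,
    mean_core_radius =
      if (any(cov)) mean(df$core_radius[cov]) else NA_real_,
    sd_core_radius =
      if (any(cov)) sd(df$core_radius[cov]) else NA_real_
  )
}

#' Angular trend of shell thickness
#'
#' Bins the per-line shell thickness by azimuth (range \[-pi, pi\], default
#' bin width pi/10) or polar angle (range \[-pi/2, pi/2\], default pi/20)
#' and reports per-bin mean and standard deviation. Empty bins are kept
#' with `n = 0` and `NA` statistics.
#'
#' @param lines a `radial_lines` object or its `lines` data.frame.
#' @param axis `"azimuth"` or `"polar"`.
#' @param bin_width bin width in radians; must divide the angular range.
#' @return data.frame: `bin_lo`, `bin_hi`, `bin_mid`, `n`,
#'   `mean_thickness`, `sd_thickness`.
#' @export
angular_trend <- function(lines, axis = c("azimuth", "polar"),
                          bin_width = NULL) {
  axis <- match.arg(axis)
  df <- if (inherits(lines, "radial_lines")) lines$lines else lines
  rng <- if (axis == "azimuth") c(-pi, pi) else c(-pi / 2, pi / 2)
  if (is.null(bin_width)) {
    bin_width <- if (axis == "azimuth") pi / 10 else pi / 20
  }
  span <- diff(rng)
  nbins <- span / bin_width
  if (abs(nbins - round(nbins)) > 1e-9) {
    stop("bin_width must divide the angular range", call. = FALSE)
  }
  nbins <- as.integer(round(nbins))
  ang <- if (axis == "azimuth") df$theta else df$phi
  bin <- pmin(pmax(floor((ang - rng[1]) / bin_width), 0), nbins - 1)
  out <- data.frame(
    bin_lo = rng[1] + (0:(nbins - 1)) * bin_width,
    bin_hi = rng[1] + (1:nbins) * bin_width
  )
  out$bin_mid <- (out$bin_lo + out$bin_hi) / 2
  out$n <- as.integer(tabulate(bin + 1L, nbins))
  out$mean_thickness <- NA_real_
  out$sd_thickness <- NA_real_
  for (b in which(out$n > 0)) {
    v <- df$shell_thickness[bin == b - 1L]
    out$mean_thickness[b] <- mean(v)
    out$sd_thickness[b] <- if (length(v) > 1) sd(v) else NA_real_
  }
  out
}

# ---- spherical helpers ------------------------------------------------------

#' Convert unit directions to spherical angles
#' @param u n x 3 matrix (or length-3 vector) of unit directions.
#' @return list with `theta` (azimuth, \[-pi, pi\]) and `phi` (elevation,
#'   \[-pi/2, pi/2\]).
#' @export
direction_to_angles <- function(u) {
  if (is.null(dim(u))) u <- matrix(u, 1, 3)
  list(theta = atan2(u[, 2], u[, 1]),
       phi = asin(pmin(1, pmax(-1, u[, 3]))))
}

#' Convert spherical angles to unit directions
#' @param theta azimuth in radians.
#' @param phi elevation in radians.
#' @return n x 3 matrix of unit directions.
#' @export
angles_to_direction <- function(theta, phi) {
  cbind(cos(phi) * cos(theta), cos(phi) * sin(theta), sin(phi))
}

point_in_mask <- function(center, mask) {
  sp <- mask$spacing
  d <- dim(mask$data)
  v <- round(as.numeric(center) / sp) + 1
  if (any(v < 1) || any(v > d)) return(FALSE)
  mask$data[v[1], v[2], v[3]]
}
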