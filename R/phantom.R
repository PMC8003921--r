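# Synthetic core-shell spheroid phantoms with machine-readable ground truth.
# Geometry phantoms are exact, noise-free binary constructions; image
# phantoms add nuclei, per-voxel label mixing, optional blur and noise.

#' Half-angle of the uncovered spherical cap for a given shell coverage
#'
#' A shell that covers a fraction `coverage_fraction` of all ray directions
#' leaves a single polar cap uncovered. The cap's half-angle `alpha`
#' satisfies the spherical-cap area fraction identity
#' `(1 - cos(alpha)) / 2 = 1 - coverage_fraction`.
#'
#' @param coverage_fraction fraction of directions covered by shell, in
#'   \[0, 1\] (1 = full coverage, no cap).
#' @return Cap half-angle in radians (0 for full coverage, pi for none).
#' @export
cap_half_angle <- function(coverage_fraction) {
  if (any(!is.finite(coverage_fraction)) ||
      any(coverage_fraction < 0) || any(coverage_fraction > 1)) {
    stop("coverage_fraction must lie in [0, 1]", call. = FALSE)
  }
  acos(pmin(1, pmax(-1, 1 - 2 * (1 - coverage_fraction))))
}

#' Specification of a synthetic core-shell spheroid phantom
#'
#' Defines the geometry (core radius, shell thickness, shell coverage via a
#' single polar cap), the cellular content (numbers and sizes of core and
#' shell nuclei), the shell-channel labelling statistics (per-voxel label
#' purity in the shell, contamination rate in the core), and the imaging
#' model (axis-wise Gaussian blur, additive/Poisson noise, anisotropic
#' sampling). Geometric defaults follow the mean published spheroid
#' morphology that this package's analyses are benchmarked against.
#'
#' @param grid_shape integer length-3 voxel counts (nx, ny, nz); by default
#'   sized to fit the spheroid with a 4-voxel margin.
#' @param spacing voxel spacing in micrometres per axis (default isotropic
#'   0.45 um, the standard post-interpolation voxel size).
#' @param center physical centre of the spheroid in micrometres; default is
#'   the grid centre.
#' @param core_radius core radius in micrometres (> 0).
#' @param shell_thickness shell thickness in micrometres (>= 0).
#' @param coverage_fraction fraction of ray directions covered by the shell
#'   in \[0, 1\]; the uncovered directions form a single spherical cap.
#' @param cap_axis direction of the uncovered cap (default -z, i.e. the
#'   well bottom); normalised internally.
#' @param n_core_nuclei,n_shell_nuclei numbers of nuclei to place in the
#'   core and in the covered shell.
#' @param nucleus_radius_mean,nucleus_radius_sd mean and standard deviation
#'   (um) of the truncated-normal distribution of nucleus semi-axes.
#' @param shell_label_purity fraction of shell volume positive in the shell
#'   channel, in \[0, 1\] (per-voxel independent labelling).
#' @param core_contamination fraction of core volume positive in the shell
#'   channel, in \[0, 1\].
#' @param psf_sigma Gaussian blur sigma in micrometres (0 = none).
#' @param noise_model list with `type` one of "none", "gaussian"
#'   (field `sd`, as a fraction of the intensity range) or "poisson"
#'   (field `scale`, expected photon count at unit intensity).
#' @param rng_seed integer seed; fixed seed implies bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = NULL,
                         spacing = c(0.45, 0.45, 0.45),
                         center = NULL,
                         core_radius = 34.3,
                         shell_thickness = 23.2,
                         coverage_fraction = 1,
                         cap_axis = c(0, 0, -1),
                         n_core_nuclei = 0,
                         n_shell_nuclei = 0,
                         nucleus_radius_mean = 4,
                         nucleus_radius_sd = 0.4,
                         shell_label_purity = 1,
                         core_contamination = 0,
                         psf_sigma = 0,
                         noise_model = list(type = "none"),
                         rng_seed = 1L) {
  spacing <- check_spacing(spacing)
  if (!is.finite(core_radius) || core_radius <= 0) {
    stop("core_radius must be > 0", call. = FALSE)
  }
  if (!is.finite(shell_thickness) || shell_thickness < 0) {
    stop("shell_thickness must be >= 0", call. = FALSE)
  }
  if (coverage_fraction < 0 || coverage_fraction > 1) {
    stop("coverage_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (shell_label_purity < 0 || shell_label_purity > 1 ||
      core_contamination < 0 || core_contamination > 1) {
    stop("label fractions must lie in [0, 1]", call. = FALSE)
  }
  if (psf_sigma < 0) stop("psf_sigma must be >= 0", call. = FALSE)
  if (!is.list(noise_model) ||
      !noise_model$type %in% c("none", "gaussian", "poisson")) {
    stop("noise_model$type must be 'none', 'gaussian' or 'poisson'",
         call. = FALSE)
  }
  outer_radius <- core_radius + shell_thickness
  if (is.null(grid_shape)) {
    # auto margin of 8 um clears the default whole-mask closing dilation
    grid_shape <- as.integer(2 * ceiling((outer_radius + 8) / spacing) + 5L)
  }
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  if (length(grid_shape) != 3L || any(grid_shape < 3L)) {
    stop("grid_shape must be 3 positive voxel counts", call. = FALSE)
  }
  if (is.null(center)) {
    center <- (grid_shape - 1) / 2 * spacing
  }
  cap_axis <- as.numeric(cap_axis)
  nrm <- sqrt(sum(cap_axis^2))
  if (nrm == 0) stop("cap_axis must be a non-zero direction", call. = FALSE)
  cap_axis <- cap_axis / nrm
  # the spheroid must fit inside the grid with a >= 2-voxel margin
  extent <- (grid_shape - 1) * spacing
  lo <- center - outer_radius
  hi <- center + outer_radius
  if (any(lo < 2 * spacing - 1e-9) || any(hi > extent - 2 * spacing + 1e-9)) {
    stop("spheroid does not fit inside the grid with a 2-voxel margin; ",
         "enlarge grid_shape or shrink the spheroid", call. = FALSE)
  }
  structure(
    list(grid_shape = grid_shape, spacing = spacing, center = center,
         core_radius = core_radius, shell_thickness = shell_thickness,
         coverage_fraction = coverage_fraction, cap_axis = cap_axis,
         n_core_nuclei = as.integer(n_core_nuclei),
         n_shell_nuclei = as.integer(n_shell_nuclei),
         nucleus_radius_mean = nucleus_radius_mean,
         nucleus_radius_sd = nucleus_radius_sd,
         shell_label_purity = shell_label_purity,
         core_contamination = core_contamination,
         psf_sigma = psf_sigma, noise_model = noise_model,
         rng_seed = as.integer(rng_seed)),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> core ", x$core_radius, " um + shell ",
      x$shell_thickness, " um, coverage ",
      round(100 * x$coverage_fraction, 1), "%, grid ",
      paste(x$grid_shape, collapse = " x "), " @ (",
      paste(signif(x$spacing, 3), collapse = ", "), ") um\n", sep = "")
  invisible(x)
}

#' Render a noise-free binary geometry phantom
#'
#' Builds exact binary masks for a spec: the whole spheroid (ball of
#' `core_radius + shell_thickness`), the shell-channel mask (voxels at
#' radial distance in `(core_radius, core_radius + shell_thickness]` whose
#' direction lies outside the uncovered cap), and the true core mask.
#' Deterministic: no randomness is involved.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `whole`, `shell`, `core` ([binary_mask()]s)
#'   and `truth` (ground-truth list: radii, thickness, coverage percent,
#'   cap half-angle, centre).
#' @export
render_geometry_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  r <- radial_distance_field(d, spec$spacing, spec$center)
  outer_radius <- spec$core_radius + spec$shell_thickness
  whole <- r <= outer_radius
  core <- r <= spec$core_radius
  ring <- r > spec$core_radius & whole
  alpha <- cap_half_angle(spec$coverage_fraction)
  if (alpha > 0 && spec$shell_thickness > 0) {
    cosang <- radial_cos_to_axis(d, spec$spacing, spec$center, spec$cap_axis,
                                 r = r)
    shell <- ring & (cosang < cos(alpha))
  } else if (spec$shell_thickness == 0) {
    shell <- array(FALSE, d)
  } else {
    shell <- ring
  }
  truth <- list(
    core_radius = spec$core_radius,
    shell_thickness = spec$shell_thickness,
    outer_radius = outer_radius,
    coverage_percent = 100 * spec$coverage_fraction,
    cap_half_angle = alpha,
    cap_axis = spec$cap_axis,
    center = spec$center
  )
  list(whole = binary_mask(whole, spec$spacing),
       shell = binary_mask(shell, spec$spacing),
       core = binary_mask(core, spec$spacing),
       truth = truth)
}

#' Render a two-channel image phantom with ground truth
#'
#' Places non-overlapping ellipsoidal nuclei in the core and in the covered
#' shell, renders a nuclear channel (nuclei at full intensity over a 5%
#' background offset) and a shell channel (shell volume positive per voxel
#' at `shell_label_purity`, core volume at `core_contamination`), then
#' applies Gaussian blur (`psf_sigma`) followed by the noise model. All
#' randomness is driven by `rng_seed`; identical specs give bit-identical
#' stacks.
#'
#' @param spec a [phantom_spec()].
#' @return list with `stack` (a [voxel_stack()]) and `truth`, a ground-truth
#'   list holding the geometry, nucleus table (centres, semi-axes, analytic
#'   volumes, compartment), realized shell/core positive fractions and the
#'   raw boolean shell-channel label array (`shell_label`).
#' @export
render_image_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- render_geometry_phantom(spec)
  d <- spec$grid_shape
  set.seed(spec$rng_seed)

  nuclei <- place_nuclei(spec, geom)
  nuclear_ind <- render_nuclei_indicator(spec, nuclei)

  # per-voxel shell-channel labels
  shell_label <- array(FALSE, d)
  ns <- sum(geom$shell$data)
  if (ns > 0 && spec$shell_label_purity > 0) {
    shell_label[geom$shell$data] <- runif(ns) < spec$shell_label_purity
  }
  nc <- sum(geom$core$data)
  if (nc > 0 && spec$core_contamination > 0) {
    shell_label[geom$core$data] <- runif(nc) < spec$core_contamination
  }

  background <- 0.05  # fixed background offset, 5% of dynamic range
  nuclear <- background + (1 - background) * nuclear_ind
  shellch <- background + (1 - background) * shell_label

  if (spec$psf_sigma > 0) {
    nuclear <- smooth_volume(nuclear, spec$psf_sigma, spec$spacing)
    shellch <- smooth_volume(shellch, spec$psf_sigma, spec$spacing)
  }
  nm <- spec$noise_model
  if (nm$type == "gaussian") {
    nuclear <- nuclear + rnorm(length(nuclear), sd = nm$sd)
    shellch <- shellch + rnorm(length(shellch), sd = nm$sd)
  } else if (nm$type == "poisson") {
    nuclear <- array(rpois(length(nuclear), nm$scale * pmax(nuclear, 0)) /
                       nm$scale, d)
    shellch <- array(rpois(length(shellch), nm$scale * pmax(shellch, 0)) /
                       nm$scale, d)
  }
  nuclear <- array(pmax(nuclear, 0), d)
  shellch <- array(pmax(shellch, 0), d)

  realized_shell <- if (ns > 0) sum(shell_label & geom$shell$data) / ns
                    else NA_real_
  realized_core <- if (nc > 0) sum(shell_label & geom$core$data) / nc
                   else NA_real_
  truth <- c(geom$truth, list(
    n_core_nuclei = sum(nuclei$compartment == "core"),
    n_shell_nuclei = sum(nuclei$compartment == "shell"),
    nuclei = nuclei,
    shell_label_purity = spec$shell_label_purity,
    core_contamination = spec$core_contamination,
    realized_shell_fraction = realized_shell,
    realized_core_fraction = realized_core,
    shell_label = shell_label
  ))
  stack <- voxel_stack(nuclear, shellch, spec$spacing,
                       metadata = list(phantom_seed = spec$rng_seed))
  list(stack = stack, truth = truth)
}

# ---- internals --------------------------------------------------------------

# truncated normal on [max(0.5, mean - 2 sd), mean + 2 sd]
draw_semi_axes <- function(n, mean, sd) {
  lo <- max(0.5, mean - 2 * sd)
  hi <- mean + 2 * sd
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    cand <- rnorm(n, mean, sd)
    ok <- cand >= lo & cand <= hi
    take <- min(sum(ok), n - filled)
    if (take > 0) {
      out[(filled + 1):(filled + take)] <- cand[ok][seq_len(take)]
      filled <- filled + take
    }
  }
  out
}

# Rejection-place non-overlapping ellipsoids; overlap is excluded via
# bounding spheres separated by a 2-voxel gap (keeps nuclei watershed- and
# component-separable on the rendered grid).
place_nuclei <- function(spec, geom) {
  n_total <- spec$n_core_nuclei + spec$n_shell_nuclei
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      a = numeric(0), b = numeric(0), c = numeric(0),
                      volume = numeric(0), compartment = character(0),
                      stringsAsFactors = FALSE)
  if (n_total == 0L) return(empty)
  gap <- 2 * min(spec$spacing)
  alpha <- cap_half_angle(spec$coverage_fraction)
  centers <- matrix(numeric(0), ncol = 3)
  rmax_placed <- numeric(0)
  rows <- vector("list", n_total)
  compartment <- rep(c("core", "shell"),
                     c(spec$n_core_nuclei, spec$n_shell_nuclei))
  max_tries <- 5000L
  for (i in seq_len(n_total)) {
    axes <- sort(draw_semi_axes(3, spec$nucleus_radius_mean,
                                spec$nucleus_radius_sd))
    rmax <- axes[3]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      if (compartment[i] == "core") {
        rad_hi <- spec$core_radius - rmax
        if (rad_hi <= 0) break
        # uniform in ball of radius rad_hi
        repeat {
          p <- runif(3, -rad_hi, rad_hi)
          if (sum(p^2) <= rad_hi^2) break
        }
        pos <- spec$center + p
      } else {
        r_lo <- spec$core_radius + rmax
        r_hi <- spec$core_radius + spec$shell_thickness - rmax
        if (r_hi <= r_lo) break
        rad <- (runif(1, r_lo^3, r_hi^3))^(1 / 3)
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        # keep the nucleus clear of the uncovered cap
        ang_margin <- asin(min(1, rmax / rad))
        cos_to_cap <- sum(u * spec$cap_axis)
        if (alpha > 0 && cos_to_cap >= cos(alpha + ang_margin)) next
        pos <- spec$center + rad * u
      }
      if (nrow(centers) > 0) {
        dd <- sqrt(colSums((t(centers) - pos)^2))
        if (any(dd < rmax_placed + rmax + gap)) next
      }
      centers <- rbind(centers, pos)
      rmax_placed <- c(rmax_placed, rmax)
      rows[[i]] <- data.frame(
        x = pos[1], y = pos[2], z = pos[3],
        a = axes[1], b = axes[2], c = axes[3],
        volume = 4 / 3 * pi * prod(axes),
        compartment = compartment[i], stringsAsFactors = FALSE
      )
      placed <- TRUE
      break
    }
    if (!placed) {
      achieved <- sum(!vapply(rows, is.null, logical(1)))
      stop(sprintf(paste0(
        "could not place nucleus %d of %d without overlap after %d ",
        "attempts (achieved %d); reduce counts or nucleus size"),
        i, n_total, max_tries, achieved), call. = FALSE)
    }
  }
  do.call(rbind, rows)
}

render_nuclei_indicator <- function(spec, nuclei) {
  d <- spec$grid_shape
  ind <- array(0, d)
  if (nrow(nuclei) == 0L) return(ind)
  sp <- spec$spacing
  for (i in seq_len(nrow(nuclei))) {
    ctr <- c(nuclei$x[i], nuclei$y[i], nuclei$z[i])
    ax <- c(nuclei$a[i], nuclei$b[i], nuclei$c[i])
    lo <- pmax(1L, floor((ctr - ax) / sp) + 1L)
    hi <- pmin(d, ceiling((ctr + ax) / sp) + 1L)
    xs <- ((lo[1]:hi[1]) - 1) * sp[1]
    ys <- ((lo[2]:hi[2]) - 1) * sp[2]
    zs <- ((lo[3]:hi[3]) - 1) * sp[3]
    q <- outer(outer(((xs - ctr[1]) / ax[1])^2, ((ys - ctr[2]) / ax[2])^2,
                     "+"), ((zs - ctr[3]) / ax[3])^2, "+")
    sub <- ind[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sub[q <= 1] <- 1
    ind[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  }
  ind
}
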