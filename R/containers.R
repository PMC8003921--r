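# Core data containers. Arrays are column-major with dim = (nx, ny, nz) in
# (x, y, z) order; voxel (i, j, k) has its centre at physical position
# ((i-1)*sx, (j-1)*sy, (k-1)*sz) micrometres. All exported quantities are in
# micrometres (lengths), square micrometres (areas) or cubic micrometres
# (volumes).

#' Two-channel 3D intensity stack
#'
#' Container for a confocal z-stack with a nuclear channel (e.g. DAPI,
#' marking all nuclei) and a shell channel (e.g. a cytoplasmic far-red dye
#' marking shell-seeded cells), plus the physical voxel spacing.
#'
#' @param nuclear 3D numeric array of nuclear-channel intensities,
#'   dim = (nx, ny, nz) in (x, y, z) order.
#' @param shell 3D numeric array of shell-channel intensities; must share
#'   the nuclear channel's dimensions.
#' @param spacing numeric length-3, micrometres per voxel along (x, y, z).
#' @param metadata optional named list of acquisition metadata.
#' @return An object of class `voxel_stack`.
#' @export
voxel_stack <- function(nuclear, shell, spacing, metadata = list()) {
  nuclear <- as_volume(nuclear)
  shell <- as_volume(shell)
  if (!identical(dim(nuclear), dim(shell))) {
    stop("nuclear and shell channels must share dimensions", call. = FALSE)
  }
  spacing <- check_spacing(spacing)
  structure(
    list(nuclear = nuclear, shell = shell, spacing = spacing,
         metadata = metadata),
    class = "voxel_stack"
  )
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$nuclear)
  cat("<voxel_stack> ", paste(d, collapse = " x "),
      " voxels, spacing (", paste(signif(x$spacing, 4), collapse = ", "),
      ") um\n", sep = "")
  invisible(x)
}

#' Binary 3D mask with physical spacing
#'
#' @param data 3D logical (or coercible) array, dim = (nx, ny, nz).
#' @param spacing numeric length-3, micrometres per voxel along (x, y, z).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing) {
  data <- as_volume(data)
  storage.mode(data) <- "logical"
  spacing <- check_spacing(spacing)
  structure(list(data = data, spacing = spacing), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat("<binary_mask> ", paste(d, collapse = " x "), " voxels, ",
      sum(x$data), " foreground (",
      signif(mask_volume(x), 4), " um^3)\n", sep = "")
  invisible(x)
}

#' Labelled nuclei volume
#'
#' Integer label grid produced by the seeded watershed (0 = background),
#' with per-label physical volumes. The watershed seeds used to generate the
#' labels are retained so that a refinement pass can drop and re-flood them.
#'
#' @param labels 3D integer array of nucleus labels (0 = background).
#' @param spacing numeric length-3, micrometres per voxel along (x, y, z).
#' @param seeds optional 3D integer array of the seed markers that produced
#'   the labels.
#' @return An object of class `label_volume` with fields `labels`, `spacing`,
#'   `volumes` (named per-label physical volumes, um^3) and `seeds`.
#' @export
label_volume <- function(labels, spacing, seeds = NULL) {
  labels <- as_volume(labels)
  storage.mode(labels) <- "integer"
  spacing <- check_spacing(spacing)
  nlab <- max(labels, 0L)
  counts <- if (nlab > 0L) tabulate(labels[labels > 0L], nbins = nlab)
            else integer(0)
  volumes <- counts * prod(spacing)
  if (nlab > 0L) names(volumes) <- seq_len(nlab)
  structure(
    list(labels = labels, spacing = spacing, volumes = volumes,
         seeds = seeds),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", length(x$volumes), " labels, median volume ",
      signif(if (length(x$volumes)) median(x$volumes) else NA_real_, 4),
      " um^3\n", sep = "")
  invisible(x)
}

#' Number of labels in a label volume
#' @param labels a [label_volume()].
#' @return integer count of distinct positive labels.
#' @export
n_labels <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  length(labels$volumes)
}

#' Physical volume of a binary mask
#' @param mask a [binary_mask()].
#' @return foreground volume in cubic micrometres.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * prod(mask$spacing)
}

# ---- internal helpers -------------------------------------------------------

as_volume <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 3L) {
    stop("expected a 3D array", call. = FALSE)
  }
  x
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive finite values (um)",
         call. = FALSE)
  }
  spacing
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) {
    stop("masks must share the same grid dimensions", call. = FALSE)
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-9) {
    stop("masks must share the same voxel spacing", call. = FALSE)
  }
  invisible(TRUE)
}

# physical coordinates (um) of voxel centres along each axis
axis_coords <- function(dim, spacing) {
  lapply(1:3, function(a) (seq_len(dim[a]) - 1) * spacing[a])
}

# squared distance field from `center` (physical um) over the grid
radial_distance_field <- function(dim, spacing, center) {
  cc <- axis_coords(dim, spacing)
  dx2 <- (cc[[1]] - center[1])^2
  dy2 <- (cc[[2]] - center[2])^2
  dz2 <- (cc[[3]] - center[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  sqrt(r2)
}

# per-voxel cosine of the angle between (voxel - center) and unit axis `u`;
# the value at the centre voxel itself (r = 0) is set to -1 (never "in cap").
radial_cos_to_axis <- function(dim, spacing, center, u, r = NULL) {
  cc <- axis_coords(dim, spacing)
  px <- (cc[[1]] - center[1]) * u[1]
  py <- (cc[[2]] - center[2]) * u[2]
  pz <- (cc[[3]] - center[3]) * u[3]
  dotp <- outer(outer(px, py, "+"), pz, "+")
  if (is.null(r)) r <- radial_distance_field(dim, spacing, center)
  cosang <- ifelse(r > 0, dotp / pmax(r, .Machine$double.eps), -1)
  cosang
}
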