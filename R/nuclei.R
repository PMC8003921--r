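# Nuclei separation: H-minima-stabilised seeds on the Euclidean distance
# transform, seeded watershed flooding, and a single refinement pass that
# drops seeds producing under-sized objects.

#' Generate watershed seeds from a nuclear mask
#'
#' Computes the Euclidean distance-to-background transform of the mask in
#' physical units (anisotropy-aware), negates it, suppresses local minima
#' shallower than `h` (H-minima transform, implemented by grayscale
#' reconstruction), and returns the connected regional-minima plateaus as
#' integer seed markers. Every seed lies inside the mask; an empty mask
#' yields zero seeds.
#'
#' @param mask a [binary_mask()] of the nuclear channel.
#' @param h H-minima depth in micrometres (default 1). Larger values merge
#'   shallow split points; `h` greater than the largest inscribed radius
#'   suppresses all seeds.
#' @return A [label_volume()] whose labels are the seed markers (and whose
#'   `seeds` field is the marker grid itself).
#' @export
make_seeds <- function(mask, h = 1) {
  stopifnot(inherits(mask, "binary_mask"))
  if (h < 0) stop("h must be >= 0", call. = FALSE)
  d <- dim(mask$data)
  if (!any(mask$data)) {
    z <- array(0L, d)
    return(label_volume(z, mask$spacing, seeds = z))
  }
  dist <- cpp_edt(as.logical(mask$data), d, mask$spacing)
  if (h > 0) {
    # h-minima of -dist == -(reconstruction-by-dilation of dist - h under
    # dist); its regional minima are the regional maxima of the
    # reconstruction, computed within the mask only
    rec <- cpp_reconstruct_dilation(dist - h, dist, as.logical(mask$data),
                                    d, 26L)
  } else {
    rec <- dist
  }
  seeds <- cpp_regional_maxima(rec, as.logical(mask$data), d, 26L)
  if (h > 0) {
    # the background sits at distance 0, so a peak whose reconstructed
    # height M - h is not above 0 is shallower than h relative to the
    # background basin and is suppressed entirely
    idx <- which(seeds > 0L)
    if (length(idx)) {
      peak <- tapply(rec[idx], seeds[idx], max)
      bad <- as.integer(names(peak))[peak <= 0]
      if (length(bad)) {
        seeds[seeds %in% bad] <- 0L
        keep <- sort(unique(seeds[seeds > 0L]))
        if (length(keep)) {
          remap <- integer(max(keep))
          remap[keep] <- seq_along(keep)
          seeds[seeds > 0L] <- remap[seeds[seeds > 0L]]
        }
      }
    }
  }
  seeds <- array(seeds, d)
  label_volume(seeds, mask$spacing, seeds = seeds)
}

#' Seeded watershed on the distance transform
#'
#' Floods the negated Euclidean distance transform from the imposed seed
#' markers: basins grow outward from the deepest (most interior) voxels, so
#' every mask voxel is assigned to exactly one seed's catchment basin and
#' background stays 0. Flooding order ties are broken first-in-first-out in
#' lexicographic voxel scan order, so the labelling is bit-reproducible.
#'
#' @param mask a [binary_mask()].
#' @param seeds a [label_volume()] from [make_seeds()], or an integer array
#'   of seed markers.
#' @return A [label_volume()] (with the seeds retained for refinement).
#' @export
seeded_watershed <- function(mask, seeds) {
  stopifnot(inherits(mask, "binary_mask"))
  seed_grid <- if (inherits(seeds, "label_volume")) seeds$labels else seeds
  seed_grid <- as_volume(seed_grid)
  storage.mode(seed_grid) <- "integer"
  if (!identical(dim(seed_grid), dim(mask$data))) {
    stop("seeds and mask must share dimensions", call. = FALSE)
  }
  if (!any(seed_grid > 0L & mask$data)) {
    stop("no seeds inside the mask; lower the H-minima depth h",
         call. = FALSE)
  }
  d <- dim(mask$data)
  dist <- cpp_edt(as.logical(mask$data), d, mask$spacing)
  lab <- cpp_watershed(as.logical(mask$data), dist, as.integer(seed_grid),
                       d, 26L)
  label_volume(array(lab, d), mask$spacing, seeds = seed_grid)
}

#' Second-pass watershed refinement
#'
#' Limits over-segmentation: removes the seeds of labels whose volume is
#' below `fraction` of the median label volume and re-runs the seeded
#' watershed with the surviving seeds, so the dropped labels' territory is
#' redistributed to their neighbours. If no label is under-sized the input
#' is returned unchanged. Exactly one refinement pass is performed.
#'
#' @param labels a [label_volume()] produced by [seeded_watershed()] (its
#'   `seeds` field must be present).
#' @param mask the [binary_mask()] the labels were derived from.
#' @param fraction volume threshold as a fraction of the median label
#'   volume (default 0.70).
#' @return A [label_volume()] with contiguously renumbered labels.
#' @export
refine_watershed <- function(labels, mask, fraction = 0.70) {
  stopifnot(inherits(labels, "label_volume"), inherits(mask, "binary_mask"))
  if (is.null(labels$seeds)) {
    stop("labels carry no seeds; run seeded_watershed() first",
         call. = FALSE)
  }
  vols <- labels$volumes
  if (length(vols) <= 1L) return(labels)
  threshold <- fraction * median(vols)
  drop <- which(vols < threshold)
  if (length(drop) == 0L) return(labels)
  if (length(drop) == length(vols)) {
    warning("all seeds fall below the volume threshold; ",
            "keeping the largest label's seed")
    drop <- setdiff(drop, which.max(vols))
  }
  seed_grid <- labels$seeds
  seed_grid[seed_grid %in% drop] <- 0L
  # renumber surviving seeds contiguously
  keep <- sort(unique(seed_grid[seed_grid > 0L]))
  remap <- integer(max(keep))
  remap[keep] <- seq_along(keep)
  seed_grid[seed_grid > 0L] <- remap[seed_grid[seed_grid > 0L]]
  seeded_watershed(mask, seed_grid)
}

#' Median single-nucleus volume
#'
#' @param labels a [label_volume()].
#' @return Median of the per-label physical volumes, in cubic micrometres.
#' @export
median_nucleus_volume <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  if (length(labels$volumes) == 0L) {
    stop("empty labelling: no nuclei to take a median over", call. = FALSE)
  }
  median(labels$volumes)
}

#' Per-nucleus summary table
#'
#' @param labels a [label_volume()].
#' @return data.frame with one row per nucleus: label, volume (um^3) and
#'   centroid in physical coordinates.
#' @export
nucleus_table <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  nlab <- length(labels$volumes)
  if (nlab == 0L) {
    return(data.frame(label = integer(0), volume = numeric(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)))
  }
  d <- dim(labels$labels)
  idx <- which(labels$labels > 0L)
  lab <- labels$labels[idx]
  co <- arrayInd(idx, d)
  sp <- labels$spacing
  data.frame(
    label = seq_len(nlab),
    volume = as.numeric(labels$volumes),
    x = as.numeric(tapply((co[, 1] - 1) * sp[1], lab, mean)),
    y = as.numeric(tapply((co[, 2] - 1) * sp[2], lab, mean)),
    z = as.numeric(tapply((co[, 3] - 1) * sp[3], lab, mean))
  )
}
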