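# Stack and mask I/O. Reading understands OME-TIFF (physical voxel size and
# channel layout from the OME-XML ImageDescription) as well as plain TIFF
# accompanied by a JSON sidecar or explicit arguments. Writing emits
# multi-page 32-bit float TIFF plus a JSON sidecar (spacing, channel order,
# slice count), since the underlying TIFF writer cannot embed OME-XML.

#' Read a two-channel z-stack from TIFF/OME-TIFF
#'
#' Voxel spacing is resolved in priority order: explicit `spacing` argument,
#' OME-XML `PhysicalSizeX/Y/Z` in the ImageDescription, then a JSON sidecar
#' (`<path>.json`) written by [write_stack()]. Reading fails loudly if no
#' spacing source is available. Channel layout for OME stacks follows
#' `SizeZ`/`SizeC` and `DimensionOrder`; plain stacks are assumed
#' channel-major (all z of channel 1, then channel 2) unless the sidecar
#' says otherwise.
#'
#' @param path TIFF file path.
#' @param channels named integer vector mapping `nuclear` and `shell` to
#'   channel indices (default `c(nuclear = 1, shell = 2)`).
#' @param spacing optional numeric length-3 override, micrometres.
#' @return A [voxel_stack()].
#' @export
read_stack <- function(path, channels = c(nuclear = 1, shell = 2),
                       spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!all(c("nuclear", "shell") %in% names(channels))) {
    stop("channels must name 'nuclear' and 'shell' indices", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)
  desc <- attr(pages[[1]], "description")
  meta <- NULL
  if (!is.null(desc) && grepl("<OME", desc, fixed = TRUE)) {
    meta <- parse_ome_description(desc)
  }
  sidecar <- paste0(path, ".json")
  if (is.null(meta) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  if (is.null(spacing)) {
    if (is.null(meta) || is.null(meta$spacing) ||
        any(!is.finite(as.numeric(meta$spacing)))) {
      stop("no voxel spacing available: supply `spacing` or provide ",
           "OME-XML metadata / a JSON sidecar", call. = FALSE)
    }
    spacing <- as.numeric(meta$spacing)
  }
  size_c <- if (!is.null(meta$size_c)) as.integer(meta$size_c) else 2L
  if (size_c < max(channels)) {
    stop("stack has ", size_c, " channel(s); channel mapping needs ",
         max(channels), call. = FALSE)
  }
  if (n_pages %% size_c != 0L) {
    stop("page count ", n_pages, " is not divisible by channel count ",
         size_c, call. = FALSE)
  }
  size_z <- n_pages %/% size_c
  interleaved <- isTRUE(meta$channel_interleaved)
  get_channel <- function(ci) {
    page_idx <- if (interleaved) seq(ci, n_pages, by = size_c)
                else ((ci - 1) * size_z) + seq_len(size_z)
    slices <- lapply(pages[page_idx], function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]
      t(p)  # readTIFF returns [row = y, col = x]; store as [x, y]
    })
    array(unlist(slices, use.names = FALSE),
          dim = c(dim(slices[[1]]), size_z))
  }
  voxel_stack(get_channel(channels[["nuclear"]]),
              get_channel(channels[["shell"]]),
              spacing,
              metadata = list(path = path, size_c = size_c,
                              size_z = size_z))
}

#' Write a two-channel stack as float TIFF with a JSON sidecar
#'
#' Pages are channel-major (all z slices of the nuclear channel, then the
#' shell channel). Intensities are clamped to \[0, 1\] for the 32-bit float
#' TIFF encoding. The sidecar `<path>.json` records spacing, channel order
#' and slice count so [read_stack()] can round-trip the stack.
#'
#' @param stack a [voxel_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "voxel_stack"))
  d <- dim(stack$nuclear)
  to_pages <- function(vol) {
    lapply(seq_len(d[3]), function(k) t(pmin(pmax(vol[, , k], 0), 1)))
  }
  pages <- c(to_pages(stack$nuclear), to_pages(stack$shell))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(spacing = stack$spacing, size_c = 2L, size_z = d[3],
         channel_interleaved = FALSE,
         channel_order = c("nuclear", "shell")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a binary mask or label volume as TIFF
#'
#' Binary masks are written as 8-bit (0/255); label volumes as 16-bit
#' label / 65535 encoding (suitable for up to 65535 nuclei).
#'
#' @param x a [binary_mask()] or [label_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(x, path) {
  if (inherits(x, "binary_mask")) {
    d <- dim(x$data)
    pages <- lapply(seq_len(d[3]), function(k) t(x$data[, , k]) * 1.0)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none",
                    reduce = FALSE)
  } else if (inherits(x, "label_volume")) {
    d <- dim(x$labels)
    pages <- lapply(seq_len(d[3]), function(k) t(x$labels[, , k]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                    reduce = FALSE)
  } else {
    stop("x must be a binary_mask or label_volume", call. = FALSE)
  }
  invisible(path)
}

# Parse spacing and layout from an OME-XML ImageDescription. Uses
# local-name() XPath so any OME namespace version is accepted.
parse_ome_description <- function(desc) {
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, "//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  att <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  order <- xml2::xml_attr(px, "DimensionOrder")
  list(
    spacing = c(att("PhysicalSizeX"), att("PhysicalSizeY"),
                att("PhysicalSizeZ")),
    size_z = att("SizeZ"),
    size_c = att("SizeC"),
    # in an interleaved order C varies before Z (e.g. XYCZT)
    channel_interleaved = !is.na(order) &&
      regexpr("C", order) < regexpr("Z", order)
  )
}
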