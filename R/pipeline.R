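# Pipeline configuration and end-to-end orchestration: segmentation ->
# nuclei -> morphometry -> radial lines -> compartments, with a serialisable
# parameter set echoed into every report for provenance.

#' Pipeline configuration
#'
#' All tunable parameters of the analysis with their defaults. The defaults
#' assume isotropic ~0.45 um voxels after z-interpolation and nuclei of
#' roughly 4 um radius; both are configurable.
#'
#' @param target_z_spacing z-spacing after interpolation, um (default 0.45).
#' @param smooth_sigma Gaussian smoothing sigma, um (default 0.5;
#'   sub-nuclear, suppresses shot noise without merging nuclei).
#' @param threshold_divisor adaptive-threshold neighbourhood divisor
#'   (default 8: box side = stack dimension / 8 per axis).
#' @param threshold_sensitivity adaptive-threshold offset fraction
#'   (default 0).
#' @param nucleus_radius nominal nucleus radius, um (default 4); sets the
#'   default small-object filter.
#' @param min_object_volume minimum object volume, um^3; default half the
#'   volume of a sphere of `nucleus_radius`.
#' @param hmin_depth H-minima depth for watershed seeding, um (default 1).
#' @param refine_fraction second-pass watershed volume fraction
#'   (default 0.70).
#' @param whole_closing_radius closing radius for the whole-spheroid mask,
#'   um (default 5).
#' @param core_closing_radius closing radius for the core-shadow mask, um
#'   (default 6).
#' @param layer_width concentric layer width, um (default 5).
#' @param n_surface_points number of centre-to-surface lines (default 5000).
#' @param azimuth_bin_width,polar_bin_width angular trend bin widths,
#'   radians (defaults pi/10 and pi/20).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(target_z_spacing = 0.45,
                            smooth_sigma = 0.5,
                            threshold_divisor = 8,
                            threshold_sensitivity = 0,
                            nucleus_radius = 4,
                            min_object_volume = NULL,
                            hmin_depth = 1,
                            refine_fraction = 0.70,
                            whole_closing_radius = 5,
                            core_closing_radius = 6,
                            layer_width = 5,
                            n_surface_points = 5000,
                            azimuth_bin_width = pi / 10,
                            polar_bin_width = pi / 20) {
  if (is.null(min_object_volume)) {
    min_object_volume <- 0.5 * (4 / 3) * pi * nucleus_radius^3
  }
  cfg <- list(
    target_z_spacing = target_z_spacing,
    smooth_sigma = smooth_sigma,
    threshold_divisor = threshold_divisor,
    threshold_sensitivity = threshold_sensitivity,
    nucleus_radius = nucleus_radius,
    min_object_volume = min_object_volume,
    hmin_depth = hmin_depth,
    refine_fraction = refine_fraction,
    whole_closing_radius = whole_closing_radius,
    core_closing_radius = core_closing_radius,
    layer_width = layer_width,
    n_surface_points = as.integer(n_surface_points),
    azimuth_bin_width = azimuth_bin_width,
    polar_bin_width = polar_bin_width
  )
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num) || any(vapply(cfg, function(v) any(!is.finite(v)),
                              logical(1)))) {
    stop("all configuration values must be finite numbers", call. = FALSE)
  }
  if (cfg$target_z_spacing <= 0 || cfg$smooth_sigma < 0 ||
      cfg$threshold_divisor < 1 || cfg$min_object_volume < 0 ||
      cfg$hmin_depth < 0 || cfg$refine_fraction < 0 ||
      cfg$refine_fraction > 1 || cfg$layer_width <= 0 ||
      cfg$n_surface_points < 1) {
    stop("configuration value out of range", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return [pipeline_config()] (for `read_config`) or `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Run the full core-shell spheroid analysis
#'
#' Executes, in order: z-interpolation to isotropic voxels, Gaussian
#' smoothing, adaptive thresholding of both channels, morphological cleanup
#' (hole filling on the nuclear mask; speckle removal without hole filling
#' on the shell mask, whose negative voxels between labelled cells are
#' genuine signal voids, not cavities), whole-volume construction, two-pass
#' watershed nuclei separation, morphometry, concentric-layer profiling,
#' centre-to-surface line analysis, angular trends, and core/shell
#' compartmentalisation. Shell-channel voxel fractions are measured on the
#' raw thresholded shell mask; line metrics use the speckle-filtered mask.
#'
#' @param stack a [voxel_stack()] or a TIFF path accepted by
#'   [read_stack()].
#' @param config a [pipeline_config()].
#' @param keep_volumes logical; retain masks and label volumes in the
#'   report (default FALSE to keep reports light).
#' @return list of class `spheroid_report`: `morphometry`, `cell_count`,
#'   `median_nucleus_volume`, `n_nuclei`, `farred_voxel_ratio`, `center`,
#'   `layers`, `line_summary`, `trend_azimuth`, `trend_polar`,
#'   `compartments`, `config`, `timings_s` and (optionally) `volumes`.
#' @export
run_pipeline <- function(stack, config = pipeline_config(),
                         keep_volumes = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot(inherits(stack, "voxel_stack"))
  timings <- c()
  tic <- function() Sys.time()
  lap <- function(t0, name) {
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  t0 <- tic()
  stack <- interpolate_isotropic(stack, config$target_z_spacing)
  smoothed <- gaussian_smooth(stack, config$smooth_sigma)
  lap(t0, "preprocess")

  t0 <- tic()
  dapi_raw <- adaptive_threshold(smoothed$nuclear, smoothed$spacing,
                                 config$threshold_divisor,
                                 config$threshold_sensitivity)
  farred_raw <- adaptive_threshold(smoothed$shell, smoothed$spacing,
                                   config$threshold_divisor,
                                   config$threshold_sensitivity)
  dapi_mask <- morphological_cleanup(dapi_raw, config$min_object_volume,
                                     fill_holes = TRUE)
  farred_clean <- morphological_cleanup(farred_raw, config$min_object_volume,
                                        fill_holes = FALSE)
  lap(t0, "segmentation")

  t0 <- tic()
  whole <- whole_volume_mask(dapi_mask, farred_clean,
                             config$whole_closing_radius)
  lap(t0, "whole_mask")

  t0 <- tic()
  seeds <- make_seeds(dapi_mask, config$hmin_depth)
  labels <- seeded_watershed(dapi_mask, seeds)
  labels <- refine_watershed(labels, dapi_mask, config$refine_fraction)
  med_vol <- median_nucleus_volume(labels)
  cells <- estimate_cell_count(dapi_mask, med_vol)
  lap(t0, "nuclei")

  t0 <- tic()
  morpho <- measure_morphometry(whole)
  fr_ratio <- farred_voxel_ratio(farred_raw, whole)
  lap(t0, "morphometry")

  t0 <- tic()
  center <- find_core_center(smoothed$nuclear, dapi_mask, farred_clean)
  layers <- concentric_layer_ratios(whole, farred_raw, center,
                                    config$layer_width)
  rl <- radial_line_analysis(whole, farred_clean, center,
                             config$n_surface_points)
  line_summary <- aggregate_lines(rl)
  tr_az <- angular_trend(rl, "azimuth", config$azimuth_bin_width)
  tr_po <- angular_trend(rl, "polar", config$polar_bin_width)
  lap(t0, "radial_lines")

  t0 <- tic()
  shadow <- core_shadow(rl)
  core_mask <- close_core_mask(shadow, whole, config$core_closing_radius)
  shell_mask <- shell_from_core(whole, core_mask)
  comp <- compartment_content(core_mask, shell_mask, farred_raw,
                              nuclei = labels,
                              median_nucleus_volume = med_vol)
  lap(t0, "compartments")

  report <- list(
    morphometry = morpho,
    cell_count = cells,
    median_nucleus_volume = med_vol,
    n_nuclei = n_labels(labels),
    farred_voxel_ratio = fr_ratio,
    center = center,
    layers = layers,
    line_summary = line_summary,
    trend_azimuth = tr_az,
    trend_polar = tr_po,
    compartments = comp,
    config = config,
    package_version = as.character(utils::packageVersion("coreshell")),
    timings_s = unlist(timings)
  )
  if (keep_volumes) {
    report$volumes <- list(
      dapi_mask = dapi_mask, farred_raw = farred_raw,
      farred_clean = farred_clean, whole = whole, labels = labels,
      core_mask = core_mask, shell_mask = shell_mask, lines = rl
    )
  }
  structure(report, class = "spheroid_report")
}

#' @export
print.spheroid_report <- function(x, ...) {
  cat("<spheroid_report>\n")
  cat("  volume      ", signif(x$morphometry$volume_um3, 4), "um^3\n")
  cat("  sphericity  ", signif(x$morphometry$sphericity, 3), "\n")
  cat("  cells       ", x$cell_count$count, "\n")
  cat("  coverage    ", signif(x$line_summary$coverage_percent, 4), "%\n")
  cat("  shell thick ", signif(x$line_summary$mean_shell_thickness, 4),
      "um\n")
  cat("  core radius ", signif(x$line_summary$mean_core_radius, 4), "um\n")
  invisible(x)
}

#' Write a report to disk
#'
#' Emits `summary.json` (scalar results and config), `lines.csv`,
#' `layers.csv`, `trend_azimuth.csv` and `trend_polar.csv` into `dir`.
#'
#' @param report a `spheroid_report`.
#' @param dir output directory (created if needed).
#' @param lines optional `radial_lines` object to dump per-line data (used
#'   when the report was built with `keep_volumes = TRUE` its copy is used
#'   automatically).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, lines = NULL) {
  stopifnot(inherits(report, "spheroid_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- list(
    morphometry = unclass(report$morphometry),
    cell_count = report$cell_count,
    median_nucleus_volume = report$median_nucleus_volume,
    n_nuclei = report$n_nuclei,
    farred_voxel_ratio = report$farred_voxel_ratio,
    center = as.list(report$center),
    line_summary = report$line_summary,
    compartments = unclass(report$compartments),
    config = unclass(report$config),
    package_version = report$package_version,
    timings_s = as.list(report$timings_s)
  )
  jsonlite::write_json(scalars, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$layers, file.path(dir, "layers.csv"),
                   row.names = FALSE)
  utils::write.csv(report$trend_azimuth,
                   file.path(dir, "trend_azimuth.csv"), row.names = FALSE)
  utils::write.csv(report$trend_polar, file.path(dir, "trend_polar.csv"),
                   row.names = FALSE)
  if (is.null(lines) && !is.null(report$volumes)) {
    lines <- report$volumes$lines
  }
  if (!is.null(lines)) {
    utils::write.csv(lines$lines, file.path(dir, "lines.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
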