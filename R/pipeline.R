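# Configuration-driven runner tying the stages into reproducible runs.
#
# A run is described by a single YAML (or list) configuration with
# per-stage sections.  Every stage writes a manifest recording the config,
# seed, package version and MD5 hashes of its outputs, sufficient to
# reproduce deterministic stages byte-for-byte.

.config_schema <- list(
  top = c("seed", "output_dir", "simulate", "preprocess", "fit", "report"),
  simulate = c("grid_shape", "voxel_size", "frame_time", "n_frames",
               "baseline", "A_true", "v_out_true", "c_out_true",
               "noise_sd", "onset", "duration", "v_in",
               "radial", "center", "radius", "peak_fap"),
  preprocess = c("steps", "temporal_window", "baseline_window", "fwhm"),
  fit = c("mode", "roi_center", "roi_extent", "A_grid", "n_starts",
          "v_in", "A_fixed"),
  report = c("r2_min", "alpha"))

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown config key%s in %s: %s",
                 if (length(bad) > 1) "s" else "", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' Load and validate a run configuration
#'
#' @param config A YAML file path or a named list.
#' @return The validated configuration list, classed `"run_config"`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  .check_keys(config, .config_schema$top, "top level")
  need <- c("seed", "output_dir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config missing required key: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (sec in c("simulate", "preprocess", "fit", "report")) {
    if (!is.null(config[[sec]]))
      .check_keys(config[[sec]], .config_schema[[sec]], sec)
  }
  structure(config, class = "run_config")
}

.write_manifest <- function(config, stage, files, dir) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("vasokin")),
    seed = config$seed,
    config = unclass(config),
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.phantom_from_config <- function(config) {
  sc <- config$simulate
  if (is.null(sc)) stop("config has no `simulate` section", call. = FALSE)
  inf <- if (isTRUE(sc$radial)) {
    list(pump_rate = 1, probe_conc = 100,
         site = sc$center, onset = sc$onset %||% 300,
         duration = sc$duration %||% 600)
  } else {
    infusion_schedule(sc$onset %||% 300, sc$duration %||% 600,
                      sc$v_in %||% 0.0108)
  }
  spec <- phantom_spec(
    grid_shape = sc$grid_shape %||% c(24, 24, 3),
    voxel_size = sc$voxel_size %||% c(0.39, 0.39, 1),
    frame_time = sc$frame_time %||% 4,
    n_frames = sc$n_frames %||% 450,
    baseline = sc$baseline %||% 100,
    A_true = sc$A_true %||% 20,
    v_out_true = sc$v_out_true %||% 0.3,
    c_out_true = sc$c_out_true %||% 1e-4,
    infusion = inf,
    noise_sd = sc$noise_sd %||% 0.5,
    seed = config$seed)
  if (!is.null(sc$peak_fap)) {
    spec <- make_fap_phantom(spec,
                             center = sc$center %||% round(spec$grid_shape / 2),
                             radius = sc$radius %||% 1,
                             peak_fap = sc$peak_fap)
  }
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulation stage of a configured analysis
#'
#' Generates the synthetic series described by the config's `simulate`
#' section and writes the raw series, the ground-truth k-map and delivery
#' map as NIfTI, and a manifest with the config and output hashes.
#'
#' @param config A [run_config()] (or path / list coercible to one).
#' @return Invisibly, a list with the output paths.
#' @export
run_simulate <- function(config) {
  config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- .phantom_from_config(config)
  series <- generate_image_series(spec)
  paths <- list(
    series = file.path(config$output_dir, "series.nii.gz"),
    k_map = file.path(config$output_dir, "k_truth.nii.gz"),
    vin_map = file.path(config$output_dir, "vin_map.nii.gz"))
  write_series_nifti(series, paths$series)
  kmap <- if (is.null(spec$k_map)) array(0, spec$grid_shape) else spec$k_map
  write_map_nifti(kmap, paths$k_map, spec$voxel_size)
  write_map_nifti(series$vin_map, paths$vin_map, spec$voxel_size)
  all_files <- c(unlist(paths),
                 file.path(config$output_dir, "series_mask.nii.gz"))
  paths$manifest <- .write_manifest(config, "simulate", all_files,
                                    config$output_dir)
  invisible(paths)
}

#' Run the preprocessing and fitting stage of a configured analysis
#'
#' Reads the simulated (or supplied) series from the run's output
#' directory, preprocesses it, and fits either an ROI-level model or
#' voxel-wise maps according to the config's `fit` section (`mode` one of
#' `"roi"` or `"voxel"`).  Results are written as JSON (ROI) or NIfTI maps
#' plus JSON summary (voxel), with v_in provenance recorded.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fit result object and output paths.
#' @export
run_fit <- function(config) {
  config <- run_config(config)
  dir <- config$output_dir
  series_path <- file.path(dir, "series.nii.gz")
  if (!file.exists(series_path))
    stop("no series found in output_dir; run run_simulate() first",
         call. = FALSE)
  series <- read_series_nifti(series_path)
  if (is.null(series$onset))
    series$onset <- (config$simulate %||% list())$onset %||% 300
  pc <- config$preprocess %||% list()
  pre <- preprocess_series(
    series,
    steps = pc$steps %||% c("global_normalize", "temporal_smooth",
                            "percent_signal_change", "spatial_smooth"),
    temporal_window = pc$temporal_window %||% 60,
    baseline_window = pc$baseline_window %||% 60,
    fwhm = pc$fwhm %||% 1)
  fc <- config$fit %||% list()
  sc <- config$simulate %||% list()
  schedule <- infusion_schedule(sc$onset %||% 300, sc$duration %||% 600,
                                fc$v_in %||% sc$v_in %||% 0.0108)
  vin_path <- file.path(dir, "vin_map.nii.gz")
  vin <- if (file.exists(vin_path)) read_map_nifti(vin_path) else schedule$v_in
  vin_model <- if (is.array(vin)) "radial_map" else "point"
  mode <- fc$mode %||% "roi"
  paths <- list()
  if (mode == "roi") {
    ctr <- fc$roi_center %||% round(dim(pre$data)[1:3] / 2)
    roi <- roi_spec(ctr, fc$roi_extent %||% c(1.2, 1.2))
    tc <- roi_timecourse(pre, roi)
    v_in_roi <- if (is.array(vin)) {
      ix <- .roi_indices(pre, roi)
      mean(vin[ix$x, ix$y, ix$z])
    } else vin
    fit <- fit_roi(tc, v_in = v_in_roi, schedule = schedule,
                   A_fixed = fc$A_fixed,
                   n_starts = fc$n_starts %||% 8)
    paths$fit <- file.path(dir, "roi_fit.json")
    jsonlite::write_json(list(
      coefficients = as.list(coef(fit)), r_squared = fit$r.squared,
      converged = fit$converged, v_in = v_in_roi,
      v_in_model = vin_model), paths$fit, auto_unbox = TRUE, digits = NA)
  } else if (mode == "voxel") {
    fit <- fit_voxelwise(pre, v_in = vin, schedule = schedule,
                         A_grid = fc$A_grid %||% seq(0, 40, by = 1),
                         n_starts = fc$n_starts %||% 4)
    paths$k_map <- file.path(dir, "k_fit.nii.gz")
    paths$r2_map <- file.path(dir, "r2_fit.nii.gz")
    write_map_nifti(fit$k_map, paths$k_map, pre$voxel_size)
    write_map_nifti(fit$r2_map, paths$r2_map, pre$voxel_size)
    paths$fit <- file.path(dir, "voxel_fit.json")
    jsonlite::write_json(list(
      A_global = fit$A_global, n_voxels = fit$n_voxels,
      v_in_model = vin_model,
      k_median = stats::median(fit$k_map, na.rm = TRUE)),
      paths$fit, auto_unbox = TRUE, digits = NA)
  } else stop("unknown fit mode: ", mode, call. = FALSE)
  paths$manifest <- .write_manifest(config, "fit",
                                    unlist(paths[names(paths) != "manifest"]),
                                    dir)
  invisible(list(fit = fit, paths = paths))
}

#' Run the reporting stage of a configured analysis
#'
#' Summarizes fit artifacts present in the run's output directory into a
#' CSV table, including the conversion of fitted rates to equivalent
#' enzyme concentrations, and a plain-text summary.
#'
#' @param config A [run_config()].
#' @param enz [enzyme_constants()] for rate-to-concentration conversion.
#' @return Invisibly, the summary data frame.
#' @export
run_report <- function(config, enz = enzyme_constants()) {
  config <- run_config(config)
  dir <- config$output_dir
  rc <- config$report %||% list()
  roi_path <- file.path(dir, "roi_fit.json")
  kmap_path <- file.path(dir, "k_fit.nii.gz")
  rows <- list()
  if (file.exists(roi_path)) {
    fit <- jsonlite::read_json(roi_path, simplifyVector = TRUE)
    rows[["roi"]] <- data.frame(
      level = "roi", k = fit$coefficients$k,
      fap_equiv_nM = fap_from_rate(fit$coefficients$k, enz),
      A = fit$coefficients$A, r_squared = fit$r_squared,
      n_significant = NA_integer_)
  }
  if (file.exists(kmap_path)) {
    kmap <- read_map_nifti(kmap_path)
    r2map <- read_map_nifti(file.path(dir, "r2_fit.nii.gz"))
    good <- !is.na(kmap) & !is.na(r2map) & r2map >= (rc$r2_min %||% 0.9)
    kmed <- stats::median(kmap[good])
    rows[["voxel"]] <- data.frame(
      level = "voxel", k = kmed, fap_equiv_nM = fap_from_rate(kmed, enz),
      A = NA_real_, r_squared = stats::median(r2map[good]),
      n_significant = NA_integer_)
  }
  if (!length(rows))
    stop("no fit artifacts found in output_dir; run run_fit() first",
         call. = FALSE)
  out <- do.call(rbind, rows)
  path <- file.path(dir, "report.csv")
  utils::write.csv(out, path, row.names = FALSE)
  .write_manifest(config, "report", path, dir)
  invisible(out)
}
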