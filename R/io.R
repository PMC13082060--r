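#' Write an image stack or activity movie as TIFF plus JSON sidecar
#'
#' Writes a 16-bit multi-page TIFF (`<prefix>.tif`) and a JSON sidecar
#' (`<prefix>.json`) carrying the metadata that TIFF does not:
#' `pixel_size_um`, `z_positions_um`, `pulses_per_pixel` and `channel` for
#' stacks; `frame_rate_hz`, `pixel_size_um` and `depth_um` for movies.
#'
#' @param x An [image_stack()] or [activity_movie()].
#' @param prefix Output path without extension.
#' @return Invisibly, the two file paths.
#' @export
write_tiff_sidecar <- function(x, prefix) {
  arr <- if (inherits(x, "image_stack")) x$voxels
         else if (inherits(x, "activity_movie")) x$frames
         else stop("x must be an image_stack or activity_movie")
  if (max(arr) > 65535) stop("counts exceed 16-bit TIFF range")
  pages <- lapply(seq_len(dim(arr)[1]), function(k) arr[k, , ] / 65535)
  tif <- paste0(prefix, ".tif")
  json <- paste0(prefix, ".json")
  tiff::writeTIFF(pages, tif, bits.per.sample = 16, compression = "none")
  meta <- if (inherits(x, "image_stack")) {
    list(kind = "image_stack", pixel_size_um = x$pixel_size_um,
         z_positions_um = x$z_positions_um, channel = x$channel,
         pulses_per_pixel = x$pulses_per_pixel)
  } else {
    list(kind = "activity_movie", frame_rate_hz = x$frame_rate_hz,
         pixel_size_um = x$pixel_size_um, depth_um = x$depth_um)
  }
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, json))
}

#' Read a TIFF + JSON sidecar pair
#'
#' Reconstructs the object written by [write_tiff_sidecar()]; the sidecar's
#' `kind` field selects the container.
#'
#' @param prefix Path without extension (as passed to the writer), or the
#'   `.tif` path itself.
#' @return An [image_stack()] or [activity_movie()].
#' @export
read_tiff_sidecar <- function(prefix) {
  prefix <- sub("\\.tif$", "", prefix)
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE, as.is = TRUE)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  arr <- array(0, dim = c(length(pages), dim(pages[[1]])))
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
  if (identical(meta$kind, "image_stack")) {
    image_stack(arr, meta$pixel_size_um, meta$z_positions_um,
                channel = meta$channel %||% "",
                pulses_per_pixel = meta$pulses_per_pixel %||% 1)
  } else if (identical(meta$kind, "activity_movie")) {
    activity_movie(arr, meta$frame_rate_hz,
                   pixel_size_um = meta$pixel_size_um %||% NA_real_,
                   depth_um = meta$depth_um %||% NA_real_)
  } else stop("sidecar does not identify a known container kind")
}

#' Write ROIs to CSV
#'
#' One row per coordinate with columns `label`, `slice`, `kind`, `row`,
#' `col`; coordinates and slice indices are 0-based.
#'
#' @param rois List of [roi()] objects.
#' @param path Output CSV path.
#' @export
write_rois_csv <- function(rois, path) {
  rows <- do.call(rbind, lapply(rois, function(r) {
    data.frame(label = r$label, slice = r$slice_index, kind = r$kind,
               row = r$coordinates[, 1], col = r$coordinates[, 2],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read ROIs from CSV
#'
#' Inverse of [write_rois_csv()]; rows sharing a label/slice/kind triple form
#' one ROI, in file order.
#'
#' @param path CSV path.
#' @return List of [roi()] objects.
#' @export
read_rois_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "slice", "kind", "row", "col")
  if (!all(need %in% names(df))) {
    stop("ROI CSV must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(df$label, df$slice, df$kind, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    roi(g$kind[1], cbind(g$row, g$col), slice_index = g$slice[1],
        label = g$label[1])
  }) |> unname()
}

.config_schema <- list(
  laser = c("f_hz", "tau_s", "psurface_mw", "esurface_nj", "wavelength_nm"),
  tissue = c("layers", "depth_factor"),
  collection = c("geometries"),
  kinetics = c("dff", "t12_s", "tau_1e_s"),
  pipeline = c("time_constant_s", "baseline_fraction", "min_rate",
               "discard_initial_s"),
  paths = c("stack", "movie", "rois", "calibration", "out_dir"))

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration with sections `laser`, `tissue`,
#' `collection`, `kinetics`, `pipeline` and `paths`; unknown sections or keys
#' are rejected by name. Returns constructed package objects alongside the
#' raw values.
#'
#' @param path Configuration file path.
#' @return List with `laser` ([laser_config()] or NULL), `tissue`
#'   ([tissue_optics_model()]), `collection` (named list of
#'   [collection_geometry()]), `kinetics` ([indicator_kinetics()]),
#'   `pipeline` (parameter list), `paths`, and `raw`.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), names(.config_schema))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(cfg)) {
    if (sec == "collection") next
    extra <- setdiff(names(cfg[[sec]]), .config_schema[[sec]])
    if (length(extra)) {
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(extra, collapse = ", ")))
    }
  }
  # YAML 1.1 reads exponent literals without a sign ("1.0e5") as strings;
  # numeric fields are coerced so either spelling works
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  laser <- if (!is.null(cfg$laser)) {
    laser_config(num(cfg$laser$f_hz), num(cfg$laser$esurface_nj),
                 pulse_width_tau_s = num(cfg$laser$tau_s) %||% 60e-15,
                 surface_power_psurface_mw = num(cfg$laser$psurface_mw),
                 wavelength_nm = num(cfg$laser$wavelength_nm) %||% 1300)
  }
  tissue <- if (!is.null(cfg$tissue)) {
    layers <- do.call(rbind, lapply(cfg$tissue$layers, function(l) {
      extra <- setdiff(names(l), c("thickness_um", "eal_um"))
      if (length(extra)) stop("unknown key(s) in tissue layer: ",
                              paste(extra, collapse = ", "))
      data.frame(thickness_um = as.numeric(l$thickness_um),
                 eal_um = as.numeric(l$eal_um))
    }))
    tissue_optics_model(layers, num(cfg$tissue$depth_factor) %||% 1.075)
  } else tissue_optics_model()
  collection <- if (!is.null(cfg$collection)) {
    geoms <- lapply(cfg$collection$geometries, function(g) {
      extra <- setdiff(names(g), c("name", "collection_na",
                                   "collection_fov_mm", "scan_fov_mm"))
      if (length(extra)) stop("unknown key(s) in collection geometry: ",
                              paste(extra, collapse = ", "))
      collection_geometry(num(g$collection_na), num(g$collection_fov_mm),
                          num(g$scan_fov_mm) %||% 0, g$name %||% "")
    })
    names(geoms) <- vapply(geoms, function(g) g$name, character(1))
    geoms
  } else list()
  kinetics <- if (!is.null(cfg$kinetics)) {
    indicator_kinetics(num(cfg$kinetics$dff) %||% 0.7,
                       half_life_t12_s = num(cfg$kinetics$t12_s),
                       tau_1e_s = num(cfg$kinetics$tau_1e_s) %||%
                         (if (is.null(cfg$kinetics$t12_s)) 0.29))
  } else indicator_kinetics()
  pipeline <- utils::modifyList(
    list(time_constant_s = 0.29, baseline_fraction = 0.20, min_rate = 150,
         discard_initial_s = 0),
    cfg$pipeline %||% list())
  list(laser = laser, tissue = tissue, collection = collection,
       kinetics = kinetics, pipeline = pipeline,
       paths = cfg$paths %||% list(), raw = cfg)
}
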