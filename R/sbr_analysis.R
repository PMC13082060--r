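#' Three-dimensional photon-count image stack
#'
#' @param voxels 3-D integer-valued array indexed `(z, y, x)`, photon counts
#'   per pixel, `>= 0`.
#' @param pixel_size_um Lateral pixel size (um).
#' @param z_positions_um Strictly increasing slice depths (um), one per
#'   z-plane, surface first.
#' @param channel Channel label.
#' @param pulses_per_pixel Laser pulses per pixel dwell, for photons-per-pulse
#'   conversion.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size_um, z_positions_um, channel = "",
                        pulses_per_pixel = 1) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (any(voxels < 0)) stop("photon counts must be >= 0")
  if (length(z_positions_um) != dim(voxels)[1]) {
    stop("z_positions_um must match the number of slices")
  }
  if (any(diff(z_positions_um) <= 0)) {
    stop("z_positions_um must be strictly increasing")
  }
  if (pixel_size_um <= 0 || pulses_per_pixel <= 0) {
    stop("pixel_size_um and pulses_per_pixel must be > 0")
  }
  structure(list(voxels = voxels, pixel_size_um = pixel_size_um,
                 z_positions_um = z_positions_um, channel = channel,
                 pulses_per_pixel = pulses_per_pixel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d slices of %d x %d px, z %g..%g um%s\n",
              d[1], d[2], d[3], min(x$z_positions_um), max(x$z_positions_um),
              if (nzchar(x$channel)) paste0(", channel ", x$channel) else ""))
  invisible(x)
}

#' Pixel-value to photon-count calibration
#'
#' @param conversion_factor Photons per pixel-intensity unit, `> 0`.
#' @param linear_range_max Largest pixel value for which the detector
#'   response was validated linear.
#' @return Object of class `photon_calibration`.
#' @export
photon_calibration <- function(conversion_factor, linear_range_max = Inf) {
  if (conversion_factor <= 0) stop("conversion_factor must be > 0")
  structure(list(conversion_factor = conversion_factor,
                 linear_range_max = linear_range_max),
            class = "photon_calibration")
}

#' Region of interest
#'
#' Coordinates are 0-based `(row, col)` pixel indices and the slice index is
#' 0-based as well, matching common image-tool export conventions; conversion
#' to R's 1-based indexing happens internally.
#'
#' @param kind `"mask"` (unordered pixel set) or `"polyline"` (ordered
#'   vertices of a line ROI).
#' @param coordinates 2-column matrix of 0-based `(row, col)` indices.
#' @param slice_index 0-based z-slice (or frame) index.
#' @param label ROI label.
#' @return Object of class `roi`.
#' @export
roi <- function(kind = c("mask", "polyline"), coordinates, slice_index = 0,
                label = "") {
  kind <- match.arg(kind)
  coordinates <- matrix(as.numeric(coordinates), ncol = 2)
  if (nrow(coordinates) == 0L) stop("ROI must contain at least one coordinate")
  if (any(coordinates < 0)) stop("ROI coordinates must be >= 0 (0-based)")
  if (kind == "polyline" && nrow(coordinates) < 2L) {
    stop("a polyline ROI needs at least two vertices")
  }
  structure(list(kind = kind, coordinates = coordinates,
                 slice_index = as.integer(slice_index), label = label),
            class = "roi")
}

# 1-based linear indices of an ROI's pixels within an ny x nx slice
.roi_pixel_index <- function(r, ny, nx) {
  rows <- r$coordinates[, 1] + 1
  cols <- r$coordinates[, 2] + 1
  if (any(rows > ny) || any(cols > nx)) stop("ROI coordinates outside image bounds")
  cbind(rows, cols)
}

#' Convert pixel intensities to photon counts
#'
#' Element-wise multiplication by the calibration conversion factor. Values
#' beyond the validated linear range are converted anyway but flagged via the
#' `"out_of_linear_range"` attribute (count of offending pixels).
#'
#' @param values Numeric array of pixel intensities.
#' @param cal A [photon_calibration()].
#' @return Photon counts, same shape; see Details for the linearity flag.
#' @export
pixels_to_photons <- function(values, cal) {
  stopifnot(inherits(cal, "photon_calibration"))
  out <- values * cal$conversion_factor
  n_bad <- sum(values > cal$linear_range_max)
  if (n_bad > 0) {
    warning(sprintf("%d pixel value(s) beyond the validated linear range", n_bad))
    attr(out, "out_of_linear_range") <- n_bad
  }
  out
}

#' Fit the photon conversion factor from paired measurements
#'
#' Zero-intercept least squares of photon counts on pixel values, mirroring
#' the bench calibration in which photon counting and imaging interrogate the
#' same sample across excitation powers. The validated linear range is the
#' largest pixel value whose residual stays within 10% of the fit.
#'
#' @param pixel_values Pixel intensities (n >= 3).
#' @param photon_counts Matching photon counts, `> 0`.
#' @return A [photon_calibration()].
#' @export
fit_conversion_factor <- function(pixel_values, photon_counts) {
  if (length(pixel_values) != length(photon_counts)) {
    stop("pixel_values and photon_counts must be paired")
  }
  if (length(pixel_values) < 3L) stop("need at least 3 calibration points")
  if (any(photon_counts <= 0) || any(pixel_values <= 0)) {
    stop("calibration measurements must be > 0")
  }
  slope <- sum(pixel_values * photon_counts) / sum(pixel_values^2)
  if (!is.finite(slope) || slope <= 0) stop("degenerate calibration fit")
  ok <- abs(photon_counts - slope * pixel_values) < 0.1 * slope * pixel_values
  linear_max <- if (any(ok)) max(pixel_values[ok]) else max(pixel_values)
  photon_calibration(slope, linear_max)
}

#' Intensity profile along a polyline ROI, in photons per pulse
#'
#' Samples the slice at 1-pixel arclength steps with nearest-pixel lookup
#' (no interpolation: counts are integers), converts to photons and divides
#' by the pulses per pixel.
#'
#' @param stack An [image_stack()].
#' @param r A polyline [roi()] on a single slice.
#' @param cal A [photon_calibration()].
#' @return data.frame with `arclength_um` and `photons_per_pulse`.
#' @export
line_profile <- function(stack, r, cal) {
  stopifnot(inherits(stack, "image_stack"), inherits(r, "roi"),
            inherits(cal, "photon_calibration"))
  if (r$kind != "polyline") stop("line_profile requires a polyline ROI")
  sl <- r$slice_index + 1L
  d <- dim(stack$voxels)
  if (sl < 1L || sl > d[1]) stop("ROI slice outside the stack")
  v <- r$coordinates  # 0-based (row, col) vertices
  seg_len <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  if (sum(seg_len) == 0) stop("zero-length polyline")
  pts <- list()
  for (i in seq_len(nrow(v) - 1L)) {
    if (seg_len[i] == 0) next
    n_steps <- max(1L, ceiling(seg_len[i]))
    frac <- seq(0, 1, length.out = n_steps + 1L)
    if (i > 1L) frac <- frac[-1]  # avoid duplicating shared vertices
    pts[[length(pts) + 1L]] <-
      cbind(v[i, 1] + frac * (v[i + 1, 1] - v[i, 1]),
            v[i, 2] + frac * (v[i + 1, 2] - v[i, 2]))
  }
  pts <- do.call(rbind, pts)
  rows <- pmin(pmax(round(pts[, 1]) + 1, 1), d[2])
  cols <- pmin(pmax(round(pts[, 2]) + 1, 1), d[3])
  vals <- stack$voxels[cbind(sl, rows, cols)]
  steps <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  arc_px <- c(0, cumsum(steps))
  data.frame(arclength_um = arc_px * stack$pixel_size_um,
             photons_per_pulse = vals * cal$conversion_factor /
               stack$pulses_per_pixel)
}

#' Signal-to-background ratio of one ROI pair on one slice
#'
#' Mean pixel value inside the signal ROI divided by the mean inside the
#' adjacent background ROI (e.g. inside a dark vessel lumen). A background
#' mean of exactly zero yields `Inf` with attribute
#' `zero_background = TRUE` rather than a pseudo-count.
#'
#' @param stack An [image_stack()].
#' @param signal_roi,background_roi Mask [roi()]s on the same slice.
#' @return Dimensionless SBR.
#' @export
sbr <- function(stack, signal_roi, background_roi) {
  stopifnot(inherits(stack, "image_stack"))
  if (signal_roi$slice_index != background_roi$slice_index) {
    stop("signal and background ROIs must be on the same slice")
  }
  sl <- signal_roi$slice_index + 1L
  d <- dim(stack$voxels)
  if (sl < 1L || sl > d[1]) stop("ROI slice outside the stack")
  plane <- stack$voxels[sl, , ]
  s <- mean(plane[.roi_pixel_index(signal_roi, d[2], d[3])])
  b <- mean(plane[.roi_pixel_index(background_roi, d[2], d[3])])
  if (b == 0) {
    out <- Inf
    attr(out, "zero_background") <- TRUE
    return(out)
  }
  s / b
}

#' SBR-versus-depth profile over a stack
#'
#' Applies [sbr()] to each supplied ROI pair and averages pairs that share a
#' slice (recording the pair count); slices whose background is identically
#' zero are dropped with their flag preserved in the averaging.
#'
#' @param stack An [image_stack()].
#' @param roi_pairs List of `list(signal = roi, background = roi)` pairs.
#' @return Object of class `sbr_profile`: data.frame with `depth_um`, `sbr`,
#'   `signal_mean`, `background_mean`, `n_pairs`, `roi_labels`, ordered by
#'   depth.
#' @export
sbr_depth_profile <- function(stack, roi_pairs) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(roi_pairs) == 0L) {
    out <- data.frame(depth_um = numeric(), sbr = numeric(),
                      signal_mean = numeric(), background_mean = numeric(),
                      n_pairs = integer(), roi_labels = character())
    class(out) <- c("sbr_profile", "data.frame")
    return(out)
  }
  d <- dim(stack$voxels)
  per_pair <- lapply(roi_pairs, function(p) {
    sl <- p$signal$slice_index + 1L
    plane <- stack$voxels[sl, , ]
    data.frame(slice = sl,
               depth_um = stack$z_positions_um[sl],
               signal_mean = mean(plane[.roi_pixel_index(p$signal, d[2], d[3])]),
               background_mean = mean(plane[.roi_pixel_index(p$background, d[2], d[3])]),
               label = p$signal$label,
               stringsAsFactors = FALSE)
  })
  per_pair <- do.call(rbind, per_pair)
  out <- do.call(rbind, lapply(split(per_pair, per_pair$slice), function(g) {
    sbrs <- ifelse(g$background_mean > 0, g$signal_mean / g$background_mean, Inf)
    data.frame(depth_um = g$depth_um[1],
               sbr = mean(sbrs),
               signal_mean = mean(g$signal_mean),
               background_mean = mean(g$background_mean),
               n_pairs = nrow(g),
               roi_labels = paste(g$label, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$depth_um), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sbr_profile", "data.frame")
  out
}

#' Imaging depth limit from an SBR profile
#'
#' The depth limit is where the SBR falls to the threshold (unity by
#' convention). The crossing is located by log-linear interpolation between
#' the bracketing slices; an exact hit returns that slice's depth;
#' non-finite SBRs (zero-background flags) are ignored.
#'
#' @param profile An `sbr_profile` (or data.frame with `depth_um`, `sbr`).
#' @param threshold SBR threshold, default 1.
#' @return Depth (um), or `NA_real_` when the profile never crosses.
#' @export
depth_limit <- function(profile, threshold = 1.0) {
  if (nrow(profile) == 0L) stop("empty SBR profile")
  p <- profile[is.finite(profile$sbr) & profile$sbr > 0, , drop = FALSE]
  p <- p[order(p$depth_um), , drop = FALSE]
  if (nrow(p) == 0L) return(NA_real_)
  hit <- which(p$sbr == threshold)
  if (length(hit)) return(p$depth_um[hit[1]])
  above <- p$sbr > threshold
  cross <- which(above[-length(above)] & !above[-1])
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  z1 <- p$depth_um[i]; z2 <- p$depth_um[i + 1]
  s1 <- p$sbr[i]; s2 <- p$sbr[i + 1]
  z1 + (z2 - z1) * (log(s1) - log(threshold)) / (log(s1) - log(s2))
}

#' Estimate the effective attenuation length from signal decay with depth
#'
#' For three-photon excitation the detected signal scales as
#' `(Esurface * exp(-z/EAL))^3`, so `ln(signal^(1/3) / Esurface)` is linear
#' in depth with slope `-1/EAL`. Fits that line by least squares (the
#' per-slice surface energies normalize out any excitation power ramp) and
#' bootstraps the depth points for a 95% CI.
#'
#' @param depths_um Depths (um), `n >= 4`.
#' @param signals Mean detected signal per depth, `> 0`.
#' @param surface_energies_nj Surface pulse energy used at each depth (nJ).
#' @param n_boot Bootstrap replicates.
#' @param seed Optional seed for the bootstrap.
#' @return List with `eal_um`, `ci_um` (length 2), `slope_per_um`.
#' @export
estimate_eal <- function(depths_um, signals, surface_energies_nj,
                         n_boot = 1000, seed = NULL) {
  n <- length(depths_um)
  if (n < 4L) stop("need at least 4 depths")
  if (length(signals) != n || length(surface_energies_nj) != n) {
    stop("depths, signals and energies must be the same length")
  }
  if (any(signals <= 0) || any(surface_energies_nj <= 0)) {
    stop("signals and surface energies must be > 0")
  }
  y <- log(signals^(1 / 3) / surface_energies_nj)
  fit_slope <- function(idx) {
    zc <- depths_um[idx] - mean(depths_um[idx])
    if (sum(zc^2) == 0) return(NA_real_)
    sum(zc * y[idx]) / sum(zc^2)
  }
  b <- fit_slope(seq_len(n))
  if (!is.finite(b) || b >= 0) stop("no attenuation detected (non-negative slope)")
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    fit_slope(sample.int(n, replace = TRUE))
  }, numeric(1))
  boot <- boot[is.finite(boot) & boot < 0]
  ci <- if (length(boot) >= 10) {
    stats::quantile(-1 / boot, c(0.025, 0.975), names = FALSE)
  } else c(NA_real_, NA_real_)
  list(eal_um = -1 / b, ci_um = ci, slope_per_um = b)
}

#' Histogram stretching for display
#'
#' Linear rescale to `[0, 1]` clipping the top `saturation_fraction` of
#' pixels to 1 and the bottom `saturation_fraction` to 0 (typical structural
#' display uses 0.2-0.5% saturation). A constant image degenerates to all
#' zeros.
#'
#' @param image Numeric matrix or array.
#' @param saturation_fraction Fraction clipped at each tail, in `[0, 0.05]`.
#' @return Rescaled image in `[0, 1]`, same shape.
#' @export
histogram_stretch <- function(image, saturation_fraction = 0.003) {
  if (saturation_fraction < 0 || saturation_fraction > 0.05) {
    stop("saturation_fraction must lie in [0, 0.05]")
  }
  lo <- stats::quantile(image, saturation_fraction, names = FALSE)
  hi <- stats::quantile(image, 1 - saturation_fraction, names = FALSE)
  if (hi <= lo) return(array(0, dim = dim(image) %||% length(image)))
  out <- (image - lo) / (hi - lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
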