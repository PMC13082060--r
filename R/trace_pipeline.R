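#' Photon-counting activity movie
#'
#' @param frames 3-D integer-valued array `(t, y, x)` of photon counts.
#' @param frame_rate_hz Acquisition frame rate (Hz), `> 0`.
#' @param pixel_size_um Lateral pixel size (um).
#' @param depth_um Imaging depth metadata (um).
#' @return Object of class `activity_movie`.
#' @export
activity_movie <- function(frames, frame_rate_hz, pixel_size_um = NA_real_,
                           depth_um = NA_real_) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (any(frames < 0)) stop("photon counts must be >= 0")
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be > 0")
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 pixel_size_um = pixel_size_um, depth_um = depth_um),
            class = "activity_movie")
}

#' @export
print.activity_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<activity_movie> %d frames of %d x %d px at %.3g Hz (%.3g s)\n",
              d[1], d[2], d[3], x$frame_rate_hz, d[1] / x$frame_rate_hz))
  invisible(x)
}

#' Fluorescence trace
#'
#' @param values Per-frame values (photon counts or normalized units).
#' @param frame_rate_hz Frame rate (Hz).
#' @param roi_label ROI label.
#' @param n_pixels Number of pixels integrated per frame.
#' @return Object of class `trace`.
#' @export
trace <- function(values, frame_rate_hz, roi_label = "", n_pixels = NA_integer_) {
  if (length(values) < 1L) stop("trace must contain at least one sample")
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be > 0")
  structure(list(values = as.numeric(values), frame_rate_hz = frame_rate_hz,
                 roi_label = roi_label, n_pixels = n_pixels),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %s: %d frames at %.3g Hz over %s px\n",
              if (nzchar(x$roi_label)) x$roi_label else "(unnamed)",
              length(x$values), x$frame_rate_hz,
              ifelse(is.na(x$n_pixels), "?", x$n_pixels)))
  invisible(x)
}

#' Extract a fluorescence trace by ROI integration
#'
#' Per-frame sum of photon counts over the ROI's pixels (somatic ROIs are
#' typically ~100 pixels at a 100-um field of view).
#'
#' @param movie An [activity_movie()].
#' @param r A mask [roi()] (its slice index is ignored: the mask applies to
#'   every frame).
#' @return A [trace()] of summed counts.
#' @export
extract_trace <- function(movie, r) {
  stopifnot(inherits(movie, "activity_movie"), inherits(r, "roi"))
  if (r$kind != "mask") stop("extract_trace requires a mask ROI")
  d <- dim(movie$frames)
  px <- .roi_pixel_index(r, d[2], d[3])
  nt <- d[1]
  flat <- matrix(movie$frames, nrow = nt)  # t x (y*x), column-major (y fastest)
  cols <- (px[, 2] - 1L) * d[2] + px[, 1]
  vals <- if (length(cols) == 1L) flat[, cols] else rowSums(flat[, cols, drop = FALSE])
  trace(vals, movie$frame_rate_hz, roi_label = r$label, n_pixels = nrow(px))
}

#' Zero-phase Hamming low-pass filter
#'
#' Convolution with a normalized Hamming window whose duration is the given
#' time constant. The tap count is `round(time_constant * frame_rate)`,
#' never fewer than 3 and forced odd so the filter is symmetric (zero
#' phase); DC gain is exactly 1 and edges are handled by reflection. At
#' 6.18 Hz the default 0.29 s window comes to 3 taps.
#'
#' @param tr A [trace()].
#' @param time_constant_s Window duration (s), default 0.29.
#' @return Filtered [trace()] with metadata preserved.
#' @export
lowpass_hamming <- function(tr, time_constant_s = 0.29) {
  stopifnot(inherits(tr, "trace"))
  if (time_constant_s <= 0) stop("time_constant_s must be > 0")
  n <- max(3L, round(time_constant_s * tr$frame_rate_hz))
  if (n %% 2L == 0L) n <- n + 1L
  x <- tr$values
  if (length(x) < n) stop("trace shorter than the filter window")
  k <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  k <- k / sum(k)
  h <- (n - 1L) %/% 2L
  padded <- c(x[(h + 1):2], x, x[(length(x) - 1):(length(x) - h)])
  y <- stats::filter(padded, k, method = "convolution", sides = 2)
  tr$values <- as.numeric(y[(h + 1):(h + length(x))])
  tr
}

#' Lower-quantile baseline of a trace
#'
#' The baseline F0 is the mean of the samples at or below the
#' `fraction`-quantile of the whole recording (lower ~20% by default). At
#' least one sample (the minimum) is always included.
#'
#' @param tr A [trace()] or numeric vector.
#' @param fraction Quantile fraction in `(0, 1)`.
#' @return Scalar baseline in the trace's units.
#' @export
baseline_f0 <- function(tr, fraction = 0.20) {
  x <- if (inherits(tr, "trace")) tr$values else as.numeric(tr)
  if (length(x) == 0L) stop("empty trace")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  q <- stats::quantile(x, fraction, names = FALSE)
  sel <- x <= q
  if (!any(sel)) sel <- x == min(x)
  mean(x[sel])
}

#' Normalize a trace to fractional fluorescence change
#'
#' `(F - F0) / F0`.
#'
#' @param tr A [trace()].
#' @param f0 Baseline, `> 0` (see [baseline_f0()]).
#' @return Normalized [trace()] (dimensionless values).
#' @export
dff <- function(tr, f0) {
  stopifnot(inherits(tr, "trace"))
  if (!is.finite(f0) || f0 <= 0) stop("baseline not positive")
  tr$values <- (tr$values - f0) / f0
  tr
}

#' Baseline photon rate and recording-fidelity flag
#'
#' Converts the trace baseline to photons (via the calibration factor) and
#' multiplies by the frame rate to obtain photons/neuron/s. Recording
#' fidelity is flagged when the rate reaches `min_rate` (150 photons/neuron/s
#' supports >= 95%-confidence single-transient detection for jGCaMP8s-like
#' kinetics).
#'
#' @param tr A [trace()] of per-frame integrated counts.
#' @param cal A [photon_calibration()]; identity factor when counts are
#'   already photons.
#' @param fraction Baseline quantile fraction, as in [baseline_f0()].
#' @param min_rate Fidelity threshold (photons/neuron/s).
#' @return List with `f0_counts` (per frame), `rate_photons_s`, `fidelity`.
#' @export
f0_photon_rate <- function(tr, cal = photon_calibration(1), fraction = 0.20,
                           min_rate = 150) {
  stopifnot(inherits(tr, "trace"))
  f0 <- baseline_f0(tr, fraction)
  rate <- f0 * cal$conversion_factor * tr$frame_rate_hz
  list(f0_counts = f0, rate_photons_s = rate, fidelity = rate >= min_rate)
}

#' 3-D median filter for activity videos
#'
#' Per-voxel median over a `(2*rx+1) x (2*ry+1) x (2*rt+1)` neighborhood in
#' `(x, y, t)`; neighborhoods are truncated at the array edges (no invented
#' padding values). The published display settings are radii 1/1/18, the
#' temporal radius spanning ~3 s at 6.18 Hz; the residual edge artifacts are
#' removed separately with [trim_edges()].
#'
#' @param movie An [activity_movie()].
#' @param rx,ry Spatial radii (px).
#' @param rt Temporal radius (frames).
#' @return Filtered [activity_movie()] (same length; compose with
#'   [trim_edges()] to drop the temporal edges).
#' @export
median3d_filter <- function(movie, rx = 1, ry = 1, rt = 18) {
  stopifnot(inherits(movie, "activity_movie"))
  if (dim(movie$frames)[1] <= 2 * rt + 1) {
    stop("movie must be longer than 2*rt + 1 frames")
  }
  out <- median3d_cpp(movie$frames, as.integer(rt), as.integer(ry),
                      as.integer(rx))
  movie$frames <- out
  movie
}

#' Trim temporal edges of a filtered movie
#'
#' Drops the first and last `n` frames (default 9, matching the temporal
#' half-window artifacts of the 1/1/18 median filter).
#'
#' @param movie An [activity_movie()].
#' @param n Frames trimmed from each end, `>= 0`.
#' @return Shortened [activity_movie()].
#' @export
trim_edges <- function(movie, n = 9) {
  stopifnot(inherits(movie, "activity_movie"))
  if (n < 0) stop("n must be >= 0")
  if (n == 0L) return(movie)
  nt <- dim(movie$frames)[1]
  if (nt <= 2 * n) stop("movie must be longer than 2*n frames")
  movie$frames <- movie$frames[(n + 1):(nt - n), , , drop = FALSE]
  movie
}

#' Run the full trace pipeline over a set of ROIs
#'
#' For each ROI: integrate counts, optionally discard an initial
#' photobleaching segment, low-pass filter, estimate the baseline, normalize
#' to dF/F and compute the baseline photon rate with its fidelity flag.
#' Filtering precedes normalization by default (`normalize_first = TRUE`
#' swaps the order). Deterministic given its inputs.
#'
#' @param movie An [activity_movie()] (assumed motion-corrected).
#' @param rois List of mask [roi()]s, one per neuron.
#' @param cal A [photon_calibration()].
#' @param time_constant_s Hamming window duration (s).
#' @param baseline_fraction Baseline quantile fraction.
#' @param min_rate Fidelity threshold (photons/neuron/s).
#' @param discard_initial_s Seconds dropped from the start of every trace
#'   before any processing (photobleaching settling), default 0.
#' @param normalize_first Normalize to dF/F before low-pass filtering.
#' @return List with `summary` (data.frame: label, n_pixels, f0_counts,
#'   rate_photons_s, fidelity) and `traces` (per-ROI list of raw, filtered
#'   and dff [trace()]s).
#' @export
process_session <- function(movie, rois, cal = photon_calibration(1),
                            time_constant_s = 0.29, baseline_fraction = 0.20,
                            min_rate = 150, discard_initial_s = 0,
                            normalize_first = FALSE) {
  stopifnot(inherits(movie, "activity_movie"))
  if (length(rois) == 0L) {
    return(list(summary = data.frame(label = character(),
                                     n_pixels = integer(),
                                     f0_counts = numeric(),
                                     rate_photons_s = numeric(),
                                     fidelity = logical()),
                traces = list()))
  }
  res <- lapply(rois, function(r) {
    raw <- extract_trace(movie, r)
    if (discard_initial_s > 0) {
      drop <- min(length(raw$values) - 1L,
                  round(discard_initial_s * raw$frame_rate_hz))
      if (drop > 0) raw$values <- raw$values[-seq_len(drop)]
    }
    if (normalize_first) {
      f0 <- baseline_f0(raw, baseline_fraction)
      norm <- dff(raw, f0)
      filt <- lowpass_hamming(norm, time_constant_s)
      budget <- f0_photon_rate(raw, cal, baseline_fraction, min_rate)
      list(raw = raw, filtered = filt, dff = filt, budget = budget)
    } else {
      filt <- lowpass_hamming(raw, time_constant_s)
      f0 <- baseline_f0(filt, baseline_fraction)
      norm <- dff(filt, f0)
      budget <- f0_photon_rate(filt, cal, baseline_fraction, min_rate)
      list(raw = raw, filtered = filt, dff = norm, budget = budget)
    }
  })
  summary <- do.call(rbind, lapply(res, function(x) {
    data.frame(label = x$raw$roi_label, n_pixels = x$raw$n_pixels,
               f0_counts = x$budget$f0_counts,
               rate_photons_s = x$budget$rate_photons_s,
               fidelity = x$budget$fidelity,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(summary = summary, traces = res)
}
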