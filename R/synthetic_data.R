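#' Recipe for a synthetic structural image stack
#'
#' Describes a deep-tissue structural acquisition: labeled vessels (and
#' optionally somata) imaged through attenuating tissue with an excitation
#' power ramp, an SBR that decays log-linearly from `sbr0` at the surface to
#' 1 at `depth_limit_um`, and Poisson shot noise on every pixel.
#'
#' @param shape Integer triple `(nz, ny, nx)`.
#' @param pixel_size_um Lateral pixel size (um).
#' @param z_range_um Depth range `(z_min, z_max)` (um) spanned by the slices.
#' @param vessels List with `n` (count) and `radius_range_um`; vessels are
#'   rendered as sinusoidal tubes crossing the field.
#' @param somata Optional list with `n`, `diameter_range_um` (default
#'   `c(10, 15)`) and `nuclear_exclusion` (fraction of somatic brightness
#'   missing from the nucleus, default 0.6).
#' @param tissue A [tissue_optics_model()].
#' @param sbr0 Surface SBR, `> 1`.
#' @param depth_limit_um Depth where the generated SBR reaches 1, `> 0`.
#' @param photon_scale Expected signal photons/pixel at the surface, `>= 0`.
#' @param energy_ramp `"compensating"` ramps the surface pulse energy as
#'   `exp(z/EAL)` to hold the focal energy (hence the signal) constant until
#'   `esurface_max_nj` is reached; `"constant"` keeps the surface energy
#'   fixed so the signal decays as `exp(-3z/EAL)`.
#' @param esurface_max_nj Surface pulse-energy cap for the ramp (nJ).
#' @param seed Integer seed; all randomness in the generator is behind it.
#' @return Object of class `stack_recipe`.
#' @export
stack_recipe <- function(shape = c(26, 64, 64), pixel_size_um = 2,
                         z_range_um = c(0, 2600),
                         vessels = list(n = 6, radius_range_um = c(4, 10)),
                         somata = NULL,
                         tissue = tissue_optics_model(),
                         sbr0 = 100, depth_limit_um = 2500,
                         photon_scale = 50,
                         energy_ramp = c("compensating", "constant"),
                         esurface_max_nj = 1000, seed = 1) {
  energy_ramp <- match.arg(energy_ramp)
  stopifnot(length(shape) == 3L, all(shape >= 1),
            inherits(tissue, "tissue_optics"))
  if (depth_limit_um <= 0) stop("depth_limit_um must be > 0")
  if (sbr0 <= 1) stop("sbr0 must be > 1")
  if (photon_scale < 0) stop("photon_scale must be >= 0")
  if (is.null(vessels) && is.null(somata)) stop("empty geometry")
  structure(list(shape = as.integer(shape), pixel_size_um = pixel_size_um,
                 z_range_um = z_range_um, vessels = vessels, somata = somata,
                 tissue = tissue, sbr0 = sbr0,
                 depth_limit_um = depth_limit_um,
                 photon_scale = photon_scale, energy_ramp = energy_ramp,
                 esurface_max_nj = esurface_max_nj, seed = as.integer(seed)),
            class = "stack_recipe")
}

# sinusoidal-tube vessel mask on an ny x nx grid
.render_vessels <- function(ny, nx, n, radius_range_px) {
  mask <- matrix(FALSE, ny, nx)
  col <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  row <- matrix(rep(seq_len(ny), nx), ny, nx)
  for (i in seq_len(n)) {
    y0 <- stats::runif(1, 0.1 * ny, 0.9 * ny)
    r <- stats::runif(1, radius_range_px[1], radius_range_px[2])
    amp <- stats::runif(1, 0, 0.05 * ny)
    period <- stats::runif(1, 0.5 * nx, 2 * nx)
    phase <- stats::runif(1, 0, 2 * pi)
    center <- y0 + amp * sin(2 * pi * col / period + phase)
    mask <- mask | (abs(row - center) <= r)
  }
  mask
}

#' Generate a synthetic structural stack with ground truth
#'
#' Renders the recipe's geometry once (vessels run across the field, so every
#' slice sees the same cross-sections), computes per-slice expected signal
#' and background means from the optics and SBR models, and draws independent
#' Poisson counts per pixel. Pixels inside the geometry draw around the
#' signal mean and pixels outside around the background mean
#' `signal / SBR(z)`, so ROI ratio measurements estimate the generating
#' SBR(z) directly.
#'
#' @param recipe A [stack_recipe()].
#' @return List with `stack` (an [image_stack()]) and `truth`: the geometry
#'   mask, per-slice depths, true SBR, expected signal/background means,
#'   surface energies, the tissue model and the generating depth limit.
#' @export
make_structural_stack <- function(recipe) {
  stopifnot(inherits(recipe, "stack_recipe"))
  set.seed(recipe$seed)
  nz <- recipe$shape[1]; ny <- recipe$shape[2]; nx <- recipe$shape[3]
  z <- seq(recipe$z_range_um[1], recipe$z_range_um[2], length.out = nz)

  mask <- matrix(FALSE, ny, nx)
  if (!is.null(recipe$vessels) && recipe$vessels$n > 0) {
    mask <- mask | .render_vessels(
      ny, nx, recipe$vessels$n,
      recipe$vessels$radius_range_um / recipe$pixel_size_um)
  }
  if (!is.null(recipe$somata) && recipe$somata$n > 0) {
    dr <- recipe$somata$diameter_range_um %||% c(10, 15)
    for (i in seq_len(recipe$somata$n)) {
      r <- stats::runif(1, dr[1] / 2, dr[2] / 2) / recipe$pixel_size_um
      cy <- stats::runif(1, r + 1, ny - r)
      cx <- stats::runif(1, r + 1, nx - r)
      rowm <- matrix(rep(seq_len(ny), nx), ny, nx)
      colm <- matrix(rep(seq_len(nx), each = ny), ny, nx)
      mask <- mask | ((rowm - cy)^2 + (colm - cx)^2 <= r^2)
    }
  }
  if (!any(mask)) stop("recipe geometry rendered an empty mask")

  atten <- attenuation_factor(recipe$tissue, z)
  e0 <- 2  # reference focal pulse energy scale (nJ); ratios only
  esurf <- if (recipe$energy_ramp == "compensating") {
    pmin(e0 / atten, recipe$esurface_max_nj)
  } else rep(e0, nz)
  # signal ~ (Esurface * attenuation)^3, normalized to photon_scale at z[1]
  efoc3 <- (esurf * atten)^3
  signal <- recipe$photon_scale * efoc3 / efoc3[1]
  sbr_true <- recipe$sbr0^(1 - z / recipe$depth_limit_um)
  background <- signal / sbr_true

  vox <- array(0, dim = c(nz, ny, nx))
  for (k in seq_len(nz)) {
    lam <- matrix(background[k], ny, nx)
    lam[mask] <- signal[k]
    vox[k, , ] <- stats::rpois(ny * nx, lam)
  }
  list(stack = image_stack(vox, recipe$pixel_size_um, z,
                           channel = "synthetic",
                           pulses_per_pixel = 1),
       truth = list(mask = mask, z_positions_um = z, sbr_true = sbr_true,
                    signal_mean = signal, background_mean = background,
                    surface_energies_nj = esurf, tissue = recipe$tissue,
                    depth_limit_um = recipe$depth_limit_um,
                    sbr0 = recipe$sbr0))
}

#' Recipe for a synthetic activity session
#'
#' Defaults reproduce the deep functional-imaging configuration this package
#' models: up to 44 neurons in a 100-um field (120 x 120 px) at 6.18 Hz,
#' jGCaMP8s-like kinetics, a 305 photons/neuron/s baseline (the 99%-confidence
#' budget tier), sparse spontaneous activity, somata of 10-15 um with nuclear
#' exclusion (60% of the photon rate in a 2-px cytoplasmic ring), and a dim
#' uniform background consistent with the high somatic SBR observed at these
#' depths.
#'
#' @param n_neurons Number of somata, `>= 1`.
#' @param fov_um Field-of-view side (um).
#' @param frame_shape `(ny, nx)` pixels.
#' @param frame_rate_hz Frame rate (Hz).
#' @param duration_s Recording duration (s).
#' @param kinetics An [indicator_kinetics()].
#' @param spike_rate_hz Poisson spike rate per neuron (Hz); ignored for a
#'   neuron with an entry in `spike_times`.
#' @param baseline_rate_f0 Baseline photon rate per neuron (photons/s).
#' @param background_rate_px_s Background photon rate per pixel (photons/s).
#' @param soma_diameter_um_range Soma diameter range (um).
#' @param depth_um Depth metadata (um).
#' @param spike_times Optional list of explicit spike-time vectors (s), one
#'   per neuron (`NULL` entries fall back to the Poisson process).
#' @param seed Integer seed.
#' @return Object of class `session_recipe`.
#' @export
session_recipe <- function(n_neurons = 44, fov_um = 100,
                           frame_shape = c(120, 120), frame_rate_hz = 6.18,
                           duration_s = 60,
                           kinetics = indicator_kinetics(),
                           spike_rate_hz = 0.1, baseline_rate_f0 = 305,
                           background_rate_px_s = 0.12,
                           soma_diameter_um_range = c(10, 15),
                           depth_um = 2000, spike_times = NULL, seed = 1) {
  stopifnot(n_neurons >= 1, fov_um > 0, all(frame_shape > 0),
            frame_rate_hz > 0, duration_s > 0,
            inherits(kinetics, "indicator_kinetics"),
            spike_rate_hz >= 0, baseline_rate_f0 > 0,
            background_rate_px_s >= 0)
  structure(list(n_neurons = as.integer(n_neurons), fov_um = fov_um,
                 frame_shape = as.integer(frame_shape),
                 frame_rate_hz = frame_rate_hz, duration_s = duration_s,
                 kinetics = kinetics, spike_rate_hz = spike_rate_hz,
                 baseline_rate_f0 = baseline_rate_f0,
                 background_rate_px_s = background_rate_px_s,
                 soma_diameter_um_range = soma_diameter_um_range,
                 depth_um = depth_um, spike_times = spike_times,
                 seed = as.integer(seed)),
            class = "session_recipe")
}

#' Instantaneous photon rate from a spike train
#'
#' Linear superposition of single-transient responses on the baseline:
#' `rate(t) = f0 * (1 + sum_s dF/F * exp(-(t - t_s)/tau) * 1[t >= t_s])`.
#'
#' @param spike_times_s Spike times (s) within `[0, duration_s)`.
#' @param kin An [indicator_kinetics()].
#' @param f0 Baseline photon rate (photons/s).
#' @param duration_s Duration (s).
#' @param dt_s Time step (s).
#' @return data.frame with `time_s` and `rate_hz`.
#' @export
spikes_to_rate <- function(spike_times_s, kin, f0, duration_s, dt_s) {
  stopifnot(inherits(kin, "indicator_kinetics"))
  if (length(spike_times_s) &&
      (any(spike_times_s < 0) || any(spike_times_s >= duration_s))) {
    stop("spike times must lie within [0, duration_s)")
  }
  t <- seq(0, duration_s, by = dt_s)
  excess <- numeric(length(t))
  for (ts in spike_times_s) {
    on <- t >= ts
    excess[on] <- excess[on] + exp(-(t[on] - ts) / kin$tau_1e_s)
  }
  data.frame(time_s = t,
             rate_hz = f0 * (1 + kin$dff_single_transient * excess))
}

# fraction of a transient's peak amplitude integrated over frame [a, b),
# onset at ts, normalized by frame length
.frame_transient_fraction <- function(a, b, ts, tau) {
  lo <- pmax(a, ts)
  out <- ifelse(b <= ts, 0,
                tau * (exp(-(lo - ts) / tau) - exp(-(b - ts) / tau)) / (b - a))
  out
}

# place n non-overlapping disks on a jittered grid; error when impossible
.place_somata <- function(n, ny, nx, radius_range_px, max_attempts = 60) {
  g <- ceiling(sqrt(n))
  cell_y <- ny / g; cell_x <- nx / g
  cells <- expand.grid(iy = seq_len(g), ix = seq_len(g))
  cells <- cells[sample.int(nrow(cells), n), , drop = FALSE]
  placed <- matrix(numeric(0), ncol = 3)  # cy, cx, r
  for (i in seq_len(n)) {
    base_y <- (cells$iy[i] - 0.5) * cell_y
    base_x <- (cells$ix[i] - 0.5) * cell_x
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      r <- stats::runif(1, radius_range_px[1], radius_range_px[2])
      cy <- min(max(base_y + stats::runif(1, -1.5, 1.5), r + 1), ny - r)
      cx <- min(max(base_x + stats::runif(1, -1.5, 1.5), r + 1), nx - r)
      if (nrow(placed) == 0 ||
          all(sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2) >
              placed[, 3] + r)) {
        placed <- rbind(placed, c(cy, cx, r))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("somata cannot be placed without overlap; reduce n or diameters")
  }
  placed
}

#' Generate a synthetic activity movie with ground truth
#'
#' Places non-overlapping somata (cytoplasmic ring bright, nucleus dim:
#' nuclear exclusion), draws spike trains, integrates the transient rate
#' model exactly over each frame and draws per-pixel Poisson counts on top of
#' a uniform background. Bitwise deterministic given the recipe seed.
#'
#' @param recipe A [session_recipe()].
#' @return List with `movie` (an [activity_movie()]) and `truth`: per-neuron
#'   spike times, mask [roi()]s (0-based), expected baseline counts per frame
#'   (neuron + background inside the mask), the neuron's own rate and pixel
#'   shares, the kinetics, and per-frame expected rate multipliers.
#' @export
make_activity_movie <- function(recipe) {
  stopifnot(inherits(recipe, "session_recipe"))
  set.seed(recipe$seed)
  ny <- recipe$frame_shape[1]; nx <- recipe$frame_shape[2]
  px_um <- recipe$fov_um / nx
  fs <- recipe$frame_rate_hz
  nt <- max(1L, round(recipe$duration_s * fs))
  kin <- recipe$kinetics

  placed <- .place_somata(recipe$n_neurons, ny, nx,
                          recipe$soma_diameter_um_range / 2 / px_um)

  rowm <- matrix(rep(seq_len(ny), nx), ny, nx)
  colm <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ring_width_px <- 2

  neurons <- vector("list", recipe$n_neurons)
  lam <- matrix(recipe$background_rate_px_s / fs, nrow = nt,
                ncol = ny * nx)
  frame_a <- (seq_len(nt) - 1) / fs
  frame_b <- seq_len(nt) / fs

  for (i in seq_len(recipe$n_neurons)) {
    cy <- placed[i, 1]; cx <- placed[i, 2]; r <- placed[i, 3]
    d2 <- (rowm - cy)^2 + (colm - cx)^2
    soma <- d2 <= r^2
    nucleus <- d2 <= (r - ring_width_px)^2
    ring <- soma & !nucleus
    if (!any(ring)) { ring <- soma; nucleus <- soma & FALSE }
    share <- matrix(0, ny, nx)
    if (any(nucleus)) {
      share[ring] <- 0.6 / sum(ring)
      share[nucleus] <- 0.4 / sum(nucleus)
    } else share[ring] <- 1 / sum(ring)

    st <- if (!is.null(recipe$spike_times) &&
              length(recipe$spike_times) >= i &&
              !is.null(recipe$spike_times[[i]])) {
      sort(recipe$spike_times[[i]])
    } else {
      n_sp <- stats::rpois(1, recipe$spike_rate_hz * recipe$duration_s)
      sort(stats::runif(n_sp, 0, recipe$duration_s))
    }
    mult <- rep(1, nt)
    for (ts in st) {
      mult <- mult + kin$dff_single_transient *
        .frame_transient_fraction(frame_a, frame_b, ts, kin$tau_1e_s)
    }
    idx <- which(soma)
    per_frame <- recipe$baseline_rate_f0 / fs
    lam[, idx] <- lam[, idx] + (mult * per_frame) %o% share[idx]

    coords <- cbind(rowm[soma], colm[soma]) - 1  # 0-based
    neurons[[i]] <- list(
      label = sprintf("n%02d", i),
      roi = roi("mask", coords, slice_index = 0, label = sprintf("n%02d", i)),
      center_px = c(cy, cx), radius_px = r,
      spike_times_s = st,
      f0_photons_s = recipe$baseline_rate_f0,
      baseline_counts_per_frame = per_frame +
        recipe$background_rate_px_s / fs * sum(soma),
      rate_multiplier = mult)
  }

  counts <- array(stats::rpois(length(lam), lam), dim = c(nt, ny, nx))
  list(movie = activity_movie(counts, fs, pixel_size_um = px_um,
                              depth_um = recipe$depth_um),
       truth = list(neurons = neurons, kinetics = kin,
                    background_rate_px_s = recipe$background_rate_px_s,
                    frame_rate_hz = fs, n_frames = nt))
}

#' Paired pixel-value / photon-count calibration fixture
#'
#' Linear pairs `counts ~ factor * pixel_value` with optional Poisson noise
#' on the counts, for exercising [fit_conversion_factor()].
#'
#' @param true_factor Generating conversion factor, `> 0`.
#' @param n_points Number of pairs.
#' @param noise Draw counts as Poisson (`TRUE`) or exact (`FALSE`).
#' @param seed Integer seed.
#' @return List with `pixel_values` and `photon_counts`.
#' @export
make_calibration_fixture <- function(true_factor, n_points = 20, noise = TRUE,
                                     seed = 1) {
  if (true_factor <= 0) stop("true_factor must be > 0")
  set.seed(seed)
  x <- seq(20, 400, length.out = n_points)
  y <- if (noise) stats::rpois(n_points, true_factor * x) else true_factor * x
  list(pixel_values = x, photon_counts = y)
}
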