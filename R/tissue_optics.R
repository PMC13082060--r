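#' Laser excitation configuration
#'
#' Describes the excitation source state at the tissue surface. The average
#' surface power is tied to the repetition rate and the surface pulse energy
#' by `Psurface = f * Esurface`; supplying all three is allowed only when they
#' are mutually consistent.
#'
#' Units are fixed package-wide: depths and attenuation lengths in micrometres,
#' pulse energies in nanojoules, average powers in milliwatts, repetition
#' rates in hertz, durations in seconds. Conversions happen only at I/O
#' boundaries.
#'
#' @param repetition_rate_f_hz Laser repetition rate (Hz).
#' @param surface_pulse_energy_esurface_nj Pulse energy delivered at the
#'   tissue surface (nJ).
#' @param pulse_width_tau_s Pulse duration (s). Default 60 fs.
#' @param surface_power_psurface_mw Optional average power at the surface
#'   (mW). If supplied it must equal `f * Esurface` within 1e-9 relative
#'   tolerance; if omitted it is derived.
#' @param wavelength_nm Excitation wavelength (nm), informational only.
#' @return An object of class `laser_config`.
#' @examples
#' # 1 uJ at the surface, 100 kHz: 100 mW average power
#' laser_config(1e5, 1000)
#' @export
laser_config <- function(repetition_rate_f_hz,
                         surface_pulse_energy_esurface_nj,
                         pulse_width_tau_s = 60e-15,
                         surface_power_psurface_mw = NULL,
                         wavelength_nm = 1300) {
  stopifnot(is.numeric(repetition_rate_f_hz), length(repetition_rate_f_hz) == 1L,
            is.numeric(surface_pulse_energy_esurface_nj),
            length(surface_pulse_energy_esurface_nj) == 1L)
  if (repetition_rate_f_hz <= 0 || surface_pulse_energy_esurface_nj <= 0 ||
      pulse_width_tau_s <= 0 || wavelength_nm <= 0) {
    stop("all laser_config fields must be > 0")
  }
  # Hz * nJ = 1e-9 W = 1e-6 mW
  derived_mw <- repetition_rate_f_hz * surface_pulse_energy_esurface_nj * 1e-6
  if (is.null(surface_power_psurface_mw)) {
    surface_power_psurface_mw <- derived_mw
  } else if (abs(surface_power_psurface_mw - derived_mw) >
             1e-9 * max(abs(derived_mw), abs(surface_power_psurface_mw))) {
    stop(sprintf(
      "inconsistent laser_config: Psurface = %.9g mW but f * Esurface = %.9g mW",
      surface_power_psurface_mw, derived_mw))
  }
  structure(
    list(repetition_rate_f_hz = repetition_rate_f_hz,
         pulse_width_tau_s = pulse_width_tau_s,
         surface_pulse_energy_esurface_nj = surface_pulse_energy_esurface_nj,
         surface_power_psurface_mw = surface_power_psurface_mw,
         wavelength_nm = wavelength_nm),
    class = "laser_config")
}

#' @export
print.laser_config <- function(x, ...) {
  cat(sprintf(
    "<laser_config> f = %.4g MHz, Esurface = %.4g nJ, Psurface = %.4g mW, tau = %.3g fs\n",
    x$repetition_rate_f_hz / 1e6, x$surface_pulse_energy_esurface_nj,
    x$surface_power_psurface_mw, x$pulse_width_tau_s * 1e15))
  invisible(x)
}

#' Layered tissue attenuation model
#'
#' Piecewise-constant effective attenuation length (EAL) model of the tissue
#' column, ordered from the surface downward. The deepest layer extends to
#' infinity, so depths beyond the total listed thickness keep attenuating with
#' the last layer's EAL. A single-row model reduces to the classical
#' `exp(-z/EAL)` ballistic attenuation.
#'
#' The default 300 um EAL is a documented placeholder typical of 1300-nm
#' excitation in cortical grey matter; measured values for a given preparation
#' should be supplied by the user.
#'
#' @param layers A data.frame (or 2-column matrix) with columns
#'   `thickness_um` and `eal_um`, surface first.
#' @param depth_calibration_factor Multiplicative correction from raw
#'   objective displacement to true tissue depth, in `[1, 1.2]`. Default
#'   1.075, the midpoint of the typical 5-10% refractive-index underestimate.
#' @return An object of class `tissue_optics`.
#' @examples
#' uniform <- tissue_optics_model()                      # one 300-um-EAL layer
#' layered <- tissue_optics_model(data.frame(
#'   thickness_um = c(1000, 200), eal_um = c(300, 150))) # scattering layer below 1 mm
#' @export
tissue_optics_model <- function(layers = data.frame(thickness_um = Inf, eal_um = 300),
                                depth_calibration_factor = 1.075) {
  layers <- as.data.frame(layers)
  if (!all(c("thickness_um", "eal_um") %in% names(layers))) {
    if (ncol(layers) == 2L) names(layers) <- c("thickness_um", "eal_um")
    else stop("layers must have columns thickness_um and eal_um")
  }
  layers <- layers[, c("thickness_um", "eal_um")]
  if (nrow(layers) < 1L) stop("at least one tissue layer is required")
  if (any(layers$thickness_um <= 0) || any(layers$eal_um <= 0)) {
    stop("layer thicknesses and EALs must be > 0")
  }
  if (depth_calibration_factor < 1.0 || depth_calibration_factor > 1.2) {
    stop("depth_calibration_factor must lie in [1.0, 1.2]")
  }
  # last layer extends indefinitely
  layers$thickness_um[nrow(layers)] <- Inf
  structure(list(layers = layers,
                 depth_calibration_factor = depth_calibration_factor),
            class = "tissue_optics")
}

#' @export
print.tissue_optics <- function(x, ...) {
  cat(sprintf("<tissue_optics> %d layer(s), depth calibration %.3f\n",
              nrow(x$layers), x$depth_calibration_factor))
  print(x$layers, row.names = FALSE)
  invisible(x)
}

#' Ballistic excitation attenuation to depth z
#'
#' Fraction of surface pulse energy (equivalently average power) remaining at
#' depth `z_um`: `exp(-sum_i dz_i / EAL_i)` over the layer segments traversed.
#' Vectorized over `z_um`.
#'
#' @param tissue A [tissue_optics_model()].
#' @param z_um Depth(s) below the surface (um), `>= 0`.
#' @return Attenuation factor(s) in `(0, 1]`.
#' @examples
#' attenuation_factor(tissue_optics_model(), 300)  # exp(-1)
#' @export
attenuation_factor <- function(tissue, z_um) {
  stopifnot(inherits(tissue, "tissue_optics"), is.numeric(z_um))
  if (any(z_um < 0)) stop("depth z_um must be >= 0")
  tops <- cumsum(c(0, tissue$layers$thickness_um))   # layer upper boundaries
  nl <- nrow(tissue$layers)
  vapply(z_um, function(z) {
    opt <- 0
    for (i in seq_len(nl)) {
      seg <- min(z, tops[i + 1]) - tops[i]
      if (seg <= 0) break
      opt <- opt + seg / tissue$layers$eal_um[i]
    }
    exp(-opt)
  }, numeric(1))
}

#' Pulse energy at the focus for a given surface pulse energy
#'
#' `Efocus = Esurface * exp(-z/EAL)` (layered generalization).
#'
#' @param esurface_nj Surface pulse energy (nJ), `> 0`.
#' @param tissue A [tissue_optics_model()].
#' @param z_um Depth (um).
#' @return Focal pulse energy (nJ).
#' @export
focus_pulse_energy <- function(esurface_nj, tissue, z_um) {
  if (any(esurface_nj <= 0)) stop("Esurface must be > 0")
  esurface_nj * attenuation_factor(tissue, z_um)
}

#' Surface pulse energy required to deliver a target focal energy
#'
#' Inverse of [focus_pulse_energy()]: `Esurface = Efocus * exp(z/EAL)`.
#'
#' @param efocus_target_nj Target pulse energy at the focus (nJ), `> 0`.
#' @param tissue A [tissue_optics_model()].
#' @param z_um Depth (um).
#' @return Required surface pulse energy (nJ).
#' @export
required_surface_energy <- function(efocus_target_nj, tissue, z_um) {
  if (any(efocus_target_nj <= 0)) stop("Efocus target must be > 0")
  efocus_target_nj / attenuation_factor(tissue, z_um)
}

#' Depth-dependent optimal laser repetition rate
#'
#' With the surface average power capped by tissue heating and the focal
#' pulse energy capped by saturation/nonlinear damage, the signal-maximizing
#' repetition rate is `f(z) = exp(-z/EAL) * Psurface_max / Efocus_max`. With
#' the typical caps (100 mW, 2 nJ) this is 50 MHz at the surface and about
#' 100 kHz around 6 attenuation lengths.
#'
#' @param tissue A [tissue_optics_model()].
#' @param z_um Depth (um).
#' @param psurface_max_mw Maximum tolerable average surface power (mW).
#' @param efocus_max_nj Maximum usable focal pulse energy (nJ).
#' @return Repetition rate (Hz).
#' @examples
#' optimal_rep_rate(tissue_optics_model(), 0)  # 5e7 Hz = 50 MHz
#' @export
optimal_rep_rate <- function(tissue, z_um, psurface_max_mw = 100,
                             efocus_max_nj = 2) {
  if (psurface_max_mw <= 0 || efocus_max_nj <= 0) {
    stop("power and energy caps must be > 0")
  }
  attenuation_factor(tissue, z_um) *
    (psurface_max_mw * 1e-3) / (efocus_max_nj * 1e-9)
}

#' Relative time-averaged three-photon signal
#'
#' Evaluates the three-photon signal-scaling law
#' `<F> ~ Efocus(z)^2 * Pfocus(z) / tau^2` with the proportionality constant
#' (cross-section, collection, quantum yield) fixed to 1: only ratios between
#' configurations are meaningful, which is why the result is wrapped as a
#' "relative" estimate.
#'
#' @param config A [laser_config()].
#' @param tissue A [tissue_optics_model()].
#' @param z_um Depth (um).
#' @return Object of class `signal_estimate` with fields `relative_signal`
#'   and `depth_z_um`.
#' @export
relative_signal <- function(config, tissue, z_um) {
  stopifnot(inherits(config, "laser_config"))
  a <- attenuation_factor(tissue, z_um)
  efocus <- config$surface_pulse_energy_esurface_nj * a
  pfocus <- config$surface_power_psurface_mw * a
  structure(list(relative_signal = efocus^2 * pfocus / config$pulse_width_tau_s^2,
                 depth_z_um = z_um),
            class = "signal_estimate")
}

#' @export
print.signal_estimate <- function(x, ...) {
  cat(sprintf("<signal_estimate> relative signal %.4g at z = %g um\n",
              x$relative_signal, x$depth_z_um))
  invisible(x)
}

#' Signal ratio between two laser configurations
#'
#' Ratio of [relative_signal()] for configuration `a` over configuration `b`
#' at the same depth in the same tissue. Comparisons assume equal pulse
#' widths; set `allow_unequal_tau = TRUE` to compare across pulse widths via
#' the `(f*tau)^-2` term of the scaling law.
#'
#' @param a,b [laser_config()] objects.
#' @param tissue A [tissue_optics_model()].
#' @param z_um Depth (um).
#' @param allow_unequal_tau Permit configurations with different pulse widths.
#' @return Dimensionless fold-change (signal of `a` per unit signal of `b`).
#' @examples
#' tis <- tissue_optics_model()
#' hi <- laser_config(1e5, 1000)  # 1 uJ, 100 kHz
#' lo <- laser_config(1e6, 100)   # 0.1 uJ, 1 MHz; same 100 mW average power
#' signal_ratio(hi, lo, tis, 2000)  # 100-fold
#' @export
signal_ratio <- function(a, b, tissue, z_um, allow_unequal_tau = FALSE) {
  stopifnot(inherits(a, "laser_config"), inherits(b, "laser_config"))
  if (!allow_unequal_tau &&
      abs(a$pulse_width_tau_s - b$pulse_width_tau_s) >
      1e-12 * a$pulse_width_tau_s) {
    stop("configurations have unequal pulse widths; set allow_unequal_tau = TRUE")
  }
  sb <- relative_signal(b, tissue, z_um)$relative_signal
  if (sb == 0) stop("zero signal in denominator configuration")
  relative_signal(a, tissue, z_um)$relative_signal / sb
}

#' Check a configuration against surface-power and focal-energy limits
#'
#' The typical deep-imaging operating caps at 1300 nm are ~100 mW average
#' power at the surface (heating) and ~2 nJ at the focus (saturation /
#' nonlinear damage). Violations are returned as data, not raised.
#'
#' @param config A [laser_config()].
#' @param psurface_limit_mw Surface average power cap (mW).
#' @param efocus_limit_nj Focal pulse energy cap (nJ).
#' @param tissue Optional [tissue_optics_model()] used to attenuate the
#'   surface pulse energy down to `z_um`; with the default `z_um = 0` the
#'   focal energy equals the surface energy (worst case).
#' @param z_um Depth at which the focal energy is evaluated (um).
#' @return A data.frame with columns `quantity`, `value`, `limit`; zero rows
#'   when the configuration is within limits.
#' @export
check_constraints <- function(config, psurface_limit_mw = 100,
                              efocus_limit_nj = 2, tissue = NULL, z_um = 0) {
  stopifnot(inherits(config, "laser_config"))
  a <- if (is.null(tissue)) 1 else attenuation_factor(tissue, z_um)
  efocus <- config$surface_pulse_energy_esurface_nj * a
  out <- data.frame(quantity = character(), value = numeric(),
                    limit = numeric(), stringsAsFactors = FALSE)
  if (config$surface_power_psurface_mw > psurface_limit_mw) {
    out <- rbind(out, data.frame(quantity = "surface_power_psurface_mw",
                                 value = config$surface_power_psurface_mw,
                                 limit = psurface_limit_mw))
  }
  if (efocus > efocus_limit_nj) {
    out <- rbind(out, data.frame(quantity = "focus_pulse_energy_efocus_nj",
                                 value = efocus, limit = efocus_limit_nj))
  }
  out
}

#' Correct a raw objective displacement to true tissue depth
#'
#' Raw axial objective displacements underestimate true depth because brain
#' tissue has a higher refractive index than the immersion water; the model's
#' calibration factor (default 1.075) rescales them.
#'
#' @param raw_depth_um Raw recorded depth(s) (um), `>= 0`.
#' @param tissue A [tissue_optics_model()] carrying the calibration factor.
#' @return Calibrated depth(s) (um).
#' @export
calibrate_depth <- function(raw_depth_um, tissue) {
  stopifnot(inherits(tissue, "tissue_optics"))
  if (any(raw_depth_um < 0)) stop("raw depth must be >= 0")
  raw_depth_um * tissue$depth_calibration_factor
}

#' Depth table of the excitation photon budget
#'
#' Tabulates, per depth: attenuation factor, focal pulse energy at the
#' optimal operating point, required surface pulse energy, optimal repetition
#' rate, and the relative signal at that operating point (normalized to 1 at
#' the surface).
#'
#' @param tissue A [tissue_optics_model()].
#' @param z_um Depths (um).
#' @param psurface_max_mw,efocus_max_nj Operating caps, as in
#'   [optimal_rep_rate()].
#' @return A data.frame with one row per depth.
#' @export
budget_depth_table <- function(tissue, z_um, psurface_max_mw = 100,
                               efocus_max_nj = 2) {
  a <- attenuation_factor(tissue, z_um)
  f <- optimal_rep_rate(tissue, z_um, psurface_max_mw, efocus_max_nj)
  # at the optimum Efocus and Pfocus-at-focus are depth-independent caps, so
  # the relative signal per unit time is proportional to f (pulse rate)
  data.frame(z_um = z_um,
             attenuation = a,
             efocus_nj = efocus_max_nj,
             esurface_nj = efocus_max_nj / a,
             rep_rate_hz = f,
             relative_signal = f / f[which.min(z_um)])
}
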