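#' Fit single-transient kinetics from spike-aligned dF/F traces
#'
#' Recovers the single-transient amplitude and decay constant from dF/F
#' traces with known spike times (e.g. synthetic ground truth). Because a
#' frame integrates the decaying transient over its duration, the expected
#' value of the j-th post-onset frame is
#' `A * tau * fs * (1 - exp(-1/(tau*fs))) * exp(-(t_start - t_spike)/tau)`;
#' consecutive-frame ratios preserve `tau` exactly, and the fitted `tau`
#' deconvolves the integration factor so the recovered amplitude is the
#' instantaneous peak dF/F, not the frame-averaged one. Only isolated spikes
#' (no neighbor within `isolation_s`) contribute, and points are pooled
#' across traces into one nonlinear least-squares fit.
#'
#' @param traces List of numeric dF/F vectors (or [trace()] objects).
#' @param spike_times List of spike-time vectors (s), parallel to `traces`.
#' @param frame_rate_hz Frame rate (Hz).
#' @param n_frames Post-onset frames used per spike.
#' @param isolation_s Minimum separation from any other spike (s).
#' @return List with `dff_amplitude`, `tau_1e_s`, `n_transients`, `n_points`.
#' @export
fit_transient_kinetics <- function(traces, spike_times, frame_rate_hz,
                                   n_frames = 3, isolation_s = 1.5) {
  stopifnot(length(traces) == length(spike_times))
  fs <- frame_rate_hz
  xs <- numeric(0); ys <- numeric(0); n_tr <- 0L
  for (i in seq_along(traces)) {
    v <- if (inherits(traces[[i]], "trace")) traces[[i]]$values else traces[[i]]
    st <- sort(spike_times[[i]])
    if (!length(st)) next
    gaps_ok <- if (length(st) == 1L) TRUE else {
      d <- diff(st)
      c(d[1] >= isolation_s,
        if (length(st) > 2L) pmin(d[-length(d)], d[-1]) >= isolation_s,
        d[length(d)] >= isolation_s)
    }
    for (s_idx in which(gaps_ok)) {
      ts <- st[s_idx]
      k0 <- floor(ts * fs) + 1L            # frame containing the spike
      kk <- k0 + seq_len(n_frames)
      if (max(kk) > length(v)) next
      t_start <- (kk - 1) / fs
      xs <- c(xs, t_start - ts)
      ys <- c(ys, v[kk])
      n_tr <- n_tr + 1L
    }
  }
  if (n_tr < 3L) stop("too few isolated transients to fit kinetics")
  fit <- stats::nls(
    y ~ A * tau * fs * (1 - exp(-1 / (tau * fs))) * exp(-x / tau),
    data = data.frame(x = xs, y = ys, fs = fs),
    start = list(A = max(0.1, stats::median(ys) * 2), tau = 0.25),
    control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
  cf <- stats::coef(fit)
  list(dff_amplitude = unname(cf["A"]), tau_1e_s = unname(cf["tau"]),
       n_transients = n_tr, n_points = length(xs))
}

#' Baseline photon rate from transient-free frames
#'
#' Unbiased baseline estimate for traces whose spike times are known: the
#' mean count over frames that start at least `settle_s` after every
#' preceding spike, times the frame rate. Complements [baseline_f0()], whose
#' lower-quantile convention is deliberately a robust lower bound in the
#' presence of unknown activity.
#'
#' @param tr A [trace()] of per-frame counts.
#' @param spike_times_s Known spike times (s).
#' @param settle_s Time after a spike before frames count as baseline (s).
#' @return Baseline rate in counts/s (photons/s for photon-count traces).
#' @export
baseline_rate_from_truth <- function(tr, spike_times_s, settle_s = 2) {
  stopifnot(inherits(tr, "trace"))
  fs <- tr$frame_rate_hz
  t_start <- (seq_along(tr$values) - 1) / fs
  quiet <- rep(TRUE, length(t_start))
  for (ts in spike_times_s) {
    quiet <- quiet & (t_start + 1 / fs <= ts | t_start >= ts + settle_s)
  }
  if (!any(quiet)) stop("no transient-free frames available")
  mean(tr$values[quiet]) * fs
}
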