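---
title: "Photon budgets, detectability and trace extraction for deep three-photon imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon budgets, detectability and trace extraction for deep three-photon imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deep3pm)
```

Deep three-photon microscopy (3PM) trades off excitation, collection and
detection against tissue scattering. This vignette is the package's account
of the models it implements, the assumptions behind them, the defaults and
why they were chosen, and what the synthetic-data tests do and do not
demonstrate about real data.

## Excitation photon budget

Three-photon fluorescence per unit time scales as
$\langle F \rangle \propto E_{focus}^2 \cdot P_{focus} / \tau^2$, the
cube-law in focal intensity re-expressed through pulse energy and average
power. Ballistic excitation attenuates as $e^{-z/\mathrm{EAL}}$; the package
generalizes this to piecewise-constant EAL layers (surface first, the last
layer extended to infinity), because cortical grey matter, white matter and
deep grey attenuate differently. All proportionality constants
(cross-section, quantum yield, collection) are fixed to 1: only *ratios*
between configurations are meaningful, and every public quantity is either a
ratio or an energy/rate with explicit units (µm, nJ, mW, Hz, s — unit
suffixes are part of every field name, conversions happen only at I/O
boundaries).

Two hardware caps define the deep-imaging operating point: average surface
power (~100 mW, tissue heating) and focal pulse energy (~2 nJ, fluorophore
saturation and nonlinear damage). Under both caps the signal-maximizing
repetition rate is $f(z) = e^{-z/\mathrm{EAL}} \cdot P_{surf}/E_{focus}$,
i.e. 50 MHz at the surface and ~100 kHz around six attenuation lengths.
`budget_depth_table()` tabulates the whole operating line;
`check_constraints()` reports violations as data rather than errors so a
planning loop can sweep configurations.

Assumptions worth stating: no fluorophore saturation dynamics, no heating
model beyond the fixed power cap, no absolute yield prediction. Pulse-width
comparisons default to equal $\tau$ (the classic "100× at equal average
power" comparison holds $\tau$ fixed); `signal_ratio(..., allow_unequal_tau
= TRUE)` enables cross-width comparisons through the $(f\tau)^{-2}$ term.

The in vivo EALs of any given preparation are measured quantities; the
package ships a documented placeholder default of 300 µm typical for
1300-nm excitation in cortex, and every function takes the tissue model as
an argument. Raw objective displacements underestimate true depth because
brain tissue is optically denser than the immersion water; the calibration
factor defaults to 1.075, the midpoint of the typical 5–10% range.

## Collection geometry

Scattered emission exits the surface over a diffuse spot whose FWHM is
about 1.5× the imaging depth. The package treats that FWHM as the spot
diameter outright — no Gaussian-tail modeling — because the quantities of
interest are the published 80%-throughput FOV diameters, and the squared
undersize ratio $(\mathrm{required\ FOV}/\mathrm{collection\ FOV})^2$ is
exactly the arithmetic behind the known ~11-fold penalty of a 1-mm FOV at
2 mm depth. The penalty saturates at 1: no credit is given for a FOV larger
than required, since the 80%-throughput convention already absorbs the
absolute efficiency. `collection_gain()` exposes the NA² factor and the FOV
penalty ratio as separate factors of its result, so a user can attribute a
gain either way; whether a published "tenfold" figure includes the NA ratio
of the specific objectives being compared is a reading the caller controls.

## Transient detectability

For a transient of amplitude $\Delta F/F$ with instantaneous rise and
exponential decay $\tau_{1/e}$ on a Poisson baseline of $F_0$ photons/s, the
matched-filter discriminability is

$$ d' = \frac{\Delta F}{F}\sqrt{\frac{F_0\,\tau_{1/e}}{2}}. $$

Defaults are jGCaMP8s-like in vivo values: $\Delta F/F = 0.7$ per action
potential and $\tau_{1/e} = 0.29$ s (derived from the ~200 ms in vivo
half-decay via $\tau = t_{1/2}/\ln 2$; the constructor cross-checks the two
within 2% when both are supplied). `required_f0()` returns the exact
inversion $F_0 = 2 d'^2 / ((\Delta F/F)^2 \tau_{1/e})$; `budget_table()`
also prints nearest-integer display values, the convention for photon-rate
tiers. Note a rounding subtlety: the conventional 99%-confidence tier is
quoted as ≈305 photons/neuron/s, which corresponds to the unrounded
$d' = 2\Phi^{-1}(0.99) = 4.6527$; inverting the two-decimal $d' = 4.65$
gives 304. The table reports the faithful inversion of whatever $d'$ list
it is given.

The d′↔confidence mapping is the equal-variance Gaussian observer with an
unbiased criterion, $\Phi(d'/2)$. That criterion reproduces the standard
99/97/95/93% pairings for $d' \in \{4.65, 3.76, 3.29, 2.95\}$ but is an
inference — photon-budget tables rarely state their criterion — and is
documented as such.

`monte_carlo_dprime()` is the independent oracle: paired Poisson trials on a
frame grid (transient onset at $t=0$, per-frame rates integrated at the
frame midpoint), scored by the $e^{-t/\tau}$ matched filter on
mean-subtracted counts. The empirical statistic divides the mean score
separation by the **null**-score standard deviation, because that is the
matched-filter SNR the analytic formula describes. A symmetric
pooled-variance denominator (available via `pooled = TRUE`) is *not* the
default: transient trials carry extra Poisson variance —
$\mathrm{Var}_{sig} = \mathrm{Var}_{null}(1 + (\Delta F/F)/3)$ for this
kernel — so pooling sits a scale-invariant ~10% below the analytic value at
$\Delta F/F = 0.7$ and would never converge to it at any photon rate. The
test suite verifies both the null-referenced agreement (within Monte-Carlo
error at $F_0 \in \{500, 1000, 5000\}$ photons/s, 20 000 trials) and the
predicted pooled-to-null ratio. Defaults: 2-s window (> 6 decay constants;
shorter windows are flagged in the result, not silently accepted),
bootstrap standard errors, one explicit seed for all randomness.

The model treats $F_0$ as the neuron's clean baseline rate; neuropil
contamination is not modeled (and neuropil subtraction is out of scope).

## SBR analysis

SBR is the mean pixel value inside a signal ROI divided by the mean in an
adjacent background ROI on the same slice — hand-drawn background regions
(e.g. inside dark vessel lumens), never automatic detection. A
zero-background slice yields `Inf` with a flag rather than a pseudo-count,
and the depth-limit search skips such slices; imposing a floor would
manufacture a crossing. The depth limit (SBR = 1 by convention) is located
by log-linear interpolation between the bracketing slices, since SBR decays
roughly exponentially with depth.

`estimate_eal()` inverts the cube law: with per-slice surface energies
$E(z)$, $\ln(S^{1/3}/E)$ is linear in depth with slope $-1/\mathrm{EAL}$.
The cube-root transform follows from signal $\propto P_{focus}^3$, and the
energy normalization makes the estimate valid under depth-ramped excitation.
Confidence intervals come from bootstrapping depth points. Degenerate
inputs — constant signal, fewer than 4 depths, non-negative slope — are
errors, not NaNs.

Conventions: ROI coordinates and slice indices are 0-based (row, col),
matching Fiji/Python exports; line profiles sample nearest pixels at 1-px
arclength steps because photon counts are integers and interpolation would
break their semantics; `histogram_stretch()` clips 0.2–0.5% tails for
display only and is never used in quantification.

## Trace pipeline

The stages mirror standard photon-counting practice, in order: ROI
integration over a somatic mask (~100 px at a 100-µm field), optional
initial-segment discard (`discard_initial_s`, default 0; indicator
photobleaching settles over the first ~15 min of a real session, which the
synthetic generator does not emulate), Hamming low-pass, lower-quantile
baseline, ΔF/F, and the baseline-rate fidelity flag at 150
photons/neuron/s. Filtering precedes normalization by default;
`normalize_first` swaps the order, which matters little for the smooth
3-tap window but is exposed because the convention varies.

Numerical choices that needed deciding:

* **Hamming window length.** The "0.29 s time constant" is read as the
  window *duration*; the tap count is `round(0.29 · frame rate)`, forced
  odd (zero phase) with a 3-tap minimum. At 6.18 Hz that is 3 taps.
  Coefficients are normalized to unit DC gain; edges are handled by
  reflection.
* **Lower-20% baseline.** $F_0$ is the *mean of the samples at or below*
  the 20th percentile, not the percentile value; the fraction is a
  parameter since the convention is approximate. This statistic is a
  deliberately robust *lower* bound in the presence of unknown activity:
  for a Poisson baseline of mean $\mu$ per frame it sits about
  $1.4\,\sigma_{\!f}$ below $\mu$ (where $\sigma_{\!f}$ is the
  post-filter noise SD), i.e. a ~15% underestimate at ~50 counts/frame and
  vanishing for brighter traces. That bias direction is conservative for
  the fidelity flag (a trace certified ≥ 150 photons/s truly is), and ΔF/F
  amplitudes read against it are correspondingly upper bounds. Parameter
  *recovery* on synthetic data therefore estimates the baseline from
  ground-truth transient-free frames (`baseline_rate_from_truth()`), which
  is unbiased.
* **Median video filter.** Exact per-voxel median over the
  (2·1+1)×(2·1+1)×(2·18+1) neighborhood (the 18-frame temporal radius spans
  ~3 s at 6.18 Hz), truncated at the array edges — no invented padding —
  with the 9-frame edge trim applied as a separate composable step
  (`trim_edges()`), matching the published display pipeline. The filter is
  for video presentation; quantitative traces are extracted from unfiltered
  counts.

All stages are pure functions; `process_session()` is bitwise reproducible
given its inputs.

## Synthetic data: what it emulates, and what it does not

`make_structural_stack()` renders vessels (sinusoidal tubes crossing the
field; optionally somata with nuclear exclusion) and draws independent
Poisson counts around per-slice means: signal from the optics model (an
excitation ramp holding 2 nJ at the focus until a 1 µJ surface cap, or a
constant-energy variant for attenuation studies) and background from
$\mathrm{SBR}(z) = \mathrm{SBR}_0^{\,1 - z/z_{lim}}$ — log-linear decay to
1 at the recipe's depth limit, the simplest monotone model consistent with
how SBR-depth curves are used; the generator pins only the SBR = 1
endpoint, which is the quantity under test. Pixels inside the geometry draw
around the signal mean (which, as in real ROI measurements, implicitly
contains the background under it), so measured ROI ratios estimate the
generating SBR directly. Defaults: SBR₀ = 100 and a 2.5-mm depth limit — the
regime of vasculature imaging at the three-photon depth limit.

`make_activity_movie()` emulates the deep functional configuration: 44
neurons in a 100-µm field (120 × 120 px) at 6.18 Hz, somata 10–15 µm with
60% of the photon rate in a 2-px cytoplasmic ring (nuclear exclusion),
baseline 305 photons/neuron/s (the 99%-confidence tier), sparse Poisson
spiking at 0.1 Hz typical of quiet deep-brain recordings, and a dim uniform
background (0.12 photons/px/s) consistent with somatic SBR well above 10 at
these depths. Transient rates are integrated *exactly* over each frame
interval, so consecutive-frame ratios preserve the decay constant; at
6.18 Hz a 0.29-s transient integrated over a 0.162-s frame retains ~77% of
its instantaneous peak, and `fit_transient_kinetics()` deconvolves that
known factor when recovering ΔF/F — an exact correction, not a fitted one.

Deliberately not modeled: optical PSF and out-of-focus blur, detector noise
beyond Poisson (deep 3PM photon counting is shot-noise limited), vascular
branching, neuropil, motion (motion correction is delegated to external
tools), and photobleaching. Passing recovery tests therefore demonstrate
that the *estimators are correct under the stated statistical model* —
Poisson counts, exponential transients, known ROIs — not that they are
robust to segmentation error, motion residue or neuropil contamination in
real recordings.

Every stochastic generator takes one explicit seed and is bitwise
reproducible; every downstream recovery test reads only the returned ground
truth, never generator internals.

## Problem sizes used in the test suite

Synthetic validations run at desk scale, chosen to keep the suite fast
while leaving comfortable statistical margin: stacks of 26 × 64 × 64 voxels
for depth-limit recovery (measured ~1% error against the generating
2500 µm), 10-slice stacks for EAL recovery across 200/300/400 µm (~1%
error, 10% tolerance), 120-s 44-neuron sessions for trace recovery
(baseline < 2%, ΔF/F ~3%, τ ~5% observed error against 10% tolerances), and
20 000-trial Monte-Carlo runs for the d′ oracle. In vivo quantities that
require real tissue — measured EALs, measured SBR-depth curves, actual
depth records — are outside what synthetic data can certify.

## Known limitations

* The layered-EAL model is ballistic-only; it has no diffuse excitation
  component, so it extrapolates poorly past ~10 attenuation lengths.
* The collection model is geometric; it will misestimate objectives whose
  throughput falls off gradually rather than at a sharp 80% FOV edge.
* `d3pm_cli()` covers the common workflows; programmatic use of the
  underlying functions is the primary interface.
* The lower-quantile baseline's small-count bias is documented above rather
  than corrected; bright traces (≥ several hundred counts/frame) make it
  negligible.
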