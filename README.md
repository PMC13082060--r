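# deep3pm

Quantitative models and analysis tools for **deep-tissue three-photon
microscopy (3PM)**: the excitation photon budget through scattering brain
tissue, the collection-side field-of-view geometry, the d′ detectability of
single calcium transients under a Poisson photon budget, signal-to-background
(SBR) quantification on image stacks, and the activity-trace extraction
pipeline — plus seeded synthetic-data generators so the whole chain can be
exercised and validated without instrument data.

The package is aimed at microscopists planning or analyzing deep (≳ 1 mm)
3PM experiments: choosing pulse energy and repetition rate for a target
depth, sizing the collection optics, budgeting photons for calcium-imaging
fidelity, and processing photon-counting stacks and movies.

## The models

**Excitation budget.** Time-averaged three-photon fluorescence scales as

    ⟨F⟩ ∝ E_focus² · P_focus / τ²,

with pulse energy and average power attenuated ballistically through layered
tissue, `E_focus = E_surface · exp(−Σᵢ Δzᵢ/EALᵢ)` (EAL = effective
attenuation length). With the surface power capped by heating (~100 mW) and
the focal pulse energy capped by saturation/nonlinear damage (~2 nJ), the
signal-maximizing repetition rate is

    f(z) = exp(−z/EAL) · P_surface/E_focus  =  exp(−z/EAL) · 50 MHz,

about 100 kHz around six attenuation lengths — the deep-imaging operating
point.

**Collection geometry.** Fluorescence from depth `z` exits the tissue over a
diffuse spot of FWHM ≈ 1.5 z, so the required collection FOV is
`1.5 z + scan FOV` and an undersized collection FOV costs the squared ratio
in efficiency (collection efficiency ∝ NA² · FOV²).

**Transient detectability.** For an indicator transient of amplitude ΔF/F
and exponential decay τ₁ᵉ on a baseline of F₀ photons/s, the matched-filter
discriminability of a single transient is

    d′ = (ΔF/F) · √(F₀ · τ₁ᵉ / 2),

validated in-package by a Monte-Carlo matched-filter simulation on Poisson
counts.

**Trace pipeline.** ROI integration → Hamming low-pass (0.29 s) →
lower-20% baseline F₀ → ΔF/F = (F−F₀)/F₀, with a 3-D median video filter
(radii 1 px/1 px/18 frames ≈ 3 s at 6.18 Hz) and 9-frame edge trim for
display, and a 150 photons/neuron/s fidelity check on the baseline rate.

## Worked example

```r
library(deep3pm)

tissue <- tissue_optics_model()          # uniform 300-um EAL placeholder
budget_depth_table(tissue, c(0, 500, 1000, 1500, 2000))
#>   z_um attenuation efocus_nj esurface_nj rep_rate_hz relative_signal
#> 1    0     1.00000         2         2.0    50000000         1.00000
#> 2  500     0.18888         2        10.6     9443780         0.18888
#> 3 1000     0.03567         2        56.1     1783700         0.03567
#> 4 1500     0.00674         2       296.8      336897         0.00674
#> 5 2000     0.00127         2      1571.5       63632         0.00127
```

Reading the 2000-µm row: holding 2 nJ at the focus requires ~1.6 µJ at the
surface, and the 100 mW heating cap then forces the repetition rate down to
~64 kHz — the reason deep 3PM runs near 100 kHz rather than the 1 MHz
typical of shallower work. The relative signal column is per unit time at
the capped operating point, so it falls with the rate itself.

```r
kin <- indicator_kinetics()              # jGCaMP8s-like: dF/F 0.7, tau 0.29 s
budget_table(kin)
#>   dprime confidence required_f0 required_f0_int
#> 1   4.65     0.9900       304.3             304
#> 2   3.76     0.9699       199.0             199
#> 3   3.29     0.9500       152.3             152
#> 4   2.95     0.9299       122.5             122
```

A neuron emitting ≥ 152 baseline photons/s supports 95%-confidence detection
of a single transient; ≥ ~305 photons/s reaches 99%.

```r
lfov <- collection_geometry(1.0, 4, 0.3, "LFOV")
conv <- collection_geometry(1.05, 1, 0.3, "conventional 25x")
collection_depth_table(lfov, conv, c(1, 1.5, 2, 2.5))
#>   z_mm required_fov_mm penalty_a penalty_b gain_a_over_b
#> 1  1.0            1.80      1.00      3.24          2.94
#> 2  1.5            2.55      1.00      6.50          5.90
#> 3  2.0            3.30      1.00     10.89          9.88
#> 4  2.5            4.05      1.03     16.40         14.51
```

At 2 mm depth the emission spot spans ~3 mm, so a 1-mm collection FOV pays
an ~11-fold penalty while a 4-mm FOV collects essentially everything —
roughly a tenfold collection gain, and together with the ~100× excitation
gain of a 1 µJ/100 kHz source over a 0.1 µJ/1 MHz one, a combined ~1000×.

Synthetic data exercise the full analysis loop:

```r
res  <- make_structural_stack(stack_recipe(seed = 11))   # SBR=1 at 2500 um
prof <- sbr_depth_profile(res$stack, ...)                # per-slice ROI pairs
depth_limit(prof)                                        # ~2500
```

A command-line wrapper (`inst/cli/deep3pm`) exposes the same operations as
subcommands (`budget`, `collection`, `detect`, `sbr`, `traces`,
`filter-video`, `simulate`); see `inst/extdata/config-example.yaml` for the
configuration format.

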