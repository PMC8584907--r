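---
title: "Methods: THz time-domain dielectric analysis of hydration shells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: THz time-domain dielectric analysis of hydration shells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thzhydrate)
```

## The problem

Dissolved carbohydrates perturb the dynamics of surrounding water far beyond
the first coordination layer. In the terahertz band (here 10–110 cm⁻¹) the
dielectric response of water separates into contributions with clear
molecular meaning: the high-frequency wing of the cooperative Debye
relaxation of the hydrogen-bond network, a fast (~0.3 ps) relaxation of
free or weakly bound molecules, and the intermolecular stretching vibration
of hydrogen-bonded pairs near 200 cm⁻¹. Tracking how these terms change
between pure water and the water phase of a dilute solution quantifies the
dynamic hydration shell.

This package implements the full analysis chain and a synthetic-data
generator that stands in for the spectrometer, so every stage is testable
without instrument data.

## From pulses to permittivity

THz time-domain spectroscopy records the electric field E(t) of a
picosecond pulse. The package's differential scheme uses the same solution
in two cuvettes whose inter-window gaps differ by Δl (defaults 50.06 µm and
100.26 µm, so Δl = 50.2 µm): the thick-cuvette trace is the "sample", the
thin-cuvette trace the "background". Windows, interface reflections and the
source spectrum cancel in the ratio, leaving a solution layer of thickness
Δl. Internal (Fabry–Pérot) reflections inside the thin water layer are not
deconvolved: the differential scheme suppresses them to first order, and
the generator omits them by default (`make_pulse_pair(etalon = TRUE)`
injects one round trip to study the residual error).

After Fourier transformation (`fourier_spectrum`: zero-padding, amplitude
and unwrapped phase interpolated onto the analysis grid), power
transmission and refractive index follow as

* Tr(ν) = (|S|/|B|)², and
* n(ν) = 1 + Δφ/(2πνΔl),

and the complex permittivity (convention ε\* = ε′ + iε″, ε″ ≥ 0 for passive
media) as

* ε′ = n² − [ln Tr/(4πνl)]²,
* ε″ = −n ln Tr/(2πνl),

which is exactly (n + iκ)² with κ = −ln Tr/(4πνl). Note that these
formulae take Tr as *power* transmission; the squared amplitude ratio is
therefore what `optics_from_pair` stores.

Phase unwrapping is anchored at the low-frequency end; the residual 2π
branch is resolved by requiring n ≥ 1 and choosing the branch whose
band-average index is closest to a water-like anchor (default 2.3,
adjustable via `n_anchor`). Windowing before the FFT is configurable
(`none` or a trailing-half Hann taper); the default is `none`, because the
differential scheme cancels window bias to first order.

Cuvette gaps are calibrated from the etalon fringes of the empty cuvette
(`etalon_thickness`): d = 1/(2 n_gap Δν̄). Fringe maxima are located by
local-extrema detection on the lightly smoothed transmission, with the
minimum peak separation seeded by a periodogram estimate of the fringe
period (robust to amplitude drift and percent-level noise); the mean
spacing is the slope of a least-squares line of peak position versus index.
The analysis band itself (10–110 cm⁻¹) holds barely one fringe of a 50 µm
gap, so calibration spectra must span a wider band, as in the FTIR-based
procedure this mimics.

Instrument resolution is ~4 cm⁻¹ while the analysis grid has 250 points;
values between transform bins are obtained by linear interpolation (of
amplitude and unwrapped phase), a choice the pipeline records in its
configuration.

## Removing the solute: effective-medium inversion

A dilute solution is treated as a biphasic system: water host with solute
inclusions at volume fraction f = mass concentration × specific volume
(≈0.03 for all presets). Two mixing rules are implemented, chosen
explicitly by geometry, never inferred:

* **Maxwell Garnett** (`mg_forward` / `mg_invert`) for small spherical or
  chaotically oriented inclusions — monosaccharides;
* a **dilute fiber-inclusion model** (`fiber_forward` / `fiber_invert`),
  εs = εw + f(εc−εw)(5εw+εc)/(3(εw+εc)), for polysaccharides.

Both inversions reduce to complex quadratics in εw. Because printed
closed-form radicals are easy to mistranscribe, the inversion contract here
is *exact satisfaction of the forward relation*: the implementation solves
the quadratic, and the explicit closed form (`fiber_invert_closed`) is
cross-checked against an independent `polyroot` solve in the test-suite.
Root selection keeps roots with ε″ ≥ −10⁻⁹ and ε′ > 0, prefers the root
closer to εs, and enforces continuity along the frequency grid. Both
directions round-trip to ≤10⁻¹⁰ relative error on random physical inputs.

The solute spectrum εc\*(ν) comes from measurements of dry amorphous
material (no phonon bands — crystalline resonances would not exist in the
dissolved state and would corrupt the subtraction). The generator models it
as a low-order polynomial; defaults are flat placeholders (≈3.0 + 0.2i
monosaccharide-like, ≈2.6 + 0.15i polysaccharide-like). No quantitative
result of the pipeline depends on these defaults — only round-trip tests
do, by construction.

## The dielectric model and the fit

The water-phase permittivity is modelled as

ε\*(ω) = Δε₁/(1−iωτ₁) + Δε₂/(1−iωτ₂) + A/(ω₀²−ω²−iωγ) + ε∞ + iσ₀/(ε₀ω),

with ω = 2πcν. Parameters and units: Δε₁, Δε₂ dimensionless strengths;
τ₁, τ₂ in ps; ω₀, γ in cm⁻¹ (converted to rad/s internally); the oscillator
amplitude is handled as the dimensionless ratio A/ω₀²; σ₀ in S/m.

Three parameters are fixed, six are fitted:

* **τ₁ = 8.28 ps** (pure water, 25 °C). Only the high-frequency wing of the
  slow Debye band lies in 10–110 cm⁻¹, so its time and strength cannot be
  separated; fixing τ₁ lets Δε₁ absorb the binding-induced change.
* **ε∞ = 2.5**, characteristic of dilute aqueous solutions near ω₀.
* **σ₀**, measured separately per solution; below 0.008 S/m it is set to
  exactly zero (presets: 1.3 S/m for galacturonic acid, 1.86 S/m for
  polygalacturonic acid, 0 otherwise).

The criterion is the mean squared *relative* deviation, each residual
normalised by the **model** value (kept as published, although normalising
by the experiment is more common):

s = (1/N) Σ [((ε′mod−ε′exp)/ε′mod)² + ((ε″mod−ε″exp)/ε″mod)²].

`fit_model` minimises the stacked relative residuals with bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`, finite-difference Jacobian);
the mean of squares of that residual vector is exactly s. Bounds
(Δε₁ ∈ [20, 120], Δε₂ ∈ [0.1, 10], τ₂ ∈ [0.05, 2] ps, ω₀ ∈ [120, 350] cm⁻¹,
γ ∈ [50, 500] cm⁻¹, A/ω₀² ∈ [0.3, 5]) are generous envelopes around the
water values whose main job is to prevent the two Debye terms from swapping
roles. Multistart (default 8 starts, seed 0): the first start is the
pure-water reference row, the rest jitter each parameter uniformly by
±30%. Parameters pinned at a bound raise a warning; a per-replicate s above
0.0021 — the worst value observed in practice — is logged as a warning by
the pipeline, not an error.

## The free-water statistic

The fast-relaxation strength converts to the percentage of water molecules
with an unoccupied hydrogen-bond vacancy:

n = 3Δε₂/((Δε₂+E)·E) · 9kTε₀/(Np²) · 100 %,  E = ε∞ + A/ω₀² + 2.

Constants are kept at their conventional 3-digit values
(k = 1.38×10⁻²³ J/K, p = 6.17×10⁻³⁰ C·m, N = 6.02×10²³ × 55.56×10³ m⁻³,
T = 298.15 K) so that published percentages are reproduced on their own
terms; ε₀ is the SI value. With the reference strengths for pure water
(Δε₂ = 2.691, A/ω₀² = 1.702) this gives:

```{r}
free_water_from_strengths(2.691, 1.702)
```

Recomputing n from rounded replicate-mean strengths reproduces the
reference column to about ±0.02; the package also computes n per replicate
and aggregates, which is the preferred route for new data (the two differ
only in the rounding of the inputs, since n is smooth in its arguments).
The identification of the oscillator ratio in E with A/ω₀² of the model is
confirmed numerically by the pure-water row.

## The synthetic generator as a study design

`simulate_replicates` emulates the study conditions: 250-point 10–110 cm⁻¹
spectra, water-phase permittivity from the model with the reference
parameter sets, mixing at f ≈ 0.03 with the preset geometry, and at least
20 replicates per sample. Replicate noise has two parts:

* multiplicative point noise, default 0.2% per spectral point (residual
  noise after heavy pulse averaging);
* replicate-level parameter jitter with per-parameter standard deviation
  2.14 × the reference 95% CI half-widths — 2.14 = √20/t₀.₀₂₅,₁₉, the
  factor under which a 20-replicate t-interval reproduces the reference CI
  magnitudes. Slow inter-replicate drift, not point noise, dominates real
  replicate scatter, and this is the simplest model with that property.

What the generator does **not** emulate: detector dark noise and delay-line
jitter, cuvette-window dispersion, water-vapour absorption lines, and (by
default) internal reflections. Passing tests therefore demonstrate the
correctness and stability of the *analysis*, not robustness to every
instrumental artifact.

Everything is seeded; replicate r of seed S uses an independent stream
derived from (S, r), and generation never disturbs the caller's RNG state.

## Numerical choices and degenerate inputs

* Unit conventions at interfaces: wavenumber cm⁻¹, time ps, thickness µm,
  conductivity S/m, temperature K; conversion to SI angular frequency
  happens once, inside `eval_model` and the optics.
* The conductivity term diverges at zero frequency; grids must be strictly
  positive, and the static-limit identity ε′(0) = Δε₁+Δε₂+A/ω₀²+ε∞ is
  checked at 0.001 cm⁻¹.
* Effective-medium inversions refuse inputs where no root is physical and
  report both roots; `medium_invert` clips loss in (−10⁻⁹, 0) to zero to
  absorb rounding at f → 0.
* Problem sizes in the test-suite: property loops use 10³ random inputs;
  end-to-end recovery uses 20 replicates × 250 points, the study's own
  scale, and completes in seconds.

## Known limitations

* The fiber model is the dilute, orientation-averaged simplification; it is
  warned against above f = 0.1 and refused above f = 0.3.
* τ₁ fixed at the pure-water value biases Δε₁ slightly for strongly bound
  systems; this is inherent to the band analysed.
* The free-water statistic inherits the rounding of its 3-digit constants;
  it is a comparative, not an absolute, measure.
* Real dry-solute spectra must be supplied for real data
  (`solute_file` in `run_config`); the built-in solute presets are
  placeholders for simulation only.
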