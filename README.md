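# thzhydrate

Terahertz time-domain dielectric analysis of carbohydrate hydration
shells: from picosecond pulse pairs to the fraction of free water
molecules.

## What it does, and for whom

Dissolved carbohydrates restructure the hydrogen-bond dynamics of the
water around them, and the 10–110 cm⁻¹ (0.3–3.3 THz) band is where those
changes show up. This package is for spectroscopists and biophysicists who
measure dilute aqueous solutions by THz time-domain spectroscopy (THz-TDS)
and want the full, reproducible analysis chain:

1. **Time domain → permittivity.** Dual-thickness referencing: the same
   solution in two cuvettes whose gaps differ by Δl = 50.2 µm; Fourier
   processing gives power transmission Tr(ν) and refractive index
   n(ν) = 1 + Δφ/(2πνΔl), and then the complex dielectric permittivity
   (ε\* = ε′ + iε″)

   ε′ = n² − [ln Tr/(4πνl)]²,  ε″ = −n ln Tr/(2πνl) ≡ (n + iκ)².

   Cuvette gaps are calibrated from etalon fringes, d = 1/(2 n_gap Δν̄).

2. **Solute subtraction.** Complex effective-medium inversion at volume
   fraction f = mass concentration × specific volume (≈ 0.03): Maxwell
   Garnett for spherical/chaotic inclusions (monosaccharides),

   (εs−εw)/(εs+2εw) = f (εc−εw)/(εc+2εw),

   or the dilute fiber-inclusion model for polysaccharides,

   εs = εw + f (εc−εw)(5εw+εc)/(3(εw+εc)),

   each inverted exactly (complex quadratic, physical-root selection).

3. **Decomposition.** Fit of the water-phase permittivity to

   ε\*(ω) = Δε₁/(1−iωτ₁) + Δε₂/(1−iωτ₂) + A/(ω₀²−ω²−iωγ) + ε∞ + iσ₀/(ε₀ω)

   with τ₁ = 8.28 ps, ε∞ = 2.5 and the measured σ₀ fixed, six parameters
   free, minimising the relative criterion
   s = (1/N)Σ[((ε′mod−ε′exp)/ε′mod)² + ((ε″mod−ε″exp)/ε″mod)²].

4. **Free-water statistic.** n = 3Δε₂/((Δε₂+E)E) · 9kTε₀/(Np²), with
   E = ε∞ + A/ω₀² + 2, expressed in percent — the share of water molecules
   with an unoccupied hydrogen-bond vacancy.

A seeded synthetic-data generator (model spectra, effective-medium mixing,
virtual pulse pairs, replicate noise) replaces the instrument, so the whole
chain is testable end to end. See the methods vignette
(`vignettes/thz-hydration-methods.Rmd`) for assumptions and numerical
choices.

## Worked example

Twenty simulated replicates of a 50 mg/mL glucose solution (f = 0.050 ×
0.62 = 0.031, spherical inclusions), inverted, fitted and aggregated:

```r
library(thzhydrate)
cfg <- run_config(
  input = list(simulate = list(sample = "glucose", n_replicates = 20)),
  geometry = "spherical",
  mass_conc_g_cm3 = 0.050, specific_volume_cm3_g = 0.62,
  sample_label = "glucose", seed = 0)
res <- run_pipeline(cfg)
res$table
#>   Carbohydrate          de1           de2       tau2_ps     w0_cm-1
#> 1      glucose 62.51 ± 1.00 2.956 ± 0.042 0.327 ± 0.007 214.6 ± 5.4
#>     gamma_cm-1        A_w0sq       n_pct
#> 1 211.2 ± 12.6 1.820 ± 0.018 3.89 ± 0.04
```

Each entry is the replicate mean ± its 95% confidence half-width. The
generating parameters (Δε₁ = 62.45, Δε₂ = 2.939, τ₂ = 0.326 ps,
ω₀ = 215.9 cm⁻¹, γ = 202.6 cm⁻¹, A/ω₀² = 1.807) all lie inside the
intervals: the pipeline recovers what the simulation put in. The lowered
Δε₁ and raised Δε₂, A/ω₀² relative to pure water are the hydration-shell
signature this analysis is built to detect. The free-water statistic from
the pure-water strengths:

```r
free_water_from_strengths(2.691, 1.702)
#> [1] 3.769042
```

i.e. ~3.8% of molecules relax freely. A command-line front end is
installed as `exec/thzh` (subcommands `simulate`, `tds`, `invert-medium`,
`fit`, `free-water`, `pipeline`, `report`).

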