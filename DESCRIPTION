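Package: thzhydrate
Title: Terahertz Time-Domain Dielectric Analysis of Carbohydrate Hydration Shells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for terahertz time-domain spectroscopy (THz-TDS) of
    aqueous carbohydrate solutions: converts dual-thickness time-domain pulse
    pairs into complex dielectric permittivity spectra, removes the solute
    contribution with complex effective-medium models (Maxwell Garnett for
    spherical inclusions, a fiber-inclusion model for polysaccharides),
    decomposes the water-phase permittivity into two Debye relaxations, a
    damped intermolecular oscillator and a dc-conductivity term, and derives
    the fraction of free (weakly hydrogen-bonded) water molecules. Includes a
    seeded synthetic-data generator that replaces the spectrometer for testing
    and simulation studies.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    pracma,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
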