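Package: photodft
Title: Photophysical Metrics and Conceptual-DFT Reactivity Descriptors for
    Organic Fluorophores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational characterization of quinoline-sulphonamide-class
    fluorophores from solution spectra and electronic-structure output.
    Reads two-column UV-vis absorbance and fluorescence emission spectra,
    locates band maxima with sub-grid parabolic refinement, and derives
    Beer-Lambert molar extinction coefficients, Stokes shifts in
    wavenumbers, and relative quantum yields against a quinine-sulfate
    reference. Computes the conceptual-DFT global reactivity descriptors
    (ionization energy, electron affinity, electronegativity, chemical
    potential, hardness, softness, electrophilicity and the
    electro-donating/accepting powers) from frontier-orbital energies via
    Koopmans' theorem. Post-processes time-dependent DFT excited states:
    parses Gaussian-style log excerpts, converts excitation energies to
    wavelengths, ranks orbital-pair contributions by the closed-shell
    2c^2 convention, and broadens stick spectra into theoretical UV-vis
    curves. A seedable synthetic-data module generates spectra, frontier
    orbital panels and excited-state lists with known ground truth for
    end-to-end parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
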