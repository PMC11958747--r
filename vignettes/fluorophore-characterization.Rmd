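---
title: "Methods: photophysical metrics, reactivity descriptors and TD-DFT post-processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photophysical metrics, reactivity descriptors and TD-DFT post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photodft)
```

photodft characterizes solution-phase organic fluorophores — the motivating
system is a 16-compound quinoline-sulphonamide panel — along three axes:
photophysics from UV-vis/fluorescence spectra, conceptual-DFT reactivity from
frontier-orbital energies, and post-processing of TD-DFT excited states. This
vignette records the models, the tunable parameters, and the numerical and
design choices, so that every number the package produces can be traced to a
stated convention.

## Spectral model and peak analysis

A `spectrum` is a strictly increasing wavelength grid (nm) with one signal
value per point: dimensionless absorbance, emission counts (arbitrary units),
or a broadened theoretical curve. Absorbance may dip slightly negative from
baseline noise; the tolerated excursion is `baseline_tol = 0.005` absorbance
units (configurable), beyond which the input is rejected as not-noise.

Band maxima are reported to 0.01 nm, which is finer than any plausible
instrument step, so `find_lambda_max()` refines the grid argmax with a
parabola through the three surrounding points. For a noiseless Gaussian band
the vertex error is far below half the grid spacing (the property suite
checks this over random centers, widths and steps of 0.5–2 nm). Two
degenerate cases are handled explicitly: a flat spectrum raises a "no peak"
error, and a maximum on the grid boundary is returned unrefined, since a
one-sided parabola would extrapolate.

Integration is trapezoidal. Sub-range integrals interpolate the range
endpoints linearly onto the grid, which makes the integral exactly additive
over contiguous sub-ranges — the property the quantum-yield pipeline relies
on. Point queries (`absorbance_at()`) interpolate linearly and refuse to
extrapolate: an out-of-range query is an error, never a guess, because a
silently extrapolated absorbance corrupts both the extinction coefficient and
the quantum yield downstream.

Optional pre-filtering for noisy data is a centered moving average of odd
width (`smooth_spectrum()`, and `summary_config(smooth_window = ...)` in the
pipeline). It is off by default: on clean data the raw parabolic refinement
is already exact to ~1e-4 nm, and any filter widens the band. Its role under
noise is discussed below.

## Photophysical metrics

Three quantities summarize each compound, all computed by
`summarize_compound()` from one absorbance and one emission spectrum plus
measurement metadata (the bundled defaults: 2×10⁻⁵ M in acetonitrile, 1 cm
path, 340 nm excitation, n = 1.344):

* **Molar extinction coefficient** (Beer–Lambert): ε = A/(c·l), with A the
  absorbance at the absorption maximum, interpolated from the raw (not
  smoothed) spectrum.
* **Stokes shift**, reported in wavenumbers: Δν̃ = 10⁷·(1/λ_abs − 1/λ_emi)
  cm⁻¹ with λ in nm; positive when emission is red-shifted. Reports follow
  the panel-table convention of printing Δν̃ × 10⁻⁴ to 4 decimals.
* **Relative quantum yield** against a reference standard (quinine sulfate
  in 0.5 M H₂SO₄, φ_R = 0.54, for ~340 nm excitation):

  φ = φ_R · (A_R/A) · (I/I_R) · (n²/n_R²)

  with I the integrated emission area and A the absorbance at the
  *excitation* wavelength (not at λ_abs — the comparative method normalizes
  by the light actually absorbed at the excitation line). The
  refractive-index factor is implemented in the standard orientation
  n²/n_R²; printed versions of this relation sometimes show the inverted
  ratio, but in a single-solvent design both ratios are 1 and
  indistinguishable from the data, so the standard form is used and noted
  here. Yields above 1 are physically impossible and indicate a measurement
  or bookkeeping error; they are returned unclamped with a warning so the
  problem surfaces instead of being hidden.

The quantum-yield column of the published panel is *not* recomputable from
printed data (the raw intensities were never published); it is therefore
covered by identity/linearity tests and by synthetic-truth recovery, never by
direct comparison.

### A note on the published Stokes column

Re-deriving the published Stokes-shift column from the published band maxima
(`analysis/02_photophysics.R`) shows the printed column was truncated, not
rounded, at 4 decimals of Δν̃ × 10⁻⁴, and that one row (10f) is internally
inconsistent: its printed shift corresponds to an emission maximum of
428.88 nm rather than the listed 429.9 nm. The package computes the
physically defined quantity and reports the discrepancy rather than
reproducing it.

## Conceptual-DFT reactivity descriptors

From HOMO/LUMO energies (eV), under Koopmans' theorem (I = −E_HOMO,
A = −E_LUMO):

| descriptor | formula | meaning |
|---|---|---|
| gap ΔE | E_LUMO − E_HOMO | excitation/reactivity scale |
| electronegativity χ | (I + A)/2 | electron-attracting tendency |
| chemical potential μ | −χ | escaping tendency of electrons |
| hardness η | (I − A)/2 | resistance to charge redistribution |
| softness S | 1/η (eV⁻¹) | its reciprocal |
| electrophilicity ω | μ²/(2η) | stabilization on electron uptake |
| ω⁻, ω⁺ | (3I+A)²/16(I−A), (I+3A)²/16(I−A) | electro-donating/accepting powers |

Design points: no ΔSCF option is offered (the descriptor set is defined here
by the frontier energies alone, matching how the panel table was built);
softness is carried in eV⁻¹ even where tables annotate it loosely in eV; ω⁻
and ω⁺ have no published reference cells, so they are validated through the
exact identity ω⁻ − ω⁺ = χ, which the property suite checks to 1e-9 on 1000
random records alongside S·η = 1. All ten values are computed and stored at
full precision; rounding happens only in `reactivity_report()` (4 decimals,
half-away-from-zero, ASCII minus, signed zeros normalized).

Re-deriving the published descriptor table from its own printed energies
reproduces 115 of 128 cells exactly at printed precision
(`analysis/03_reactivity.R`). The 13 exceptions — six gap cells and seven
electrophilicity cells, each off by about one unit in the last printed
digit — are exactly the columns most sensitive to digits beyond the printed
four, indicating the source table was computed from unrounded orbital
energies. The implementation does not special-case these cells; the
acceptance suite whitelists them explicitly.

Ranking (`rank_by()`) is a stable sort with ties broken by compound id, so
reports are reproducible run-to-run.

## TD-DFT post-processing

Energy↔wavelength conversion uses hc = 1239.84193 eV·nm (CODATA); this
reproduces the published wavelength/energy pairings to within 0.02 nm over
all 30 rows (max deviation 0.0099 nm), i.e. to their printing precision.

Orbital-pair contributions use the closed-shell convention 200·c²: the
factor 2 reflects the doubly occupied reference determinant, and it is the
only convention under which dominant configurations (|c| ≤ 1/√2) reach the
published 80–99 % range. An `"open"` shell flag switches to 100·c². Symbolic
labels are resolved against a per-molecule HOMO index (H, H−1, …, L, L+1,
…); occupied orbitals below the HOMO are always rendered H−n, since mixed
sign conventions for occupied offsets in printed tables cannot be
disambiguated without the orbital numbering. When no HOMO index is supplied,
raw integer indices are reported verbatim.

Theoretical spectra are built by Gaussian broadening in the *energy* domain:
signal(λ) = Σᵢ fᵢ·exp(−(E(λ) − Eᵢ)²/(2σ²)), default σ = 0.4 eV — a common
empirical linewidth for solution UV-vis band envelopes. By default the curve
is in arbitrary units weighted by oscillator strength; an optional
`prefactor = "epsilon"` mode applies the standard conversion constant
1.3062974×10⁸/σ(cm⁻¹) to yield molar absorptivity.

The log parser reads Gaussian-style excerpts ("Excited State n: …
<E> eV <λ> nm f=<f>" followed by "<i> -> <j> <coefficient>" lines). The
wavelength stored in the file is ignored in favor of recomputation from the
energy, so the hc convention is applied uniformly. Unrecognized lines outside
state blocks are ignored (logs are noisy); a malformed number inside a block
is an error naming the line, never a silent skip. The serializer writes 17
significant digits so that a write/parse round trip is bit-exact — the
property the synthetic-data tests rely on.

## The synthetic-data generator

The generator stands in for the study's unpublished raw spectra. It emulates
the documented measurement conditions — 2×10⁻⁵ M, 1 cm path, 340 nm
excitation, acetonitrile — and draws per-compound truths uniformly inside
the observed panel ranges: λ_abs 337.83–341.73 nm, λ_emi 411.70–429.90 nm,
ε 1.55–2.40×10⁴ M⁻¹cm⁻¹, φ 0.015–0.558.

Modeling choices, and what they do *not* claim:

* **Band shape**: one Gaussian per band. Only a single maximum per compound
  was ever reported, and no raw spectra exist to constrain vibronic
  structure. Default FWHM 25 nm (absorption) and 45 nm (emission) are
  plausible solution-phase values and are configurable; nothing downstream
  asserts the widths themselves, only recovery behavior.
* **Amplitudes**: the absorption peak is ε·c·l (Beer–Lambert); the emission
  area is obtained by inverting the comparative quantum-yield relation, so
  the noiseless pipeline recovers φ by construction — this closure is the
  point: it tests the pipeline, not nature.
* **Noise**: additive homoscedastic Gaussian, parameterized as a fraction of
  peak height. No shot noise, drift, scatter or inner-filter effects; real
  spectra can violate all of these, so passing recovery tests demonstrates
  numerical correctness of the pipeline, not robustness to every instrument
  artifact.
* **Grid**: the instrument step is unknown, so the grid is a parameter
  (default 0.5 nm, ranges 280–400 and 300–540 nm); grids must cover each
  band to ±5σ or the generator refuses, since a truncated band biases areas.
* **Determinism**: every generator accepts a seed and records it in the
  truth manifest; identical seeds give identical artifacts.

### Noisy-data configuration and problem sizes

Error propagation through the three-point parabola shows the vertex noise is
(h/2)·σ_noise√2 / (|f″|h²) for grid step h, and the second difference of a
wide band is tiny: at 0.5 % noise on a 0.5 nm grid the raw refinement jitters
by ~1 nm. Smoothing restores the leverage: vertex noise falls roughly as the
reciprocal of the moving-average width. The documented noisy-data
configuration is `summary_config(smooth_window = 25)` — 12.5 nm at the
default grid, about half the narrower band's FWHM — sized from this analysis
with the 45 nm emission band as the binding case. Positions come from the
smoothed signal; heights, areas and point absorbances always come from the
raw signal, so smoothing introduces no amplitude bias.

The recovery study in the acceptance suite and `scripts/acceptance.R` uses a
16-compound noiseless panel (closure check) and 100 replicate 16-compound
panels at 0.5 % noise (median-error check) — 1600 noisy compounds, which
keeps the full run in seconds while giving stable medians.

## Known limitations

* Descriptors inherit Koopmans' approximation; no ΔSCF or quasiparticle
  corrections.
* The comparative quantum-yield method assumes optically dilute samples and
  identical excitation geometry; no inner-filter or reabsorption correction
  is applied.
* Peak refinement assumes a locally quadratic band top; strongly overlapping
  bands should be windowed explicitly (`abs_window`/`emi_window`).
* The broadening model has a single global σ and no vibronic progression;
  it reproduces band envelopes, not fine structure.
* The log parser targets the excerpt format documented above; it is not a
  general quantum-chemistry log reader.
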