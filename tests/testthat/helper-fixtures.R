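# Shared fixtures, built in code at test time.

gaussian_spectrum <- function(center, sd = 10, grid = seq(center - 60, center + 60, by = 1),
                              height = 1, kind = "absorbance",
                              meta = measurement_meta()) {
  spectrum(grid, height * exp(-(grid - center)^2 / (2 * sd^2)),
           kind = kind, meta = meta)
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

panel_meta <- function() {
  measurement_meta("acetonitrile", concentration_M = 2e-5,
                   path_length_cm = 1, excitation_nm = 340,
                   refractive_index = 1.344)
}
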