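test_that("energy/wavelength conversion uses hc = 1239.84193 eV nm", {
  expect_equal(round_half_up(energy_to_wavelength(3.1911), 2), 388.53)
  expect_equal(energy_to_wavelength(1.23984193), 1000)
  expect_equal(round_half_up(energy_to_wavelength(4.0), 2), 309.96)
  # reciprocal round trip
  e <- seq(1.5, 6, by = 0.01)
  expect_equal(wavelength_to_energy(energy_to_wavelength(e)), e,
               tolerance = 1e-12)
  expect_error(energy_to_wavelength(0), class = "photodft_nonpositive_input")
  expect_error(wavelength_to_energy(-5), class = "photodft_nonpositive_input")
})

test_that("contribution percentages follow the closed-shell 2c^2 convention", {
  expect_equal(contribution_percent(1 / sqrt(2)), 100)
  expect_equal(round_half_up(contribution_percent(0.51473), 2), 52.99)
  expect_equal(contribution_percent(0), 0)
  expect_equal(contribution_percent(0.5, shell = "open"), 25)
  expect_equal(contribution_percent(orbital_transition(50, 51, -0.3)), 18)
  expect_error(contribution_percent(1.2), class = "photodft_bad_coefficient")
  expect_error(orbital_transition(1, 2, -1.01),
               class = "photodft_bad_coefficient")
})

test_that("major_contributions ranks, labels and tie-breaks deterministically", {
  st <- excited_state(1, 3.0, 0.1, list(
    orbital_transition(50, 51, 0.70),
    orbital_transition(49, 51, 0.10)))
  mc <- major_contributions(st, top_k = 2, homo_index = 50)
  expect_equal(mc$percent[1], 98)
  expect_identical(mc$label, c("H -> L", "H-1 -> L"))

  # equal coefficients: ascending (from, to) order decides
  tie <- excited_state(2, 3.2, 0, list(
    orbital_transition(49, 52, 0.4),
    orbital_transition(49, 51, 0.4),
    orbital_transition(48, 53, 0.4)))
  mct <- major_contributions(tie, top_k = 3)
  expect_identical(mct$from_orbital, c(48L, 49L, 49L))
  expect_identical(mct$to_orbital, c(53L, 51L, 52L))

  # top_k beyond the list clamps; empty transition list errors
  expect_equal(nrow(major_contributions(st, top_k = 10)), 2L)
  expect_error(major_contributions(excited_state(3, 3.1, 0), top_k = 1),
               class = "photodft_empty_input")
})

test_that("orbital labels resolve against a stated HOMO index", {
  expect_identical(orbital_label(c(50, 48, 51, 53), homo_index = 50),
                   c("H", "H-2", "L", "L+2"))
  expect_identical(orbital_label(47L), "47")
})

test_that("normalized closed-shell states carry 100 % total contribution", {
  states <- generate_tddft_states(5, 4, seed = 21)
  for (st in states) {
    pct <- sum(vapply(st$transitions, contribution_percent, 0))
    expect_equal(pct, 100, tolerance = 1e-9)
  }
})

test_that("broadened spectra peak at the transition wavelength", {
  grid <- seq(250, 600, by = 0.5)
  st <- excited_state(1, 3.0, 1)
  sp <- broaden_stick_spectrum(list(st), sigma_ev = 0.2, grid_nm = grid)
  expect_identical(sp$kind, "theoretical")
  pk <- find_lambda_max(sp)
  expect_equal(pk$lambda_nm, 1239.84193 / 3.0, tolerance = 1e-4)
  expect_true(all(sp$signal >= 0))

  # far (> 5 sigma) from every state the curve vanishes
  edge <- sp$signal[grid > energy_to_wavelength(3.0 - 5 * 0.2) + 1]
  expect_true(all(edge < 1e-5))

  expect_error(broaden_stick_spectrum(list(st), sigma_ev = 0, grid_nm = grid),
               class = "photodft_nonpositive_input")
  empty <- broaden_stick_spectrum(list(), grid_nm = grid)
  expect_true(all(empty$signal == 0))
})

test_that("energy-domain band areas add linearly in oscillator strength", {
  # oracle: direct trapezoid on a uniform energy grid
  e_grid <- seq(1.5, 5.5, by = 0.001)
  band <- function(states, sigma = 0.2) {
    y <- numeric(length(e_grid))
    for (st in states)
      y <- y + st$oscillator_strength *
        exp(-(e_grid - st$energy_ev)^2 / (2 * sigma^2))
    sum(diff(e_grid) * (y[-1] + y[-length(y)]) / 2)
  }
  one <- list(excited_state(1, 3.0, 0.4))
  two <- list(excited_state(1, 3.0, 0.4), excited_state(2, 3.9, 0.4))
  expect_equal(band(two), 2 * band(one), tolerance = 1e-6)

  # the package's wavelength-domain curve, re-expressed in energy, matches
  grid_nm <- energy_to_wavelength(rev(e_grid))
  sp <- broaden_stick_spectrum(two, sigma_ev = 0.2, grid_nm = grid_nm)
  y_pkg <- rev(sp$signal)
  area_pkg <- sum(diff(e_grid) * (y_pkg[-1] + y_pkg[-length(y_pkg)]) / 2)
  expect_equal(area_pkg, band(two), tolerance = 1e-9)
})

test_that("epsilon prefactor scales the broadened curve by the standard constant", {
  grid <- seq(300, 550, by = 1)
  st <- list(excited_state(1, 3.0, 0.1))
  plain <- broaden_stick_spectrum(st, sigma_ev = 0.4, grid_nm = grid)
  eps <- broaden_stick_spectrum(st, sigma_ev = 0.4, grid_nm = grid,
                                prefactor = "epsilon")
  expect_equal(eps$signal,
               plain$signal * 1.3062974e8 / (0.4 * 8065.543937))
})

test_that("log parsing reads the fixture and survives a round trip", {
  states <- parse_tddft_log(system.file("extdata",
                                        "tddft_10a_synthetic.log",
                                        package = "photodft"))
  expect_length(states, 3)
  expect_equal(states[[1]]$energy_ev, 3.1911)
  expect_equal(states[[1]]$oscillator_strength, 0.0090)
  expect_equal(states[[1]]$transitions[[1]]$coefficient, 0.51473)
  expect_equal(round_half_up(
    contribution_percent(states[[1]]$transitions[[1]]), 2), 52.99)
  expect_identical(states[[2]]$transitions[[2]]$coefficient, -0.26074)

  expect_length(parse_tddft_log(character(0)), 0)
  expect_length(parse_tddft_log("no states in here"), 0)

  bad <- c("Excited State 1: Singlet-A 3.0 eV 413.28 nm f=0.1",
           "  1 -> 2  0.5",
           "  1 -> 3  x.y")
  err <- expect_error(parse_tddft_log(bad), class = "photodft_parse")
  expect_match(conditionMessage(err), "line 3")

  # serialize -> parse reproduces generated states exactly
  gen <- generate_tddft_states(4, 3, seed = 33)
  expect_identical(parse_tddft_log(write_tddft_log(gen)), gen)
  # and via a file on disk
  p <- tempfile(fileext = ".log")
  write_tddft_log(gen, p)
  expect_identical(parse_tddft_log(p), gen)
})
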