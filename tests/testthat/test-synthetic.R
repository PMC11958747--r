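test_that("generators are deterministic under a fixed seed", {
  a1 <- generate_absorption_spectrum(339.63, 1.75e4, noise_sd = 0.002, seed = 41)
  a2 <- generate_absorption_spectrum(339.63, 1.75e4, noise_sd = 0.002, seed = 41)
  expect_identical(a1$spectrum$signal, a2$spectrum$signal)

  f1 <- generate_fmo_panel(16, seed = 42)
  f2 <- generate_fmo_panel(16, seed = 42)
  expect_identical(f1, f2)

  s1 <- generate_tddft_states(3, 3, seed = 43)
  s2 <- generate_tddft_states(3, 3, seed = 43)
  expect_identical(s1, s2)

  p1 <- generate_compound_panel(3, seed = 44, noise_sd_frac = 0.005)
  p2 <- generate_compound_panel(3, seed = 44, noise_sd_frac = 0.005)
  expect_identical(p1, p2)
})

test_that("noiseless absorption bands obey Beer-Lambert at the maximum", {
  gen <- generate_absorption_spectrum(339.63, 1.75e4, conc_M = 2e-5,
                                      path_cm = 1)
  pk <- find_lambda_max(gen$spectrum)
  expect_equal(pk$lambda_nm, 339.63, tolerance = 1e-6)
  expect_equal(pk$height, 0.35, tolerance = 1e-6)
  expect_equal(gen$truth$true_epsilon, 1.75e4)
  expect_error(
    generate_absorption_spectrum(339.63, 1.75e4,
                                 grid_nm = seq(330, 345, by = 0.5)),
    class = "photodft_grid_coverage")
})

test_that("emission areas invert the comparative quantum-yield relation", {
  ref <- default_reference()
  # sample constructed identical to the reference: area equals the ref area
  gen_id <- generate_emission_spectrum(420, 0.54, ref,
                                       abs_at_excitation = ref$absorbance_ref,
                                       refractive_index = ref$refractive_index_ref)
  expect_equal(integrate_signal(gen_id$spectrum),
               ref$integrated_emission_ref, tolerance = 1e-6)

  # noiseless pipeline recovers an arbitrary truth exactly
  gen <- generate_emission_spectrum(427.63, 0.25, ref,
                                    abs_at_excitation = 0.31)
  phi <- relative_quantum_yield(integrate_signal(gen$spectrum), 0.31,
                                ref$refractive_index_ref, ref)
  expect_equal(phi, 0.25, tolerance = 1e-6)
})

test_that("the strongest emitter of the panel range is recovered under noise", {
  ref <- default_reference()
  set.seed(45)
  phis <- replicate(50, {
    gen_a <- generate_absorption_spectrum(341.73, 1.95e4)
    a_exc <- absorbance_at(gen_a$spectrum, 340)
    peak_h <- integrate_signal(
      generate_emission_spectrum(413.06, 0.558, ref, a_exc)$spectrum) /
      (45 / 2.3548 * sqrt(2 * pi))
    gen_e <- generate_emission_spectrum(413.06, 0.558, ref, a_exc,
                                        noise_sd = 0.005 * peak_h)
    relative_quantum_yield(integrate_signal(gen_e$spectrum), a_exc,
                           ref$refractive_index_ref, ref)
  })
  expect_lt(abs(median(phis) / 0.558 - 1), 0.01)
})

test_that("frontier-orbital panels respect ranges and gap positivity", {
  recs <- generate_fmo_panel(16, seed = 46)
  expect_length(recs, 16)
  for (r in recs) {
    expect_s3_class(r, "fmo_record")
    expect_true(r$homo_ev < r$lumo_ev)
    expect_true(r$homo_ev >= -5.93 && r$homo_ev <= -5.41)
    expect_true(r$lumo_ev >= -3.69 && r$lumo_ev <= -2.00)
  }
  expect_error(generate_fmo_panel(5, homo_range = c(-1, 0),
                                  lumo_range = c(-5, -4)),
               class = "photodft_invalid_input")
  # overlapping ranges still yield valid records via resampling
  recs2 <- generate_fmo_panel(200, homo_range = c(-6, -3),
                              lumo_range = c(-5, -2), seed = 47)
  expect_true(all(vapply(recs2, function(r) r$homo_ev < r$lumo_ev, TRUE)))
})

test_that("generated excited states are normalized and ordered", {
  states <- generate_tddft_states(3, 3, seed = 48)
  energies <- vapply(states, function(s) s$energy_ev, 0)
  expect_identical(energies, sort(energies))
  for (st in states) {
    norm2 <- sum(vapply(st$transitions, function(t) 2 * t$coefficient^2, 0))
    expect_equal(norm2, 1, tolerance = 1e-12)
    expect_true(st$oscillator_strength >= 0 && st$oscillator_strength <= 0.2)
  }
  expect_error(generate_tddft_states(0, 3),
               class = "photodft_invalid_input")
})

test_that("a single-compound panel returns one complete tuple", {
  p <- generate_compound_panel(1, seed = 49)
  expect_length(p, 1)
  expect_named(p[[1]], c("absorption", "emission", "fmo", "states", "truth"))
  expect_identical(p[[1]]$absorption$kind, "absorbance")
  expect_identical(p[[1]]$emission$kind, "emission")
  expect_length(p[[1]]$states, 3)
  tr <- p[[1]]$truth
  expect_true(tr$true_lambda_abs_nm >= 337.83 && tr$true_lambda_abs_nm <= 341.73)
  expect_true(tr$true_lambda_emi_nm >= 411.70 && tr$true_lambda_emi_nm <= 429.90)
  expect_true(tr$true_epsilon >= 1.55e4 && tr$true_epsilon <= 2.40e4)
  expect_true(tr$true_phi >= 0.015 && tr$true_phi <= 0.558)
})

test_that("peak-location error grows monotonically with noise", {
  ref <- default_reference()
  set.seed(50)
  med_err <- vapply(c(0, 0.005, 0.02), function(nf) {
    errs <- replicate(100, {
      p <- generate_compound_panel(1, noise_sd_frac = nf)[[1]]
      cfg <- summary_config(smooth_window = if (nf > 0) 11 else NULL)
      s <- summarize_compound(p$absorption, p$emission, ref, config = cfg)
      abs(s$lambda_abs_nm - p$truth$true_lambda_abs_nm)
    })
    median(errs)
  }, 0)
  expect_true(med_err[1] < med_err[2])
  expect_true(med_err[2] < med_err[3])
})
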