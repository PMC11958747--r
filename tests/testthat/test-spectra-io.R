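test_that("CSV reading validates, sorts and rejects malformed input", {
  p <- write_temp_csv(c("wavelength_nm,value", "300,0.1", "301,0.2"))
  sp <- read_spectrum_csv(p, "absorbance", quiet = TRUE)
  expect_s3_class(sp, "spectrum")
  expect_equal(sp$wavelengths_nm, c(300, 301))
  expect_equal(sp$signal, c(0.1, 0.2))

  # out-of-order rows are sorted; comments and blank lines ignored
  p2 <- write_temp_csv(c("# instrument export", "", "301,0.2", "300,0.1"))
  sp2 <- read_spectrum_csv(p2, "absorbance", quiet = TRUE)
  expect_equal(sp2$wavelengths_nm, c(300, 301))
  expect_equal(sp2$signal, c(0.1, 0.2))

  expect_error(read_spectrum_csv(tempfile(), "absorbance", quiet = TRUE),
               class = "photodft_missing_file")
  expect_error(
    read_spectrum_csv(write_temp_csv(c("300,0.1", "300,0.2")),
                      "absorbance", quiet = TRUE),
    class = "photodft_duplicate_wavelength")
  expect_error(
    read_spectrum_csv(write_temp_csv(c("w,v", "300,abc", "301,0.2")),
                      "absorbance", quiet = TRUE),
    class = "photodft_bad_numeric")
  expect_error(
    read_spectrum_csv(write_temp_csv(c("w,v", "300,0.1")),
                      "absorbance", quiet = TRUE),
    class = "photodft_too_few_rows")
})

test_that("write/read round trip preserves full double precision", {
  set.seed(101)
  w <- sort(runif(50, 300, 500))
  s <- rnorm(50)
  sp <- spectrum(w, s, kind = "emission")
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  back <- read_spectrum_csv(path, "emission", quiet = TRUE)
  expect_identical(back$wavelengths_nm, sp$wavelengths_nm)
  expect_identical(back$signal, sp$signal)
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(spectrum(300, 1, "absorbance"),
               class = "photodft_too_few_rows")
  expect_error(spectrum(c(300, 300, 301), c(1, 2, 3), "absorbance"),
               class = "photodft_duplicate_wavelength")
  expect_error(spectrum(c(300, 301), c(1, NaN), "absorbance"),
               class = "photodft_invalid_input")
  # baseline noise below tolerance passes, beyond fails
  expect_s3_class(spectrum(c(300, 301), c(-0.004, 1), "absorbance"),
                  "spectrum")
  expect_error(spectrum(c(300, 301), c(-0.02, 1), "absorbance"),
               class = "photodft_invalid_input")
})

test_that("find_lambda_max refines symmetric peaks and honors windows", {
  # noiseless Gaussian on a 1-nm grid: sub-grid recovery
  sp <- gaussian_spectrum(340, sd = 10, grid = seq(300, 380, by = 1))
  pk <- find_lambda_max(sp)
  expect_equal(pk$lambda_nm, 340, tolerance = 0.01)

  # two bands; window selects the minor one (oracle: brute-force argmax)
  g <- seq(300, 470, by = 1)
  s2 <- exp(-(g - 340)^2 / 200) + 0.6 * exp(-(g - 420)^2 / 200)
  sp2 <- spectrum(g, s2, kind = "absorbance")
  oracle <- g[g >= 400 & g <= 450][which.max(s2[g >= 400 & g <= 450])]
  pk2 <- find_lambda_max(sp2, window = c(400, 450))
  expect_equal(oracle, 420)
  expect_equal(pk2$lambda_nm, 420, tolerance = 0.01)

  expect_error(find_lambda_max(spectrum(1:10, rep(2, 10), "emission")),
               class = "photodft_no_peak")
  expect_error(find_lambda_max(sp2, window = c(480, 500)),
               class = "photodft_empty_window")

  # boundary maximum: no interpolation applied
  mono <- spectrum(1:10, 1:10, kind = "emission")
  expect_identical(find_lambda_max(mono)$lambda_nm, 10)
})

test_that("parabolic refinement recovers Gaussian centers within half a step", {
  set.seed(7)
  for (i in 1:25) {
    center <- runif(1, 330, 350)
    step <- sample(c(0.5, 1, 2), 1)
    sd <- runif(1, 8, 15)
    sp <- gaussian_spectrum(center, sd = sd,
                            grid = seq(280, 400, by = step))
    pk <- find_lambda_max(sp)
    expect_lt(abs(pk$lambda_nm - center), step / 2)
  }
})

test_that("integrate_signal matches closed forms and a brute-force oracle", {
  rect <- spectrum(seq(400, 410, 1), rep(2, 11), "emission")
  expect_equal(integrate_signal(rect), 20)

  tri_g <- seq(400, 410, 1)
  tri <- spectrum(tri_g, pmax(0, 1 - abs(tri_g - 405) / 5), "emission")
  expect_equal(integrate_signal(tri), 5)

  set.seed(12)
  w <- sort(runif(40, 300, 500))
  s <- runif(40)
  sp <- spectrum(w, s, "emission")
  oracle <- 0
  for (i in seq_len(39))
    oracle <- oracle + (w[i + 1] - w[i]) * (s[i] + s[i + 1]) / 2
  expect_equal(integrate_signal(sp), oracle)

  expect_error(integrate_signal(sp, range = c(200, 400)),
               class = "photodft_out_of_range")
})

test_that("integration is additive over contiguous sub-ranges", {
  set.seed(13)
  w <- sort(runif(60, 300, 500))
  sp <- spectrum(w, runif(60), "emission")
  splits <- c(350.7, w[25], 444.444)  # off-grid and on-grid split points
  for (b in splits) {
    lhs <- integrate_signal(sp, c(w[1], b)) + integrate_signal(sp, c(b, w[60]))
    expect_equal(lhs, integrate_signal(sp), tolerance = 1e-9)
  }
})

test_that("absorbance_at interpolates linearly and never extrapolates", {
  sp <- spectrum(c(300, 302, 400, 500), c(0, 1, 1, 0.5), "absorbance")
  expect_identical(absorbance_at(sp, 400), 1)
  expect_equal(absorbance_at(sp, 301), 0.5)
  expect_error(absorbance_at(sp, 299), class = "photodft_out_of_range")
  em <- spectrum(c(300, 301), c(1, 2), "emission")
  expect_error(absorbance_at(em, 300.5), class = "photodft_invalid_input")
})

test_that("smoothing and resampling behave on known signals", {
  sp <- spectrum(1:21, rep(3, 21), "emission")
  expect_equal(smooth_spectrum(sp, 5)$signal, rep(3, 21))
  expect_error(smooth_spectrum(sp, 4), class = "photodft_invalid_input")

  lin <- spectrum(c(0, 10), c(0, 5), "emission")
  rs <- resample_spectrum(lin, c(0, 2.5, 5, 10))
  expect_equal(rs$signal, c(0, 1.25, 2.5, 5))
  expect_error(resample_spectrum(lin, c(-1, 5)),
               class = "photodft_out_of_range")
})

test_that("YAML config populates measurement metadata", {
  p <- tempfile(fileext = ".yaml")
  writeLines(c("solvent: acetonitrile", "concentration_M: 2.0e-5",
               "path_length_cm: 1.0", "excitation_nm: 340"), p)
  m <- read_meta_config(p)
  expect_equal(m$concentration_M, 2e-5)
  expect_equal(m$excitation_nm, 340)
  expect_true(is.na(m$refractive_index))
  bundled <- read_meta_config(system.file("extdata", "meta_default.yaml",
                                          package = "photodft"))
  expect_equal(bundled$refractive_index, 1.344)
})
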