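within_noise_free <- function(cl) {
  p <- class_spectrum_params(cl)
  p$noise_sd <- 0
  p
}

test_that("class spectra carry the expected spectral signatures", {
  # sodium D line dominates salt
  s <- make_emission_spectrum("salt", 1, seed = 1)
  peak <- s$wavelength_nm[which.max(s$intensity)]
  expect_gte(peak, 585)
  expect_lte(peak, 595)

  # pollen: green band; >= 60% of energy inside 450-650 nm, peak in 500-550.
  # Oracle: analytic Gaussian band integrals of the constructed components.
  p <- class_spectrum_params("pollen")
  comp <- rbind(p$lines, p$continuum)
  band_frac <- function(lo, hi) {
    sg <- comp[, "fwhm_nm"] / (2 * sqrt(2 * log(2)))
    areas <- comp[, "amplitude"] * comp[, "fwhm_nm"] * sqrt(pi / (4 * log(2)))
    inside <- areas * (pnorm(hi, comp[, "center_nm"], sg) -
                         pnorm(lo, comp[, "center_nm"], sg))
    sum(inside) / sum(areas)
  }
  expect_gte(band_frac(450, 650), 0.6)
  sp <- make_emission_spectrum("pollen", 1,
                               params = within_noise_free("pollen"))
  pk <- sp$wavelength_nm[which.max(sp$intensity)]
  expect_gte(pk, 500)
  expect_lte(pk, 550)
  # numeric fraction agrees with the analytic oracle
  g <- sp$wavelength_nm
  sel <- g >= 450 & g <= 650
  num_frac <- pracma::trapz(g[sel], sp$intensity[sel]) /
    pracma::trapz(g, sp$intensity)
  expect_equal(num_frac, band_frac(450, 650), tolerance = 0.01)
})

test_that("degenerate and invalid spectra are handled by contract", {
  p <- class_spectrum_params("chalk")
  p$lines[, "amplitude"] <- 0
  p$continuum[, "amplitude"] <- 0
  p$noise_sd <- 0
  s <- make_emission_spectrum("chalk", 1, params = p)
  expect_true(all(s$intensity == 0))

  expect_error(make_emission_spectrum("granite", 1), "unknown particle class")
  expect_error(class_spectrum_params("dust"), "unknown particle class")
  expect_error(emission_spectrum(c(350, 350, 351), c(1, 1, 1)),
               "strictly increasing")
  # constructor clips negative intensities
  expect_true(all(emission_spectrum(1:3, c(-1, 0, 2))$intensity >= 0))
  # params/class mismatch rejected
  expect_error(make_emission_spectrum("salt", 1,
                                      params = class_spectrum_params("chalk")))
  # deterministic under a fixed seed
  expect_identical(make_emission_spectrum("chalk", 1, seed = 9),
                   make_emission_spectrum("chalk", 1, seed = 9))
})

test_that("camera rendering integrates spectra channel-wise", {
  grid <- default_wavelength_grid()
  cam <- camera_model()
  # zero spectrum -> black
  expect_equal(unname(spectrum_to_rgb(emission_spectrum(grid, grid * 0), cam)),
               c(0, 0, 0))
  # narrow line at the R-channel centre with a narrow-response camera:
  # closed-form product-of-Gaussians integral (both centred at 600 nm)
  cam30 <- camera_model(fwhm_nm = c(30, 30, 30))
  line <- emission_spectrum(grid, exp(-4 * log(2) * (grid - 600)^2 / 2^2))
  rgb <- spectrum_to_rgb(line, cam30)
  k <- 4 * log(2)
  expect_equal(unname(rgb["r"]), sqrt(pi / (k * (1 / 2^2 + 1 / 30^2))),
               tolerance = 1e-4)   # trapezoid on a 1 nm grid vs closed form
  expect_lt(rgb["g"], 1e-3)
  expect_lt(rgb["b"], 1e-6)
  # salt renders orange: r > g > b
  srgb <- spectrum_to_rgb(make_emission_spectrum("salt", 1, seed = 2), cam)
  expect_true(srgb["r"] > srgb["g"] && srgb["g"] > srgb["b"])
})
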