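test_that("spectral preprocessing subtracts dark and reference with clipping", {
  grid <- default_wavelength_grid()
  mk <- function(y) emission_spectrum(grid, y)
  flat <- mk(rep(2, length(grid)))
  expect_true(all(process_spectrum(flat, flat, mk(grid * 0))$intensity == 0))

  # reference + pure line recovered exactly
  line <- exp(-4 * log(2) * (grid - 589)^2 / 4)
  ref <- gaussian_ref <- rep(0.3, length(grid))
  out <- process_spectrum(mk(ref + line), mk(grid * 0), mk(ref))
  expect_equal(out$intensity, line, tolerance = 1e-12)

  # random triple: element-wise brute-force oracle
  set.seed(31)
  raw <- runif(length(grid)); drk <- runif(length(grid), 0, 0.5)
  rf <- runif(length(grid), 0, 0.5)
  out <- process_spectrum(mk(raw), mk(drk), mk(rf))
  expect_equal(out$intensity, pmax(raw - drk - rf, 0))

  expect_error(process_spectrum(mk(raw), emission_spectrum(grid + 1, raw), mk(rf)),
               "grids must match")
})

test_that("supra-550 fraction matches closed-form integrals", {
  below <- emission_spectrum(350:500, rep(1, 151))
  above <- emission_spectrum(600:800, rep(1, 201))
  expect_equal(supra550_fraction(below), 0)
  expect_equal(supra550_fraction(above), 1)
  # flat on 350-750: (750-550)/(750-350) = 0.5 exactly
  flat <- emission_spectrum(350:750, rep(3.7, 401))
  expect_equal(supra550_fraction(flat), 0.5)
  # zero spectrum -> 0 by contract
  expect_equal(supra550_fraction(emission_spectrum(350:750, rep(0, 401))), 0)
})

test_that("onset detector recovers the generator's onset power", {
  expect_equal(detect_onset(generate_power_series()), 0.85)
  s50 <- generate_power_series(model = clamping_model(onset_fraction = 0.50))
  expect_equal(detect_onset(s50), 0.50)
  # no broadening -> no onset
  flat <- generate_power_series(model = clamping_model(broad_amplitude = 0))
  expect_true(is.na(detect_onset(flat)))
  expect_error(detect_onset(generate_power_series(powers = c(0.2, 0.5, 1))),
               "at least 4")
})

test_that("clamping model is monotone with flat pre-onset broadening", {
  cm <- clamping_model()
  p <- seq(0.05, 1, by = 0.05)
  sc <- intensity_scale(p, cm)
  expect_true(all(diff(sc) > 0))
  series <- generate_power_series(powers = seq(0.2, 1, 0.05), model = cm)
  fr <- vapply(series, function(el) supra550_fraction(el$spectrum), numeric(1))
  pw <- vapply(series, `[[`, numeric(1), "power_fraction")
  pre <- fr[pw < cm$onset_fraction]
  expect_lt(max(pre) - min(pre), 1e-12)             # flat below onset
  post <- fr[pw >= cm$onset_fraction]
  expect_true(all(diff(post) >= -1e-12))            # non-decreasing above
  expect_gt(min(post[-1]), max(pre))
})

test_that("peak intensity is linear in pulse energy with the documented convention", {
  expect_equal(peak_intensity(laser_params(0.8)),
               2 * peak_intensity(laser_params(0.4)))
  expect_equal(peak_intensity(laser_params(1.0)) /
                 peak_intensity(laser_params(0.2)), 5.0)
  # frozen regression constant from an independent hand calculation of
  # I = 0.94 E / tau * 2 / (pi w0^2), w0 = lambda f / (pi w_in)
  expect_equal(peak_intensity(laser_params(1.0)), 5.802294e15,
               tolerance = 1e-6)
  expect_error(laser_params(-1), "positive|range")
  expect_error(laser_params(2.0), "range")
})
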