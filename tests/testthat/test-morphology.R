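draw_disc <- function(img, cy, cx, r) {
  yy <- row(img) - cy; xx <- col(img) - cx
  img[yy^2 + xx^2 <= r^2] <- 0.9
  img
}

test_that("segmentation finds exactly the constructed particles", {
  img <- matrix(0.02, 400, 400)
  centres <- expand.grid(y = seq(40, 360, 80), x = seq(40, 360, 80))[1:10, ]
  for (i in 1:10) img <- draw_disc(img, centres$y[i], centres$x[i], 15)
  tab <- segment_particles(img, pixel_scale = 0.5)   # d = 15 um discs
  expect_equal(nrow(tab), 10)
  expect_equal(mean(tab$d_eq_um), 15, tolerance = 0.05)

  # size inclusion criterion: 2 um discs are dropped, 10 um kept
  img <- matrix(0.02, 600, 600)
  for (i in 1:5) img <- draw_disc(img, 60, 60 + 100 * (i - 1), 2 / 0.192 / 2)
  for (i in 1:5) img <- draw_disc(img, 300, 60 + 100 * (i - 1), 10 / 0.192 / 2)
  tab <- segment_particles(img, pixel_scale = 0.192, min_diameter_um = 3)
  expect_equal(nrow(tab), 5)
  expect_true(all(tab$d_eq_um > 8))

  # blank image -> empty table
  expect_equal(nrow(segment_particles(matrix(0.02, 50, 50), 0.5,
                                      threshold = 0.5)), 0)
})

test_that("shape metrics match analytic values for canonical shapes", {
  # square: continuum circularity pi/4
  sq <- matrix(0, 140, 140); sq[20:120, 20:120] <- 1
  m <- shape_metrics(sq)
  expect_equal(m$circularity, pi / 4, tolerance = 0.03)
  expect_lt(m$eccentricity, 0.01)
  # large disc: circularity -> 1, eccentricity -> 0
  xx <- row(matrix(0, 160, 160)) - 80; yy <- col(matrix(0, 160, 160)) - 80
  dc <- (xx^2 + yy^2 <= 50^2) * 1
  m <- shape_metrics(dc)
  expect_equal(m$circularity, 1, tolerance = 0.05)
  expect_lt(m$eccentricity, 0.05)
  expect_equal(m$d_eq_um, 100, tolerance = 1)
  # 2:1 ellipse: eccentricity sqrt(1 - 1/4), circularity vs Ramanujan
  el <- (xx^2 / 64^2 + yy^2 / 32^2 <= 1) * 1
  m <- shape_metrics(el)
  expect_equal(m$eccentricity, sqrt(3) / 2, tolerance = 0.01)
  a <- 64; b <- 32
  P_ram <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  expect_equal(m$circularity, 4 * pi * (pi * a * b) / P_ram^2, tolerance = 0.02)
  expect_error(shape_metrics(matrix(c(1, 0, 0, 0), 2, 2)), "degenerate")
})

test_that("pixel scale rescales sizes but not dimensionless shape", {
  xx <- row(matrix(0, 100, 100)) - 50; yy <- col(matrix(0, 100, 100)) - 50
  el <- (xx^2 / 30^2 + yy^2 / 20^2 <= 1) * 1
  m1 <- shape_metrics(el, pixel_scale = 1)
  m2 <- shape_metrics(el, pixel_scale = 2.5)
  expect_equal(m2$d_eq_um, 2.5 * m1$d_eq_um)
  expect_equal(m2$perimeter_um, 2.5 * m1$perimeter_um)
  expect_equal(m2$area_um2, 2.5^2 * m1$area_um2)
  expect_identical(m2$circularity, m1$circularity)
  expect_identical(m2$eccentricity, m1$eccentricity)
})

test_that("segmentation recovers the generator's size and shape statistics", {
  out <- slide_fixture("pollen", 500)
  tab <- segment_particles(out$image, 0.5)
  # every particle found (no merging on the jittered grid)
  expect_equal(nrow(tab), 500)
  expect_lt(abs(mean(tab$d_eq_um) - mean(out$particles$d_eq_um)) /
              mean(out$particles$d_eq_um), 0.05)
  expect_lt(abs(mean(tab$circularity) - 0.86), 0.05)
  out2 <- slide_fixture("salt", 300)
  tab2 <- segment_particles(out2$image, 0.5)
  expect_lt(abs(mean(tab2$circularity) - 0.70), 0.05)
  expect_lt(abs(mean(tab2$d_eq_um) - mean(out2$particles$d_eq_um)) /
              mean(out2$particles$d_eq_um), 0.05)
})

test_that("air-sampler arithmetic follows V = Q t / 1000", {
  s <- sampler_stats(342, flow_lpm = 10, minutes = 9, area_mm2 = 12.2)
  expect_identical(s$volume_m3, 0.09)
  expect_equal(s$concentration_m3, 3800)
  # direct division disagrees with the published rounded ~3.4e3 figure
  expect_false(isTRUE(all.equal(s$concentration_m3, 3.4e3, tolerance = 0.05)))
  expect_equal(s$surface_density_mm2, 342 / 12.2)
  z <- sampler_stats(0)
  expect_equal(z$concentration_m3, 0)
  expect_true(is.na(z$surface_density_mm2))
  expect_error(sampler_stats(10, flow_lpm = 0), "flow_lpm")
  expect_error(sampler_stats(10, area_mm2 = 0), "positive")
})
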