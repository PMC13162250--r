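test_that("blank noise-free frames contain only the stripe", {
  sc <- mini_scene(noise_sd = 0)
  fr <- render_frame("blank", sc, seed = 5)
  bg <- round(sc$background_level * 255) / 255
  stripe_rows <- which(exp(-(seq_len(sc$height) - sc$stripe_row)^2 /
                             (2 * (sc$stripe_thickness / 2)^2)) > 1e-4)
  outside <- fr$pixels[-stripe_rows, , ]
  expect_true(all(outside == bg))
  expect_gt(max(fr$pixels[stripe_rows, , ]), bg)
  expect_equal(nrow(fr$events), 0)
})

test_that("rendering is reproducible bit-for-bit under a fixed seed", {
  a <- render_frame("chalk", mini_scene(), seed = 11)
  b <- render_frame("chalk", mini_scene(), seed = 11)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$events, b$events)
  expect_identical(png::writePNG(a$pixels), png::writePNG(b$pixels))
  c <- render_frame("chalk", mini_scene(), seed = 12)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("event counts are Poisson with the configured class means", {
  sc <- mini_scene()
  n <- vapply(1:1000, function(i)
    nrow(render_frame("chalk", sc, seed = 10000 + i)$events), numeric(1))
  # Monte-Carlo mean recovery: 5 +/- 3 * sd / sqrt(1000)
  expect_lt(abs(mean(n) - 5), 3 * sqrt(5) / sqrt(1000))
  n1 <- vapply(1:300, function(i)
    nrow(render_frame("pollen", sc, seed = 20000 + i)$events), numeric(1))
  expect_lt(abs(mean(n1) - 1), 4 * 1 / sqrt(300))
})

test_that("class chromaticities separate by construction; blank is neutral", {
  sc <- mini_scene()
  # centroids of RENDERED event pixels (top pixels around each event centre),
  # so 8-bit quantisation, stripe mixing and clipping are all included
  event_pixel_chroma <- function(cl) {
    pts <- list()
    for (i in 1:40) {
      fr <- render_frame(cl, sc, seed = 3000 + i)
      if (!nrow(fr$events)) next
      for (k in seq_len(nrow(fr$events))) {
        r <- round(fr$events$y[k]); c <- round(fr$events$x[k])
        if (r < 1 || r > sc$height || c < 1 || c > sc$width) next
        px <- fr$pixels[r, c, ]
        if (sum(px) > 0) pts[[length(pts) + 1]] <- px / sum(px)
      }
    }
    rowMeans(do.call(cbind, pts))[1:2]
  }
  cents <- t(vapply(c("chalk", "pollen", "salt"), event_pixel_chroma,
                    numeric(2)))
  d <- as.matrix(dist(cents))
  expect_gt(min(d[upper.tri(d)]), 0.05)
  # blank's brightest pixels (the stripe) are near-neutral chromaticity
  fr <- render_frame("blank", sc, seed = 77)
  s <- fr$pixels[, , 1] + fr$pixels[, , 2] + fr$pixels[, , 3]
  top <- order(s, decreasing = TRUE)[1:30]
  rg <- cbind(fr$pixels[, , 1][top], fr$pixels[, , 2][top]) / s[top]
  expect_lt(max(abs(colMeans(rg) - 1 / 3)), 0.08)
  # and far from every coloured centroid
  expect_gt(min(sqrt(rowSums(sweep(cents, 2, colMeans(rg))^2))), 0.05)
})

test_that("reducing power strictly reduces expected brightness", {
  p <- c(0.3, 0.6, 0.85, 1)
  sc <- lapply(p, function(pp) mini_scene(noise_sd = 0, power_fraction = pp))
  bright <- vapply(sc, function(s)
    mean(render_frame("blank", s, seed = 1)$pixels), numeric(1))
  expect_true(all(diff(bright) > 0))
  expect_true(all(diff(intensity_scale(seq(0.05, 1, 0.05))) > 0))
})

test_that("events that cannot fit in the frame are rejected", {
  expect_error(render_frame("salt", mini_scene(event_sigma_range = c(30, 30))),
               "exceeds the frame")
})
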