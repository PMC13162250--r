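test_that("cropping splits the frame into two centred squares", {
  fr <- array(0, c(1200, 1920, 3))
  fr[601, 101, 1] <- 1   # marker at 0-based (600, 100)
  fr[1, 1, 1] <- 0.5     # marker at (0, 0), outside the retained band
  seg <- crop_segments(fr)
  expect_equal(dim(seg$left), c(960, 960, 3))
  expect_equal(dim(seg$right), c(960, 960, 3))
  # (600, 100) -> (480, 100) 0-based in the left segment
  expect_equal(unname(which(seg$left == 1, arr.ind = TRUE)[1, 1:2]),
               c(481, 101))
  expect_equal(sum(seg$left == 0.5) + sum(seg$right == 0.5), 0)
  # reassembling the two segments reproduces the central band exactly
  expect_identical(cbind(seg$left[, , 1], seg$right[, , 1]),
                   fr[121:1080, , 1])
  expect_error(crop_segments(array(0, c(1200, 1921, 3))), "even")
  expect_error(crop_segments(array(0, c(100, 1920, 3))), "at most twice")
})

test_that("bilinear resize matches hand-computed weights", {
  cons <- array(0.37, c(16, 16, 3))
  expect_true(all(resize_image(cons, 8) == 0.37))
  # independent scalar oracle: pixel-centre mapping with edge clamping
  bilin_ref <- function(img, side) {
    H <- nrow(img); out <- matrix(0, side, side)
    for (i in seq_len(side)) for (j in seq_len(side)) {
      sy <- min(max((i - 0.5) * H / side - 0.5, 0), H - 1)
      sx <- min(max((j - 0.5) * H / side - 0.5, 0), H - 1)
      y0 <- floor(sy); x0 <- floor(sx)
      y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, H - 1)
      fy <- sy - y0; fx <- sx - x0
      out[i, j] <- (1 - fy) * ((1 - fx) * img[y0 + 1, x0 + 1] + fx * img[y0 + 1, x1 + 1]) +
        fy * ((1 - fx) * img[y1 + 1, x0 + 1] + fx * img[y1 + 1, x1 + 1])
    }
    out
  }
  chk <- matrix(c(1, 0, 0, 1), 2, 2)
  got <- resize_image(array(chk, c(2, 2, 1)), 8)
  expect_equal(got[, , 1], bilin_ref(chk, 8), tolerance = 1e-12)
  # smooth-gradient round trip 960 -> 512 -> 960
  g <- outer(seq(0, 1, length.out = 960), seq(0, 1, length.out = 960),
             function(a, b) 0.5 + 0.4 * sin(2 * pi * a) * cos(2 * pi * b))
  rt <- resize_image(resize_image(array(g, c(960, 960, 1)), 512), 960)[, , 1]
  expect_lt(max(abs(rt - g)), 0.005)
  # interpolation preserves the value range
  expect_gte(min(rt), min(g)); expect_lte(max(rt), max(g))
  expect_error(resize_image(cons, 4), ">= 8")
})

test_that("a degenerate augmentation policy is the identity", {
  pol <- augment_policy(reflect_x = FALSE, reflect_y = FALSE, rotate_deg = 0,
                        scale_range = c(1, 1), translate_frac = 0)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_equal(augment_image(img, pol, seed = 4), img, tolerance = 1e-12)
})

test_that("vertical translation is bounded by height/8 and X is never shifted", {
  pol <- augment_policy()
  set.seed(51)
  sh <- replicate(1e4, {
    p <- sample_augment_params(pol, height = 512)
    c(p$shift_y, p$shift_x)
  })
  expect_lte(max(abs(sh[1, ])), 64)       # height / 8 exactly
  expect_gt(max(abs(sh[1, ])), 55)        # and the bound is approached
  expect_true(all(sh[2, ] == 0))
})

test_that("sampled rotations are uniform over +/- 5 degrees", {
  set.seed(52)
  ang <- replicate(1e4, sample_augment_params(augment_policy(), 512)$angle_deg)
  expect_lte(max(abs(ang)), 5)
  counts <- table(cut(ang, breaks = seq(-5, 5, length.out = 21)))
  expect_gt(chisq.test(counts)$p.value, 0.001)
  sc <- replicate(1e3, sample_augment_params(augment_policy(), 512)$scale_x)
  expect_true(all(sc >= 0.95 & sc <= 1.05))
})

test_that("augmentation preserves dimensions and value range", {
  img <- array(runif(64 * 64 * 3, 0.2, 0.8), c(64, 64, 3))
  for (s in 1:10) {
    out <- augment_image(img, augment_policy(), seed = 600 + s)
    expect_equal(dim(out), dim(img))
    expect_gte(min(out), min(img) - 1e-9)
    expect_lte(max(out), max(img) + 1e-9)
  }
})
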