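# A linear toy network whose Grad-CAM heatmap is hand-computable: a single
# 2-filter conv block (no batch norm, no pooling), an identity fully
# connected layer and a known class-weight matrix.
toy_gradcam_net <- function(side = 4) {
  spec <- cnn_architecture(input_side = side, block_filters = list(2),
                           fc_units = side * side * 2, n_classes = 4,
                           dropout = 0, batchnorm = FALSE)
  net <- build_network(spec, seed = 1)
  w <- array(0, c(3, 3, 3, 2))
  w[2, 2, 1, 1] <- 1                       # filter 1: centre tap, channel 1
  w[2, 2, 2, 2] <- 0.5; w[1, 2, 2, 2] <- 0.25  # filter 2 mixes channel 2
  net$params$conv1_w <- w
  net$params$conv1_b <- c(0, 0)
  D <- side * side * 2
  net$params$fc1_w <- diag(D)              # identity head (inputs positive)
  net$params$fc1_b <- numeric(D)
  fc2 <- matrix(0, D, 4)
  fc2[1:(side * side), 1] <- 0.7           # class 1 weights: channel 1 taps
  fc2[(side * side + 1):D, 1] <- -0.2      # and channel 2 taps
  fc2[, 2] <- 0.1
  net$params$fc2_w <- fc2
  net$params$fc2_b <- numeric(4)
  net
}

test_that("Grad-CAM equals the hand-computed activation x gradient map", {
  side <- 4
  net <- toy_gradcam_net(side)
  set.seed(21)
  img <- array(runif(side * side * 3, 0.2, 1), c(side, side, 3))
  # hand computation: A_k = conv activations (all positive -> ReLU passes),
  # d logit_1 / d A = fc2 column 1 reshaped; channel weights = spatial means
  conv_ref <- function(x, w) {
    H <- dim(x)[1]
    xp <- array(0, c(H + 2, H + 2, 3)); xp[2:(H + 1), 2:(H + 1), ] <- x
    A <- array(0, c(H, H, 2))
    for (f in 1:2) for (c in 1:3) for (ky in 1:3) for (kx in 1:3)
      A[, , f] <- A[, , f] +
        xp[ky:(ky + H - 1), kx:(kx + H - 1), c] * w[ky, kx, c, f]
    A
  }
  A <- conv_ref(img, net$params$conv1_w)
  expect_true(all(A >= 0))
  alpha <- c(mean(matrix(0.7, side, side)), mean(matrix(-0.2, side, side)))
  cam_ref <- pmax(alpha[1] * A[, , 1] + alpha[2] * A[, , 2], 0)
  cam_ref <- cam_ref / max(cam_ref)
  got <- gradcam(net, img, target_class = "blank", layer = 1)
  expect_equal(got, cam_ref, tolerance = 1e-5)
})

test_that("Grad-CAM degenerate cases behave by contract", {
  net <- toy_gradcam_net(4)
  zero <- array(0, c(4, 4, 3))
  hm <- gradcam(net, zero, target_class = "blank", layer = 1)
  expect_true(all(hm == 0))                 # bias-free model, zero input
  set.seed(22)
  img <- array(runif(48), c(4, 4, 3))
  hm <- gradcam(net, img, target_class = "blank", layer = 1)
  expect_equal(max(hm), 1)                  # max-normalised
  expect_true(all(hm >= 0 & hm <= 1))
  expect_error(gradcam(net, img, target_class = "blank", layer = 12),
               "invalid conv layer")
  expect_error(gradcam(net, img, target_class = "quartz", layer = 1),
               "unknown target class")
})

test_that("patch extraction selects disjoint windows around maxima", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  hm <- matrix(0, 64, 64)
  centres <- rbind(c(10, 12), c(40, 50), c(55, 20))
  for (i in 1:3) hm[centres[i, 1], centres[i, 2]] <- 1 - 0.1 * i
  ps <- extract_patches(img, hm, k = 3, patch_side = 8)
  expect_length(ps, 3)
  got <- t(vapply(ps, function(p) c(p$row, p$col), numeric(2)))
  expect_equal(got, centres - 1 - 4)        # windows centred on the blobs
  # patch pixels come from the image at the right offset
  expect_equal(ps[[1]]$img,
               img[(ps[[1]]$row + 1):(ps[[1]]$row + 8),
                   (ps[[1]]$col + 1):(ps[[1]]$col + 8), , drop = FALSE])

  # uniform heatmap: row-major tie-break puts the first window at the corner
  ps <- extract_patches(img, matrix(1, 64, 64), k = 1, patch_side = 8)
  expect_equal(c(ps[[1]]$row, ps[[1]]$col), c(0, 0))

  # random heatmaps: selected windows pairwise disjoint (brute force)
  for (s in 1:20) {
    set.seed(700 + s)
    hm <- matrix(runif(64 * 64), 64, 64)
    ps <- extract_patches(img, hm, k = 3, patch_side = 16)
    corners <- t(vapply(ps, function(p) c(p$row, p$col), numeric(2)))
    if (nrow(corners) > 1)
      for (i in 1:(nrow(corners) - 1)) for (j in (i + 1):nrow(corners))
        expect_true(abs(corners[i, 1] - corners[j, 1]) >= 16 ||
                      abs(corners[i, 2] - corners[j, 2]) >= 16)
  }
})

test_that("patch chromaticity selects the brightest pixels", {
  p <- array(0, c(8, 8, 3))
  idx <- cbind(sample(8, 6, TRUE), sample(8, 6, TRUE))
  p[cbind(idx, rep(1, 6))] <- 1             # six pure-red pixels
  pts <- patch_chromaticity(p, n_pixels = 30)
  expect_lte(nrow(pts), 6)                  # duplicates in idx collapse
  expect_true(all(pts$r == 1 & pts$g == 0))

  # exactly 30 non-black pixels -> exactly those 30 points
  q <- array(0, c(10, 10, 3))
  sel <- sample(100, 30)
  for (ch in 1:3) q[, , ch][sel] <- runif(30, 0.1, 1)
  pts <- patch_chromaticity(q, n_pixels = 30)
  expect_equal(nrow(pts), 30)

  # selection equals a brute-force sort by R+G+B
  r <- array(runif(10 * 10 * 3), c(10, 10, 3))
  s <- r[, , 1] + r[, , 2] + r[, , 3]
  pts <- patch_chromaticity(r, n_pixels = 12)
  expect_equal(sort(pts$brightness, decreasing = TRUE),
               sort(s, decreasing = TRUE)[1:12])
  # r + g + b = 1 identically for the implied triple
  b <- 1 - pts$r - pts$g
  expect_true(all(pts$r >= 0 & pts$g >= 0 & b >= -1e-12))

  expect_warning(out <- patch_chromaticity(array(0, c(4, 4, 3))), "all-black")
  expect_equal(nrow(out), 0)
})
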