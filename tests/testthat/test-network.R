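test_that("architecture bookkeeping matches the printed dimension sequence", {
  full <- cnn_profile("full")
  expect_equal(feature_map_sides(full), c(512L, 256L, 128L, 64L))
  expect_equal(nrow(filasense:::conv_layout(full)), 7)  # exactly 7 conv layers
  small <- cnn_profile("small")
  expect_equal(feature_map_sides(small), c(128L, 64L, 32L, 16L))
  # block 1 layer 1: 3*3*3*32 + 32 = 896 parameters
  expect_equal(count_params(full, by_layer = TRUE)$conv[1], 896)
  # closed-form total for the small profile, written out independently
  conv_tot <- function(cin, cout) 9 * cin * cout + cout
  expected <- conv_tot(3, 16) + conv_tot(16, 16) + conv_tot(16, 32) +
    conv_tot(32, 32) + conv_tot(32, 64) + conv_tot(64, 64) +
    conv_tot(64, 128) +
    2 * (16 + 16 + 32 + 32 + 64 + 64 + 128) +        # batch-norm scale/shift
    (16 * 16 * 128) * 64 + 64 + 64 * 4 + 4
  expect_equal(count_params(small), expected)
  expect_error(cnn_architecture(input_side = 100), "divisible")
})

test_that("initialisation is seeded and deterministic", {
  a <- build_network(tiny_architecture(), seed = 5)
  b <- build_network(tiny_architecture(), seed = 5)
  expect_identical(a$params, b$params)
  c <- build_network(tiny_architecture(), seed = 6)
  expect_false(identical(a$params$conv1_w, c$params$conv1_w))
})

test_that("native convolution matches a direct R convolution oracle", {
  conv_ref <- function(x, w, b) {
    H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; F <- dim(w)[4]
    xp <- array(0, c(H + 2, W + 2, C)); xp[2:(H + 1), 2:(W + 1), ] <- x
    y <- array(0, c(H, W, F))
    for (f in 1:F) for (c in 1:C) for (ky in 1:3) for (kx in 1:3)
      y[, , f] <- y[, , f] +
        xp[ky:(ky + H - 1), kx:(kx + W - 1), c] * w[ky, kx, c, f]
    sweep(y, 3, b, "+")
  }
  set.seed(8)
  x <- array(rnorm(9 * 10 * 2 * 3), c(9, 10, 2, 3))
  w <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  b <- rnorm(4)
  got <- filasense:::fs_conv3_fwd(x, w, b)
  for (n in 1:3)
    expect_equal(got[, , , n], conv_ref(x[, , , n], w, b), tolerance = 1e-5)
})

test_that("backpropagation agrees with finite differences", {
  spec <- cnn_architecture(input_side = 16,
                           block_filters = list(c(4, 4), c(6), 8),
                           fc_units = 10, dropout = 0)
  net <- build_network(spec, seed = 3)
  set.seed(7)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y_idx <- c(2L, 4L)
  loss_at <- function(nn) {
    fw <- filasense:::forward_cnn(nn, x, training = TRUE, keep = FALSE)
    filasense:::softmax_xent(fw$probs, y_idx)$loss
  }
  fw <- filasense:::forward_cnn(net, x, training = TRUE, keep = TRUE)
  sx <- filasense:::softmax_xent(fw$probs, y_idx)
  bw <- filasense:::backward_cnn(net, fw$cache, sx$dlogits)
  h <- 1e-3
  for (nm in names(bw$grads)) {
    if (grepl("^conv\\d+_b$", nm)) {
      # with batch norm directly after each conv the bias gradient is
      # analytically zero (the batch mean absorbs it)
      expect_lt(max(abs(bw$grads[[nm]])), 1e-6)
      next
    }
    g <- bw$grads[[nm]]
    set.seed(utf8ToInt(substr(nm, 1, 1)))
    for (k in sample(length(g), min(3, length(g)))) {
      np <- net; np$params[[nm]][k] <- np$params[[nm]][k] + h
      nm2 <- net; nm2$params[[nm]][k] <- nm2$params[[nm]][k] - h
      fd <- (loss_at(np) - loss_at(nm2)) / (2 * h)
      expect_lt(abs(fd - g[k]) / max(1e-3, abs(fd) + abs(g[k])), 0.05)
    }
  }
})

test_that("inference-mode gradients treat running moments as constants", {
  # regression test: in inference mode batch-norm statistics are fixed, so
  # the backward pass is the plain affine dy * gamma / sqrt(var + eps); the
  # training-mode formula would wrongly zero-centre gradients per channel
  # (this is what Grad-CAM differentiates through)
  spec <- cnn_architecture(input_side = 16, block_filters = list(c(4), 6),
                           fc_units = 8, dropout = 0)
  net <- build_network(spec, seed = 11)
  # make running moments distinct from the init values
  net$running$bn1_mean <- runif(4, -0.1, 0.1)
  net$running$bn1_var <- runif(4, 0.5, 1.5)
  net$running$bn2_mean <- runif(6, -0.1, 0.1)
  net$running$bn2_var <- runif(6, 0.5, 1.5)
  set.seed(12)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  loss_at <- function(nn) {
    fw <- filasense:::forward_cnn(nn, x, training = FALSE, keep = FALSE)
    filasense:::softmax_xent(fw$probs, 2L)$loss
  }
  fw <- filasense:::forward_cnn(net, x, training = FALSE, keep = TRUE)
  sx <- filasense:::softmax_xent(fw$probs, 2L)
  bw <- filasense:::backward_cnn(net, fw$cache, sx$dlogits)
  h <- 1e-3
  for (nm in c("conv1_w", "conv2_w", "bn1_gamma", "bn2_beta", "fc1_w")) {
    g <- bw$grads[[nm]]
    for (k in sample(length(g), 3)) {
      np <- net; np$params[[nm]][k] <- np$params[[nm]][k] + h
      nm2 <- net; nm2$params[[nm]][k] <- nm2$params[[nm]][k] - h
      fd <- (loss_at(np) - loss_at(nm2)) / (2 * h)
      expect_lt(abs(fd - g[k]) / max(1e-3, abs(fd) + abs(g[k])), 0.05)
    }
  }
})

test_that("inference is deterministic with probabilities summing to one", {
  net <- build_network(tiny_architecture(), seed = 9)
  x <- array(runif(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  f1 <- filasense:::forward_cnn(net, x, training = FALSE, keep = FALSE)
  f2 <- filasense:::forward_cnn(net, x, training = FALSE, keep = FALSE)
  expect_equal(rowSums(f1$probs), rep(1, 3), tolerance = 1e-6)
  expect_identical(f1$probs, f2$probs)
})
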