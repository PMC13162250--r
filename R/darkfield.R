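#' Dark-field slide configuration
#'
#' Per-class particle size and shape distributions for synthetic dark-field
#' micrographs of particles deposited on a glass slide.  Defaults encode the
#' measured class statistics: equivalent diameters 9.4 +/- 4.1 um (range
#' 3-28) for chalk, 20.7 +/- 3.8 um (range 4.6-30.7) for pollen and
#' 21.8 +/- 6.8 um (range 12-37) for salt, with mean circularity /
#' eccentricity targets 0.74/0.60 (chalk), 0.86/0.55 (pollen) and 0.70/0.66
#' (salt).  Diameters are truncated normals on the stated ranges.  The image
#' scale defaults to 0.192 um per pixel.
#'
#' @param pixel_scale micrometres per pixel.
#' @param classes named list of per-class parameter lists with fields
#'   `d_mean`, `d_sd`, `d_range` (um), `circ`, `circ_sd`, `ecc`, `ecc_sd`.
#' @param background_level,noise_sd dark background level and noise sd.
#' @param brightness_range particle brightness range.
#' @return an object of class `slide_config`.
#' @export
slide_config <- function(pixel_scale = 0.192,
                         classes = list(
                           chalk  = list(d_mean = 9.4,  d_sd = 4.1, d_range = c(3, 28),
                                         circ = 0.74, circ_sd = 0.08, ecc = 0.60, ecc_sd = 0.15),
                           pollen = list(d_mean = 20.7, d_sd = 3.8, d_range = c(4.6, 30.7),
                                         circ = 0.86, circ_sd = 0.11, ecc = 0.55, ecc_sd = 0.17),
                           salt   = list(d_mean = 21.8, d_sd = 6.8, d_range = c(12, 37),
                                         circ = 0.70, circ_sd = 0.07, ecc = 0.66, ecc_sd = 0.17)),
                         background_level = 0.04, noise_sd = 0.01,
                         brightness_range = c(0.7, 1.0)) {
  stopifnot(pixel_scale > 0)
  for (p in classes)
    stopifnot(p$d_sd >= 0, diff(p$d_range) > 0, p$circ > 0, p$circ <= 1,
              p$ecc >= 0, p$ecc < 1)
  structure(list(pixel_scale = pixel_scale, classes = classes,
                 background_level = background_level, noise_sd = noise_sd,
                 brightness_range = brightness_range),
            class = "slide_config")
}

# Truncated-normal draw by rejection.
rtruncnorm1 <- function(mean, sd, range) {
  if (sd == 0) return(min(max(mean, range[1]), range[2]))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
}

# Area, centroid and second central moments of a closed polygon
# (standard Green's-theorem formulas; vertices counter-clockwise).
polygon_moments <- function(x, y) {
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  Ixx <- sum((y^2 + y * y2 + y2^2) * cr) / 12        # integral of y^2 dA
  Iyy <- sum((x^2 + x * x2 + x2^2) * cr) / 12        # integral of x^2 dA
  Ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  mu20 <- Iyy / A - cx^2   # var of x
  mu02 <- Ixx / A - cy^2   # var of y
  mu11 <- Ixy / A - cx * cy
  list(area = A, cx = cx, cy = cy, mu20 = mu20, mu02 = mu02, mu11 = mu11,
       perimeter = sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)))
}

moment_eccentricity <- function(mu20, mu02, mu11) {
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2, 2),
              symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

# Polar boundary of one particle: rotated ellipse modulated by random
# harmonics.  The modulation depth is solved by bisection so the continuum
# circularity matches the target, and the base-ellipse aspect is corrected
# by fixed-point iteration so the *moment* eccentricity of the modulated
# shape (what segmentation measures) matches the eccentricity target (the
# harmonics alone inflate it).  Returns the radius function on the theta
# grid and the continuum ground-truth metrics.
particle_boundary <- function(d_eq_px, ecc_target, circ_target, n_theta = 720) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  phi <- stats::runif(1, 0, pi)
  r0 <- d_eq_px / 2
  # lobes start at k = 3: a k = 2 harmonic is an elliptical distortion and
  # would fight the base-ellipse eccentricity targeting
  ks <- 3:7
  cs <- stats::rnorm(length(ks)) / ks
  ps <- stats::runif(length(ks), 0, 2 * pi)
  g <- rowSums(sapply(seq_along(ks), function(i) cs[i] * cos(ks[i] * th + ps[i])))
  if (max(abs(g)) > 0) g <- g / max(abs(g))
  solve_for <- function(e_base) {
    ratio <- sqrt(1 - min(e_base, 0.995)^2)          # b/a of the base ellipse
    a <- r0 / sqrt(ratio); b <- r0 * sqrt(ratio)
    re <- a * b / sqrt((b * cos(th - phi))^2 + (a * sin(th - phi))^2)
    shape_at <- function(m) {
      r <- re * pmax(1 + m * g, 0.05)
      x <- r * cos(th); y <- r * sin(th)
      mom <- polygon_moments(x, y)
      list(r = r, mom = mom, circ = 4 * pi * mom$area / mom$perimeter^2)
    }
    s0 <- shape_at(0)
    if (s0$circ <= circ_target) return(s0)
    lo <- 0; hi <- 0.5
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (shape_at(mid)$circ > circ_target) lo <- mid else hi <- mid
    }
    shape_at((lo + hi) / 2)
  }
  e_base <- ecc_target
  for (it in 1:3) {
    sol <- solve_for(e_base)
    e_meas <- moment_eccentricity(sol$mom$mu20, sol$mom$mu02, sol$mom$mu11)
    e_base <- min(max(e_base - (e_meas - ecc_target), 0), 0.93)
  }
  sol <- solve_for(e_base)
  mom <- sol$mom
  list(theta = th, r = sol$r,
       d_eq_px = 2 * sqrt(mom$area / pi),
       circularity = sol$circ,
       eccentricity = moment_eccentricity(mom$mu20, mom$mu02, mom$mu11))
}

#' Render a synthetic dark-field slide image
#'
#' Places `n_particles` bright particles with class-specific size and shape
#' distributions on a dark noisy background, on a jittered grid that avoids
#' overlap.  The returned ground-truth table carries each particle's
#' continuum (pre-rasterisation) equivalent diameter, circularity and
#' eccentricity, computed by quadrature on the parametric boundary.
#'
#' @param class_label `"chalk"`, `"pollen"` or `"salt"`.
#' @param n_particles number of particles (>= 0).
#' @param slide a `slide_config`.
#' @param seed optional seed.
#' @return list with `image` (grayscale matrix in [0, 1]) and `particles`
#'   (data frame: x_px, y_px, d_eq_um, circularity, eccentricity).
#' @export
render_darkfield_slide <- function(class_label, n_particles,
                                   slide = slide_config(), seed = NULL) {
  stopifnot(n_particles >= 0)
  if (!class_label %in% names(slide$classes))
    stop("no slide parameters for class: ", class_label)
  p <- slide$classes[[class_label]]
  scale <- slide$pixel_scale
  # cell must hold the worst-case elongated, modulated boundary, not just
  # the equivalent diameter (aspect stretch up to ~1.7x for e <= 0.93)
  cell <- ceiling(p$d_range[2] / scale * 1.8) + 12
  with_seed(seed, {
    ncol_g <- max(1, ceiling(sqrt(max(n_particles, 1))))
    nrow_g <- max(1, ceiling(max(n_particles, 1) / ncol_g))
    H <- nrow_g * cell; W <- ncol_g * cell
    img <- matrix(slide$background_level, H, W)
    if (slide$noise_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, slide$noise_sd), H, W)
    rows <- list()
    if (n_particles > 0) {
      cells <- sample.int(nrow_g * ncol_g, n_particles)
      n_resampled <- 0
      for (i in seq_len(n_particles)) {
        repeat {
          d_um <- rtruncnorm1(p$d_mean, p$d_sd, p$d_range)
          ecc_t <- min(max(stats::rnorm(1, p$ecc, p$ecc_sd), 0), 0.93)
          cir_t <- min(max(stats::rnorm(1, p$circ, p$circ_sd), 0.35), 1)
          bnd <- particle_boundary(d_um / scale, ecc_t, cir_t)
          if (2 * max(bnd$r) + 4 <= cell) break
          n_resampled <- n_resampled + 1
        }
        gr <- (cells[i] - 1) %/% ncol_g
        gc <- (cells[i] - 1) %% ncol_g
        jit <- (cell - max(bnd$r) * 2 - 4) / 2
        cy <- gr * cell + cell / 2 + stats::runif(1, -1, 1) * max(jit, 0)
        cx <- gc * cell + cell / 2 + stats::runif(1, -1, 1) * max(jit, 0)
        bright <- stats::runif(1, slide$brightness_range[1],
                               slide$brightness_range[2])
        rmax <- max(bnd$r)
        rr <- max(1, floor(cy - rmax)):min(H, ceiling(cy + rmax))
        cc <- max(1, floor(cx - rmax)):min(W, ceiling(cx + rmax))
        dy <- rr - cy
        dx <- cc - cx
        thp <- atan2(outer(dy, rep(1, length(cc))),
                     outer(rep(1, length(dy)), dx))
        rho <- sqrt(outer(dy^2, dx^2, "+"))
        rb <- stats::approx(c(bnd$theta - 2 * pi, bnd$theta, bnd$theta + 2 * pi),
                            rep(bnd$r, 3), xout = as.numeric(thp))$y
        inside <- matrix(as.numeric(rho <= rb), length(rr), length(cc))
        img[rr, cc] <- pmax(img[rr, cc], inside * bright)
        rows[[i]] <- data.frame(
          x_px = cx, y_px = cy,
          d_eq_um = bnd$d_eq_px * scale,
          circularity = bnd$circularity,
          eccentricity = bnd$eccentricity)
      }
      if (n_resampled > 0)
        message(n_resampled, " oversize diameter draw(s) resampled")
    }
    particles <- if (length(rows)) do.call(rbind, rows) else
      data.frame(x_px = numeric(0), y_px = numeric(0), d_eq_um = numeric(0),
                 circularity = numeric(0), eccentricity = numeric(0))
    list(image = pmin(pmax(img, 0), 1), particles = particles)
  })
}
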