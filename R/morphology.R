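#' Shape metrics of a single segmented region
#'
#' Computes the equivalent diameter `2 * sqrt(A / pi)`, circularity
#' `4 * pi * A / P^2` and moment eccentricity of one connected region.  The
#' perimeter is measured on the 0.5-level marching-squares contour after a
#' light circular moving-average smoothing (window 5), which removes the
#' systematic stair-step overestimate of raw digital contours; circularity
#' may slightly exceed 1 for small rasterised discs.
#'
#' @param region logical or 0/1 matrix containing one region (area >= 4 px).
#' @param pixel_scale micrometres per pixel.
#' @return list with `area_um2`, `d_eq_um`, `perimeter_um`, `circularity`,
#'   `eccentricity`, `centroid_x`, `centroid_y` (px).
#' @export
shape_metrics <- function(region, pixel_scale = 1) {
  m <- (region != 0) * 1
  A <- sum(m)
  if (A < 4) stop("degenerate region: area below 4 px")
  P <- contour_perimeter(m)
  idx <- which(m == 1, arr.ind = TRUE)
  ctr <- colMeans(idx)
  dd <- sweep(idx, 2, ctr)
  # second central moments with the 1/12 px term for single-pixel extent
  mu <- crossprod(dd) / A + diag(2) / 12
  ecc <- moment_eccentricity(mu[1, 1], mu[2, 2], mu[1, 2])
  list(area_um2 = A * pixel_scale^2,
       d_eq_um = 2 * sqrt(A / pi) * pixel_scale,
       perimeter_um = P * pixel_scale,
       circularity = 4 * pi * A / P^2,
       eccentricity = ecc,
       centroid_y = ctr[1], centroid_x = ctr[2])
}

# Marching-squares (0.5 level) contour length with circular moving-average
# smoothing of the contour vertices.
contour_perimeter <- function(mask, window = 5) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  cl <- grDevices::contourLines(seq_len(H + 2), seq_len(W + 2), pad, levels = 0.5)
  total <- 0
  k <- (window - 1) / 2
  for (cc in cl) {
    x <- cc$x[-length(cc$x)]; y <- cc$y[-length(cc$y)]
    n <- length(x)
    if (n < window) {
      total <- total + sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
      next
    }
    xs <- stats::filter(c(utils::tail(x, k), x, utils::head(x, k)),
                        rep(1 / window, window))[(k + 1):(k + n)]
    ys <- stats::filter(c(utils::tail(y, k), y, utils::head(y, k)),
                        rep(1 / window, window))[(k + 1):(k + n)]
    total <- total + sum(sqrt(diff(c(xs, xs[1]))^2 + diff(c(ys, ys[1]))^2))
  }
  total
}

#' Segment particles in a dark-field image
#'
#' Global intensity thresholding (Otsu by default), 8-connected component
#' labelling, per-region shape metrics, and removal of regions below the
#' inclusion threshold (equivalent diameter >= 3 um by default).
#'
#' @param image grayscale matrix or RGB array in [0, 1].
#' @param pixel_scale micrometres per pixel (default 0.192).
#' @param min_diameter_um inclusion threshold on equivalent diameter.
#' @param threshold `"otsu"` or a numeric global threshold.
#' @return a `particle_table` data frame with one row per retained particle:
#'   `centroid_x`, `centroid_y` (px), `area_um2`, `d_eq_um`, `perimeter_um`,
#'   `circularity`, `eccentricity`.
#' @export
segment_particles <- function(image, pixel_scale = 0.192, min_diameter_um = 3,
                              threshold = "otsu") {
  stopifnot(pixel_scale > 0)
  if (length(dim(image)) == 3) image <- apply(image, c(1, 2), mean)
  thr <- if (is.numeric(threshold)) threshold else
    EBImage::otsu(EBImage::Image(image))
  mask <- (image > thr) * 1L
  empty <- data.frame(centroid_x = numeric(0), centroid_y = numeric(0),
                      area_um2 = numeric(0), d_eq_um = numeric(0),
                      perimeter_um = numeric(0), circularity = numeric(0),
                      eccentricity = numeric(0))
  if (!any(mask == 1L)) return(structure(empty, class = c("particle_table", "data.frame")))
  labels <- fs_label8(mask)
  nlab <- max(labels)
  rows <- list()
  for (l in seq_len(nlab)) {
    idx <- which(labels == l, arr.ind = TRUE)
    if (nrow(idx) < 4) next
    r_rng <- range(idx[, 1]); c_rng <- range(idx[, 2])
    sub <- matrix(0, diff(r_rng) + 1, diff(c_rng) + 1)
    sub[cbind(idx[, 1] - r_rng[1] + 1, idx[, 2] - c_rng[1] + 1)] <- 1
    sm <- shape_metrics(sub, pixel_scale)
    rows[[length(rows) + 1]] <- data.frame(
      centroid_x = sm$centroid_x + c_rng[1] - 1,
      centroid_y = sm$centroid_y + r_rng[1] - 1,
      area_um2 = sm$area_um2, d_eq_um = sm$d_eq_um,
      perimeter_um = sm$perimeter_um, circularity = sm$circularity,
      eccentricity = sm$eccentricity)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[out$d_eq_um >= min_diameter_um, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("particle_table", "data.frame"))
}

#' Air-sampler volume, concentration and surface-density arithmetic
#'
#' `V = Q * t / 1000` cubic metres for a flow `Q` in litres per minute over
#' `t` minutes; particle concentration `n = N / V`; surface density
#' `sigma = N / area`.
#'
#' @param n_particles detected particle count `N`.
#' @param flow_lpm sampler flow rate in L/min (default 10).
#' @param minutes sampling duration in minutes (default 9).
#' @param area_mm2 optional deposit area in mm^2.
#' @return an object of class `sampler_stats`: list with `volume_m3`,
#'   `concentration_m3` and `surface_density_mm2` (NA when no area given).
#' @export
sampler_stats <- function(n_particles, flow_lpm = 10, minutes = 9,
                          area_mm2 = NULL) {
  stopifnot(n_particles >= 0, flow_lpm > 0, minutes > 0)
  if (!is.null(area_mm2) && area_mm2 <= 0) stop("deposit area must be positive")
  V <- flow_lpm * minutes / 1000
  structure(list(volume_m3 = V,
                 concentration_m3 = n_particles / V,
                 surface_density_mm2 = if (is.null(area_mm2)) NA_real_ else
                   n_particles / area_mm2,
                 n_particles = n_particles, flow_lpm = flow_lpm,
                 minutes = minutes), class = "sampler_stats")
}

#' @export
print.sampler_stats <- function(x, ...) {
  cat(sprintf("<sampler_stats> N = %d, V = %.3g m^3, n = %.3g m^-3",
              x$n_particles, x$volume_m3, x$concentration_m3))
  if (!is.na(x$surface_density_mm2))
    cat(sprintf(", sigma = %.3g mm^-2", x$surface_density_mm2))
  cat("\n")
  invisible(x)
}
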