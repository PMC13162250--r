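#' Emission spectrum container
#'
#' A wavelength-sampled intensity curve on a strictly increasing grid, the
#' common currency between the spectral model and the camera rendering.
#' Negative intensities (e.g. from additive noise) are clipped at zero.
#'
#' @param wavelength_nm strictly increasing numeric grid in nanometres.
#' @param intensity non-negative intensities (arbitrary units), same length.
#' @return an object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength_nm, intensity) {
  stopifnot(length(wavelength_nm) == length(intensity))
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 intensity = pmax(as.numeric(intensity), 0)),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %d samples, %.0f-%.0f nm, peak %.3g at %.1f nm\n",
              length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm),
              max(x$intensity), x$wavelength_nm[which.max(x$intensity)]))
  invisible(x)
}

#' Default wavelength grid (350-800 nm, 1 nm step)
#' @export
default_wavelength_grid <- function() seq(350, 800, by = 1)

#' Particle classes modelled by the simulator
#' @export
particle_classes <- function() c("blank", "chalk", "pollen", "salt")

check_class_label <- function(class_label) {
  if (!is.character(class_label) || length(class_label) != 1L ||
      !class_label %in% particle_classes())
    stop("unknown particle class: ", paste(class_label, collapse = ", "),
         " (expected one of ", paste(particle_classes(), collapse = ", "), ")")
  class_label
}

#' Parametric emission-spectrum model for a particle class
#'
#' Each class is modelled as a sum of Gaussian emission lines plus a broad
#' Gaussian continuum, with additive measurement noise.  The defaults encode
#' the qualitative signatures of filament-induced plasma emission: chalk is
#' dominated by discrete calcium transitions (violet Ca II H/K and Ca I
#' 422.7 nm together with red Ca I lines around 612-644 nm, giving a pink
#' rendered colour), pollen by a broad organic-fluorophore band peaking in
#' the green at 500-550 nm, salt by the sodium D doublet near 589 nm
#' (rendered orange), and blank by the weak filament-only plasma continuum.
#'
#' @param class_label one of `particle_classes()`.
#' @return an object of class `class_spectrum_params` with fields
#'   `class_label`, `lines` (matrix with columns center_nm, fwhm_nm,
#'   amplitude), `continuum` (one row of the same form) and `noise_sd`.
#' @export
class_spectrum_params <- function(class_label) {
  check_class_label(class_label)
  ln <- function(...) {
    m <- matrix(c(numeric(0), ...), ncol = 3, byrow = TRUE)
    colnames(m) <- c("center_nm", "fwhm_nm", "amplitude")
    m
  }
  p <- switch(class_label,
    blank = list(
      lines = ln()[0, , drop = FALSE],
      continuum = ln(450, 120, 0.25),
      noise_sd = 0.002),
    chalk = list(
      lines = ln(393.4, 1.6, 0.90,
                 396.8, 1.6, 0.80,
                 422.7, 1.6, 1.00,
                 445.5, 2.0, 0.35,
                 558.9, 2.0, 0.20,
                 612.2, 2.0, 0.85,
                 616.2, 2.0, 0.75,
                 643.9, 2.0, 0.65),
      continuum = ln(520, 300, 0.04),
      noise_sd = 0.005),
    pollen = list(
      lines = ln(430.0, 3.0, 0.06),
      continuum = ln(525, 60, 1.00),
      noise_sd = 0.005),
    salt = list(
      lines = ln(589.0, 1.8, 1.00,
                 589.6, 1.8, 0.50,
                 568.8, 2.0, 0.06,
                 616.0, 2.0, 0.05),
      continuum = ln(585, 140, 0.07),
      noise_sd = 0.005))
  stopifnot(all(p$lines[, "amplitude"] >= 0), all(p$lines[, "fwhm_nm"] > 0),
            p$continuum[, "fwhm_nm"] > 0, p$continuum[, "amplitude"] >= 0)
  structure(c(list(class_label = class_label), p),
            class = "class_spectrum_params")
}

#' Synthesise a class emission spectrum at a given laser power
#'
#' Sums the class's Gaussian lines and continuum, scales the result by the
#' intensity-vs-power law of the clamping model (normalised to full power),
#' and adds clipped Gaussian noise.  The blank class yields the filament-only
#' continuum, which downstream reference subtraction removes.
#'
#' @param class_label one of `particle_classes()`.
#' @param power_fraction laser power as a fraction of maximum, in (0, 1].
#' @param params a `class_spectrum_params`; defaults to the class defaults.
#' @param seed optional integer seed for the noise draw.
#' @param clamping a `clamping_model` supplying the intensity-vs-power law.
#' @param wavelength_nm wavelength grid.
#' @return an `emission_spectrum`.
#' @export
make_emission_spectrum <- function(class_label, power_fraction = 1,
                                   params = class_spectrum_params(class_label),
                                   seed = NULL,
                                   clamping = clamping_model(),
                                   wavelength_nm = default_wavelength_grid()) {
  check_class_label(class_label)
  stopifnot(power_fraction > 0, power_fraction <= 1)
  if (!identical(params$class_label, class_label))
    stop("params are for class '", params$class_label, "', not '", class_label, "'")
  grid <- wavelength_nm
  y <- numeric(length(grid))
  if (nrow(params$lines))
    for (i in seq_len(nrow(params$lines)))
      y <- y + gaussian_fwhm(grid, params$lines[i, 1], params$lines[i, 2],
                             params$lines[i, 3])
  y <- y + gaussian_fwhm(grid, params$continuum[, 1], params$continuum[, 2],
                         params$continuum[, 3])
  scale <- intensity_scale(power_fraction, clamping) / intensity_scale(1, clamping)
  y <- y * scale
  if (params$noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(grid), 0, params$noise_sd))
  emission_spectrum(grid, y)
}

#' Camera spectral-response model
#'
#' Gaussian per-channel responses standing in for the RGB colour-filter
#' transmission of the imaging camera (the true filter curves are not
#' published); defaults centre the channels at 600/540/460 nm with 80 nm
#' full width at half maximum and unit gain.
#'
#' @param centers_nm,fwhm_nm,gains per-channel (R, G, B) response parameters.
#' @param exposure global exposure scale.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(centers_nm = c(600, 540, 460),
                         fwhm_nm = c(80, 80, 80),
                         gains = c(1, 1, 1),
                         exposure = 1) {
  stopifnot(length(centers_nm) == 3, all(fwhm_nm > 0), all(gains > 0),
            exposure > 0)
  structure(list(centers_nm = centers_nm, fwhm_nm = fwhm_nm, gains = gains,
                 exposure = exposure), class = "camera_model")
}

#' Render an emission spectrum to a linear RGB triple
#'
#' Each channel is the trapezoidal integral of the spectrum weighted by that
#' channel's Gaussian response, times gain and exposure.  Values are linear
#' and unclipped; normalise downstream as needed.
#'
#' @param spectrum an `emission_spectrum`.
#' @param camera a `camera_model`.
#' @return named numeric triple `c(r =, g =, b =)`, non-negative.
#' @export
spectrum_to_rgb <- function(spectrum, camera = camera_model()) {
  stopifnot(inherits(spectrum, "emission_spectrum"),
            inherits(camera, "camera_model"))
  grid <- spectrum$wavelength_nm
  out <- vapply(1:3, function(ch) {
    resp <- gaussian_fwhm(grid, camera$centers_nm[ch], camera$fwhm_nm[ch])
    camera$gains[ch] * camera$exposure *
      pracma::trapz(grid, spectrum$intensity * resp)
  }, numeric(1))
  names(out) <- c("r", "g", "b")
  out
}
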