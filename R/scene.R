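#' Camera-frame scene configuration
#'
#' Geometry and radiometry of a rendered camera frame: a horizontal filament
#' stripe across the frame plus class-specific emission events.  The default
#' geometry matches the full-resolution camera (1920 x 1200 px); event-count
#' means per class are blank 0, chalk 5, pollen 1, salt 3 (Poisson).  All
#' pixel values are on a linear [0, 1] scale before 8-bit quantisation.
#'
#' @param width,height frame size in pixels.
#' @param stripe_row centre row of the filament stripe (default mid-frame).
#' @param stripe_thickness stripe Gaussian cross-profile width (px); the
#'   profile sigma is `stripe_thickness / 2`.
#' @param stripe_length_frac stripe length as a fraction of frame width
#'   (the imaged plasma channel spans most of the field of view).
#' @param stripe_color linear RGB hue of the plasma stripe (normalised
#'   internally); near-neutral by default.
#' @param stripe_brightness peak stripe brightness at full power.
#' @param event_mean named Poisson means of event counts per class.
#' @param event_sigma_range range of the isotropic event blob sigma (px).
#' @param event_amp_range range of event peak amplitudes at full power.
#'   The defaults balance two radiometric constraints that the chromaticity
#'   analysis needs: event cores stay inside the sensor's linear range (a
#'   clipped pixel renders neutral, destroying the class colour signature),
#'   and every event outshines the near-white stripe in summed brightness
#'   even for low-sum hues such as pollen green, so the brightest pixels of
#'   an event patch are event pixels.
#' @param event_band_sd vertical scatter (sd, px) of event centres about the
#'   stripe row; defaults to `1.5 * stripe_thickness`.
#' @param background_level dark background level.
#' @param noise_sd per-pixel Gaussian noise sd.
#' @param power_fraction laser power fraction in (0, 1].
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(width = 1920, height = 1200, stripe_row = NULL,
                         stripe_thickness = 10, stripe_length_frac = 0.9,
                         stripe_color = c(0.72, 0.78, 0.92),
                         stripe_brightness = 0.15,
                         event_mean = c(blank = 0, chalk = 5, pollen = 1, salt = 3),
                         event_sigma_range = c(6, 12),
                         event_amp_range = c(0.4, 0.7),
                         event_band_sd = NULL,
                         background_level = 0.02, noise_sd = 0.005,
                         power_fraction = 1) {
  stopifnot(width >= 16, height >= 16, stripe_thickness > 0,
            power_fraction > 0, power_fraction <= 1,
            all(event_mean >= 0), event_mean[["blank"]] == 0,
            stripe_brightness > 0, all(event_amp_range > 0),
            diff(event_sigma_range) >= 0, noise_sd >= 0)
  structure(list(
    width = as.integer(width), height = as.integer(height),
    stripe_row = stripe_row %||% (height / 2),
    stripe_thickness = stripe_thickness,
    stripe_length_frac = stripe_length_frac,
    stripe_color = stripe_color / max(stripe_color),
    stripe_brightness = stripe_brightness,
    event_mean = event_mean,
    event_sigma_range = event_sigma_range,
    event_amp_range = event_amp_range,
    event_band_sd = event_band_sd %||% (1.5 * stripe_thickness),
    background_level = background_level, noise_sd = noise_sd,
    power_fraction = power_fraction), class = "scene_config")
}

#' Desk-scale scene configuration
#'
#' Same scene at reduced resolution (256 x 160 frames, preserving the 1.6
#' aspect ratio, yielding 128 x 128 crop segments).  Event sigmas match the
#' full profile's footprint at the *network input* (6-12 px at 1920 becomes
#' 3.2-6.4 px after cropping and resizing to 512), rather than scaling with
#' the frame: the chromaticity analysis takes a fixed 30 brightest pixels
#' per patch, so an event must always have at least ~30 bright pixels.
#' Class signatures (colour, counts, brightness) are unchanged.
#'
#' @param ... overrides passed to [scene_config()].
#' @export
scene_config_small <- function(...) {
  defaults <- list(width = 256, height = 160, stripe_thickness = 4,
                   event_sigma_range = c(3, 5))
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_config, args)
}

#' Render one camera frame with emission events
#'
#' Builds `background noise + filament stripe + events`: the stripe has a
#' Gaussian cross-profile with brightness scaled by the intensity-vs-power
#' law; the event count is Poisson with the class mean; each event is an
#' isotropic 2-D Gaussian blob placed along the stripe whose colour is the
#' camera rendering of a per-event draw of the class emission spectrum
#' (line amplitudes jittered log-normally).  The frame is clipped to [0, 1]
#' and quantised to 8 bits.  Fully deterministic under a fixed seed.
#'
#' @param class_label one of `particle_classes()`.
#' @param scene a `scene_config`.
#' @param camera a `camera_model`.
#' @param params a `class_spectrum_params` for the class.
#' @param seed optional integer seed.
#' @param clamping a `clamping_model`.
#' @return an object of class `labeled_image`: list with `pixels`
#'   (height x width x 3 array in [0, 1], 8-bit quantised), `label`,
#'   `power_fraction`, `seed` and an `events` ground-truth data frame
#'   (columns x, y, sigma, amp, r, g, b).
#' @export
render_frame <- function(class_label, scene = scene_config(),
                         camera = camera_model(),
                         params = class_spectrum_params(class_label),
                         seed = NULL, clamping = clamping_model()) {
  check_class_label(class_label)
  stopifnot(inherits(scene, "scene_config"))
  if (3 * max(scene$event_sigma_range) > min(scene$height, scene$width))
    stop("event radius exceeds the frame")
  H <- scene$height; W <- scene$width
  p <- scene$power_fraction
  pscale <- intensity_scale(p, clamping) / intensity_scale(1, clamping)
  with_seed(seed, {
    frame <- array(scene$background_level, dim = c(H, W, 3))
    if (scene$noise_sd > 0)
      frame <- frame + stats::rnorm(length(frame), 0, scene$noise_sd)
    # filament stripe: Gaussian cross-profile, finite length, power-scaled
    len <- round(scene$stripe_length_frac * W)
    c0 <- floor((W - len) / 2) + 1
    cols <- c0:(c0 + len - 1)
    rows <- seq_len(H)
    prof <- exp(-(rows - scene$stripe_row)^2 / (2 * (scene$stripe_thickness / 2)^2))
    keep <- prof > 1e-4
    stripe_amp <- scene$stripe_brightness * pscale
    for (ch in 1:3)
      frame[keep, cols, ch] <- frame[keep, cols, ch] +
        stripe_amp * scene$stripe_color[ch] * prof[keep]
    # emission events
    n_ev <- stats::rpois(1, scene$event_mean[[class_label]])
    events <- data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                         amp = numeric(0), r = numeric(0), g = numeric(0),
                         b = numeric(0))
    if (n_ev > 0) {
      for (k in seq_len(n_ev)) {
        x <- stats::runif(1, min(cols), max(cols))
        y <- stats::rnorm(1, scene$stripe_row, scene$event_band_sd)
        y <- min(max(y, 1), H)
        sg <- stats::runif(1, scene$event_sigma_range[1], scene$event_sigma_range[2])
        amp <- stats::runif(1, scene$event_amp_range[1], scene$event_amp_range[2]) * pscale
        jp <- params
        if (nrow(jp$lines))
          jp$lines[, "amplitude"] <- jp$lines[, "amplitude"] *
            exp(stats::rnorm(nrow(jp$lines), 0, 0.15))
        jp$continuum[, "amplitude"] <- jp$continuum[, "amplitude"] *
          exp(stats::rnorm(1, 0, 0.15))
        jp$noise_sd <- 0
        spec <- make_emission_spectrum(class_label, power_fraction = p,
                                       params = jp, clamping = clamping)
        rgb <- spectrum_to_rgb(spec, camera)
        if (max(rgb) > 0) rgb <- rgb / max(rgb)
        r_lo <- max(1, floor(y - 3 * sg)); r_hi <- min(H, ceiling(y + 3 * sg))
        c_lo <- max(1, floor(x - 3 * sg)); c_hi <- min(W, ceiling(x + 3 * sg))
        rr <- r_lo:r_hi; cc <- c_lo:c_hi
        blob <- exp(-(outer((rr - y)^2, (cc - x)^2, "+")) / (2 * sg^2))
        for (ch in 1:3)
          frame[rr, cc, ch] <- frame[rr, cc, ch] + amp * rgb[ch] * blob
        events[k, ] <- c(x, y, sg, amp, rgb)
      }
    }
    frame <- round(pmin(pmax(frame, 0), 1) * 255) / 255
    structure(list(pixels = frame, label = class_label,
                   power_fraction = p, seed = seed, events = events),
              class = "labeled_image")
  })
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<labeled_image> %s, %dx%d px, power %.2f, %d event(s)\n",
              x$label, d[2], d[1], x$power_fraction, nrow(x$events)))
  invisible(x)
}
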