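#' Derive a stage seed from a master seed
#'
#' Every random consumer in the package draws its seed from a single master
#' seed plus a stage tag, so that a whole experiment is reproducible from one
#' integer while stages stay statistically decoupled.
#'
#' @param master integer master seed.
#' @param stage character tag naming the consumer (e.g. `"dataset"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(master) %% 2147483647 * 48271 + h * 16807) %% 2147483562 + 1)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Gaussian profile parameterised by full width at half maximum.
gaussian_fwhm <- function(x, center, fwhm, amplitude = 1) {
  amplitude * exp(-4 * log(2) * (x - center)^2 / fwhm^2)
}

# Analytic area of a Gaussian line of peak height `amplitude`.
gaussian_fwhm_area <- function(fwhm, amplitude = 1) {
  amplitude * fwhm * sqrt(pi / (4 * log(2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
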