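#' Synthetic SERS spectrum configuration
#'
#' Parameters of the instrument emulator: sharp peaks at library positions
#' riding on a smooth fifth-order polynomial fluorescence background with
#' additive Gaussian noise, measured as several parallel replicates whose
#' overall amplitude varies slightly from spot to spot.
#'
#' @param peak_shape `"gaussian"` (default) or `"lorentzian"` lineshape.
#' @param base_amplitude apex height in a.u. assigned to normalized
#'   intensity 1 (default 4000; must exceed 400 so that at least the
#'   strongest peak survives the standard height filter).
#' @param peak_fwhm full width at half maximum in cm^-1 (default 12; must
#'   be < 100, the width filter ceiling).
#' @param background_coefficients 6 coefficients (constant first) of a
#'   fifth-order polynomial evaluated on the wavenumber axis rescaled to
#'   \[-1, 1\]; the evaluated curve is clipped at 0.
#' @param noise_sd additive Gaussian noise standard deviation in a.u.
#'   (default 20).
#' @param replicate_count spectra per sample (default 6, the measurement
#'   protocol's parallel-spot count).
#' @param replicate_jitter fractional amplitude variation across replicates
#'   (default 0.05): replicate r scales all peaks by a common factor
#'   `1 + U(-jitter, jitter)`.
#' @param seed integer RNG seed; replicate r uses a stream derived from
#'   `(seed, r)`.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(peak_shape = c("gaussian", "lorentzian"),
                             base_amplitude = 4000, peak_fwhm = 12,
                             background_coefficients = c(0, 0, 0, 0, 0, 0),
                             noise_sd = 20, replicate_count = 6,
                             replicate_jitter = 0.05, seed = 7) {
  peak_shape <- match.arg(peak_shape)
  if (!(base_amplitude > 400)) {
    stop("synthetic_config: base_amplitude must exceed 400 a.u.")
  }
  if (!(peak_fwhm > 0 && peak_fwhm < 100)) {
    stop("synthetic_config: peak_fwhm must lie in (0, 100) cm^-1")
  }
  if (length(background_coefficients) != 6) {
    stop("synthetic_config: exactly 6 background coefficients required")
  }
  if (noise_sd < 0) stop("synthetic_config: noise_sd must be >= 0")
  if (replicate_count < 1) stop("synthetic_config: replicate_count must be >= 1")
  if (replicate_jitter < 0) stop("synthetic_config: replicate_jitter must be >= 0")
  structure(list(peak_shape = peak_shape,
                 base_amplitude = as.numeric(base_amplitude),
                 peak_fwhm = as.numeric(peak_fwhm),
                 background_coefficients = as.numeric(background_coefficients),
                 noise_sd = as.numeric(noise_sd),
                 replicate_count = as.integer(replicate_count),
                 replicate_jitter = as.numeric(replicate_jitter),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Rescale a wavenumber axis to [-1, 1]; shared by the generator and the
# baseline fit for numerical conditioning of fifth-order polynomials.
scale_axis <- function(wavenumbers) {
  lo <- min(wavenumbers); hi <- max(wavenumbers)
  2 * (wavenumbers - lo) / (hi - lo) - 1
}

eval_poly <- function(coefficients, x) {
  # coefficients[1] + coefficients[2]*x + ... (constant first)
  y <- numeric(length(x))
  for (k in rev(seq_along(coefficients))) y <- y * x + coefficients[k]
  y
}

#' Generate a polynomial fluorescence background
#'
#' Evaluates a fifth-order polynomial (6 coefficients, constant first) on
#' the grid's wavenumber axis rescaled to \[-1, 1\], clipped at 0 so the
#' background is non-negative.
#'
#' @param grid a [wavenumber_grid].
#' @param coefficients numeric vector of exactly 6 coefficients.
#' @return A [raman_spectrum] holding the background curve.
#' @export
generate_background <- function(grid = wavenumber_grid(),
                                coefficients = c(0, 0, 0, 0, 0, 0)) {
  stopifnot(inherits(grid, "wavenumber_grid"))
  if (length(coefficients) != 6) {
    stop("generate_background: exactly 6 coefficients required")
  }
  x <- scale_axis(grid$wavenumbers)
  y <- pmax(eval_poly(as.numeric(coefficients), x), 0)
  raman_spectrum(y, grid = grid, label = "background")
}

# Unit-apex lineshape centered at `position` with the given FWHM.
peak_lineshape <- function(wavenumbers, position, fwhm, shape) {
  if (shape == "gaussian") {
    exp(-4 * log(2) * (wavenumbers - position)^2 / fwhm^2)
  } else {
    1 / (1 + (2 * (wavenumbers - position) / fwhm)^2)
  }
}

# Noise-free, jitter-free analytic peak sum for a pattern: the oracle the
# generator and tests share.
peak_sum <- function(pattern, config, grid) {
  wn <- grid$wavenumbers
  y <- numeric(length(wn))
  for (i in seq_len(n_peaks(pattern))) {
    y <- y + pattern$peaks$normalized_intensity[i] * config$base_amplitude *
      peak_lineshape(wn, pattern$peaks$position[i], config$peak_fwhm,
                     config$peak_shape)
  }
  y
}

replicate_rng_seed <- function(seed, replicate_index) {
  (as.integer(seed) + 7919L * as.integer(replicate_index)) %% 2147483647L
}

#' Generate one synthetic replicate spectrum
#'
#' intensities = background + sum over pattern peaks of
#' lineshape(position, fwhm) x normalized_intensity x base_amplitude x
#' (1 + jitter_r) + Gaussian noise, with jitter and noise drawn from an RNG
#' stream derived deterministically from `(config$seed, replicate_index)`.
#' Peak apexes land exactly on grid points when library positions are
#' on-grid.
#'
#' @param pattern a non-empty [peak_pattern].
#' @param config a [synthetic_config].
#' @param replicate_index 1-based replicate number.
#' @param grid target [wavenumber_grid].
#' @return A [raman_spectrum] labelled `"<cultivar> [replicate <r>]"`.
#' @export
generate_spectrum <- function(pattern, config = synthetic_config(),
                              replicate_index = 1,
                              grid = wavenumber_grid()) {
  stopifnot(inherits(pattern, "peak_pattern"),
            inherits(config, "synthetic_config"))
  if (n_peaks(pattern) == 0) {
    stop("generate_spectrum: pattern has no peaks; use generate_background() for a background-only spectrum")
  }
  bg <- generate_background(grid, config$background_coefficients)
  signal <- peak_sum(pattern, config, grid)
  rng <- local({
    set.seed(replicate_rng_seed(config$seed, replicate_index))
    jitter_r <- if (config$replicate_jitter > 0) {
      stats::runif(1, -config$replicate_jitter, config$replicate_jitter)
    } else 0
    noise <- if (config$noise_sd > 0) {
      stats::rnorm(length(grid$wavenumbers), sd = config$noise_sd)
    } else numeric(length(grid$wavenumbers))
    list(jitter = jitter_r, noise = noise)
  })
  y <- bg$intensities + signal * (1 + rng$jitter) + rng$noise
  raman_spectrum(y, grid = grid,
                 label = sprintf("%s [replicate %d]", pattern$cultivar,
                                 replicate_index),
                 metadata = list(cultivar = pattern$cultivar,
                                 replicate = replicate_index,
                                 seed = config$seed))
}

#' Generate a synthetic replicate set
#'
#' Calls [generate_spectrum()] for replicate indices
#' `1..config$replicate_count`. Identical `(pattern, config)` give
#' bit-identical output.
#'
#' @inheritParams generate_spectrum
#' @return A [replicate_set] named after the pattern's cultivar.
#' @export
generate_replicate_set <- function(pattern, config = synthetic_config(),
                                   grid = wavenumber_grid()) {
  spectra <- lapply(seq_len(config$replicate_count), function(r) {
    generate_spectrum(pattern, config, replicate_index = r, grid = grid)
  })
  replicate_set(pattern$cultivar, spectra)
}
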