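#' Wavenumber grid
#'
#' A regular Raman-shift axis. The default grid is 400--1800 cm\eqn{^{-1}}
#' at 1 cm\eqn{^{-1}} spacing, the acquisition range and resolution used
#' throughout the package.
#'
#' @param start,stop Raman shift bounds in cm^-1 (`start < stop`).
#' @param step grid spacing in cm^-1 (> 0).
#' @return An object of class `wavenumber_grid` with fields `start`, `stop`,
#'   `step` and the evaluated axis `wavenumbers`.
#' @examples
#' g <- wavenumber_grid()
#' length(g$wavenumbers)  # 1401
#' @export
wavenumber_grid <- function(start = 400, stop = 1800, step = 1) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (!(start < stop)) stop("wavenumber_grid: 'start' must be < 'stop'")
  if (!(step > 0)) stop("wavenumber_grid: 'step' must be > 0")
  wn <- seq(start, stop, by = step)
  structure(list(start = start, stop = stop, step = step, wavenumbers = wn),
            class = "wavenumber_grid")
}

#' @export
print.wavenumber_grid <- function(x, ...) {
  cat(sprintf("<wavenumber_grid> %g-%g cm^-1, step %g (%d points)\n",
              x$start, x$stop, x$step, length(x$wavenumbers)))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$start, b$start)) &&
    isTRUE(all.equal(a$stop, b$stop)) &&
    isTRUE(all.equal(a$step, b$step))
}

#' Raman spectrum
#'
#' A spectrum is a vector of arbitrary-unit intensities on a
#' [wavenumber_grid], with a free-text label and a provenance metadata list
#' (e.g. `excitation_nm = 785`, `power_mW = 3.3`; metadata never enters any
#' computation).
#'
#' @param intensities numeric vector, one finite value per grid point.
#' @param grid a [wavenumber_grid] (default grid if omitted).
#' @param label free-text sample label.
#' @param metadata named list of provenance key/value pairs.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(intensities, grid = wavenumber_grid(),
                           label = "", metadata = list()) {
  stopifnot(inherits(grid, "wavenumber_grid"), is.numeric(intensities))
  n <- length(grid$wavenumbers)
  if (length(intensities) != n) {
    stop(sprintf("raman_spectrum: expected %d intensities (one per grid point), got %d",
                 n, length(intensities)))
  }
  if (!all(is.finite(intensities))) {
    stop("raman_spectrum: intensities must all be finite")
  }
  structure(list(grid = grid, intensities = as.numeric(intensities),
                 label = as.character(label), metadata = metadata),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> '%s': %d points, %g-%g cm^-1, intensity range [%.4g, %.4g]\n",
              x$label, length(x$intensities), x$grid$start, x$grid$stop,
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Replicate set
#'
#' Parallel spectra of one sample measured at different spots (default
#' protocol: 6 replicates), all sharing one grid.
#'
#' @param sample_name sample (cultivar) name.
#' @param spectra list of [raman_spectrum] objects on identical grids.
#' @return An object of class `replicate_set`.
#' @export
replicate_set <- function(sample_name, spectra) {
  if (length(spectra) < 1) stop("replicate_set: at least one spectrum required")
  if (!all(vapply(spectra, inherits, logical(1), "raman_spectrum"))) {
    stop("replicate_set: all elements must be raman_spectrum objects")
  }
  g <- spectra[[1]]$grid
  same <- vapply(spectra, function(s) grids_identical(s$grid, g), logical(1))
  if (!all(same)) stop("replicate_set: all spectra must share one grid")
  structure(list(sample_name = as.character(sample_name), spectra = spectra),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> '%s': %d replicate(s), %d grid points\n",
              x$sample_name, length(x$spectra),
              length(x$spectra[[1]]$intensities)))
  invisible(x)
}

#' Characteristic-peak distribution pattern
#'
#' The library record for one cultivar: characteristic peak positions with
#' intensities normalized by the maximum peak height, so that exactly one
#' peak has normalized intensity 1. Absolute heights and FWHM widths are
#' optional: patterns transcribed from published tables carry only position
#' and normalized intensity, patterns produced by [extract_pattern()] carry
#' all four fields.
#'
#' @param cultivar cultivar name.
#' @param position numeric vector of peak positions (cm^-1), strictly
#'   increasing.
#' @param normalized_intensity numeric vector in (0, 1]; its maximum must be
#'   exactly 1 unless the pattern is empty.
#' @param height optional absolute apex heights (a.u., > 0).
#' @param width optional FWHM widths (cm^-1, > 0).
#' @return An object of class `peak_pattern`; `$peaks` is a data.frame with
#'   columns `position`, `normalized_intensity`, `height`, `width`.
#' @examples
#' peak_pattern("Beautiful Purple", position = 732, normalized_intensity = 1)
#' @export
peak_pattern <- function(cultivar, position = numeric(0),
                         normalized_intensity = numeric(0),
                         height = NULL, width = NULL) {
  n <- length(position)
  if (length(normalized_intensity) != n) {
    stop("peak_pattern: 'position' and 'normalized_intensity' lengths differ")
  }
  if (is.null(height)) height <- rep(NA_real_, n)
  if (is.null(width)) width <- rep(NA_real_, n)
  if (length(height) != n || length(width) != n) {
    stop("peak_pattern: 'height'/'width' lengths must match 'position'")
  }
  if (n > 0) {
    if (any(diff(position) <= 0)) {
      stop("peak_pattern: positions must be strictly increasing")
    }
    if (any(normalized_intensity <= 0) || any(normalized_intensity > 1)) {
      stop("peak_pattern: normalized intensities must lie in (0, 1]")
    }
    if (max(normalized_intensity) != 1) {
      stop("peak_pattern: the strongest peak must have normalized intensity exactly 1")
    }
    if (any(!is.na(height) & height <= 0)) stop("peak_pattern: heights must be > 0")
    if (any(!is.na(width) & width <= 0)) stop("peak_pattern: widths must be > 0")
  }
  peaks <- data.frame(position = as.numeric(position),
                      normalized_intensity = as.numeric(normalized_intensity),
                      height = as.numeric(height),
                      width = as.numeric(width))
  structure(list(cultivar = as.character(cultivar), peaks = peaks),
            class = "peak_pattern")
}

n_peaks <- function(pattern) nrow(pattern$peaks)

#' @export
print.peak_pattern <- function(x, ...) {
  cat(sprintf("<peak_pattern> '%s' (%d peak(s))\n", x$cultivar, n_peaks(x)))
  if (n_peaks(x) > 0) {
    cat(sprintf("  %4.0f cm^-1  %6.4g\n",
                x$peaks$position, x$peaks$normalized_intensity), sep = "")
  }
  invisible(x)
}

#' Spectral pattern library
#'
#' A named collection of [peak_pattern] records plus provenance metadata —
#' the reference "data library" used for cultivar identification.
#'
#' @param patterns list of [peak_pattern] objects with unique, non-empty
#'   cultivar names.
#' @param name library name.
#' @param created creation timestamp string (defaults to now, UTC).
#' @param notes free text.
#' @return An object of class `spectral_library`; `$patterns` is a named
#'   list keyed by cultivar.
#' @export
spectral_library <- function(patterns = list(), name = "library",
                             created = format(Sys.time(), tz = "UTC",
                                              "%Y-%m-%dT%H:%M:%SZ"),
                             notes = "") {
  if (!all(vapply(patterns, inherits, logical(1), "peak_pattern"))) {
    stop("spectral_library: all patterns must be peak_pattern objects")
  }
  cultivars <- vapply(patterns, function(p) p$cultivar, character(1))
  if (any(!nzchar(cultivars))) stop("spectral_library: cultivar names must be non-empty")
  if (anyDuplicated(cultivars)) {
    stop(sprintf("spectral_library: duplicate cultivar name(s): %s",
                 paste(unique(cultivars[duplicated(cultivars)]), collapse = ", ")))
  }
  names(patterns) <- cultivars
  structure(list(name = as.character(name), patterns = patterns,
                 created = as.character(created), notes = as.character(notes)),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> '%s': %d pattern(s), created %s\n",
              x$name, length(x$patterns), x$created))
  invisible(x)
}

#' @export
length.spectral_library <- function(x) length(x$patterns)
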