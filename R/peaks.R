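#' Peak detection configuration
#'
#' Filters defining a "characteristic peak": a local maximum of the
#' baseline-corrected spectrum whose apex intensity exceeds `min_height`
#' (a.u., default 400 — the standard height floor for instrument-scale
#' spectra) and whose full width at half maximum is below `max_width`
#' (default 100 cm^-1). Height is the apex intensity above zero of the
#' corrected spectrum, not a prominence relative to neighbouring valleys:
#' after baseline removal the background sits at ~0, so apex intensity is
#' the natural height. Maxima closer than `min_separation` are merged
#' keeping the higher (noise can split one apex into two adjacent maxima;
#' genuinely distinct peaks of one cultivar are tens of cm^-1 apart, so a
#' 5 cm^-1 merge radius cannot fuse true peaks). An optional centered
#' moving-average smoothing (odd window, grid points) is applied for apex
#' *localization* only; reported heights always come from the unsmoothed
#' corrected spectrum.
#'
#' @param min_height apex height floor in a.u. (default 400).
#' @param max_width FWHM ceiling in cm^-1 (default 100).
#' @param min_separation merge radius in cm^-1 (default 5; must be at least
#'   the grid step when used).
#' @param smoothing_window odd integer window in grid points, or 0 for no
#'   smoothing (default 0).
#' @return An object of class `peak_detection_config`.
#' @export
peak_detection_config <- function(min_height = 400, max_width = 100,
                                  min_separation = 5, smoothing_window = 0) {
  if (!(min_height > 0)) stop("peak_detection_config: min_height must be > 0")
  if (!(max_width > 0)) stop("peak_detection_config: max_width must be > 0")
  if (min_separation < 0) {
    stop("peak_detection_config: min_separation must be >= 0")
  }
  if (smoothing_window != 0 &&
      (smoothing_window < 3 || smoothing_window %% 2 == 0)) {
    stop("peak_detection_config: smoothing_window must be 0 or an odd integer >= 3")
  }
  structure(list(min_height = as.numeric(min_height),
                 max_width = as.numeric(max_width),
                 min_separation = as.numeric(min_separation),
                 smoothing_window = as.integer(smoothing_window)),
            class = "peak_detection_config")
}

#' Average a replicate set into the mean spectrum
#'
#' Pointwise arithmetic mean of all (baseline-corrected) replicates; the
#' result is labelled with the sample name. Averaging n replicates reduces
#' independent additive noise by a factor sqrt(n).
#'
#' @param set a [replicate_set].
#' @return A [raman_spectrum].
#' @export
average_replicates <- function(set) {
  stopifnot(inherits(set, "replicate_set"))
  if (length(set$spectra) == 0) stop("average_replicates: empty replicate set")
  mat <- vapply(set$spectra, function(s) s$intensities,
                numeric(length(set$spectra[[1]]$intensities)))
  mat <- matrix(mat, ncol = length(set$spectra))
  raman_spectrum(rowMeans(mat), grid = set$spectra[[1]]$grid,
                 label = set$sample_name,
                 metadata = list(replicates = length(set$spectra)))
}

moving_average <- function(y, window) {
  if (window == 0) return(y)
  half <- (window - 1L) %/% 2L
  n <- length(y)
  out <- stats::filter(y, rep(1 / window, window), sides = 2)
  out <- as.numeric(out)
  # shrink the window near the edges instead of dropping points
  for (i in seq_len(half)) {
    out[i] <- mean(y[1:(i + half)])
    out[n - i + 1] <- mean(y[(n - i + 1 - half):n])
  }
  out
}

# FWHM of the peak at index `apex` via linear interpolation of the two
# half-height crossings; NA when a crossing is not found inside the grid.
fwhm_at <- function(wn, y, apex) {
  half <- y[apex] / 2
  left <- NA_real_
  i <- apex
  while (i > 1) {
    i <- i - 1
    if (y[i] < half) {
      left <- wn[i] + (wn[i + 1] - wn[i]) * (half - y[i]) / (y[i + 1] - y[i])
      break
    }
  }
  right <- NA_real_
  i <- apex
  n <- length(y)
  while (i < n) {
    i <- i + 1
    if (y[i] < half) {
      right <- wn[i - 1] + (wn[i] - wn[i - 1]) * (y[i - 1] - half) / (y[i - 1] - y[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' Detect characteristic peaks
#'
#' Finds local maxima of a baseline-corrected spectrum (optionally after
#' centered moving-average smoothing used for localization only), applies
#' the height and width filters of `config`, and merges maxima closer than
#' `config$min_separation` keeping the higher. Peak height is the apex
#' intensity of the unsmoothed corrected spectrum; width is the FWHM
#' obtained by linear interpolation of the two half-height crossings (peaks
#' whose FWHM cannot be bracketed inside the grid, or is `>= max_width`,
#' are discarded).
#'
#' @param spectrum a baseline-corrected [raman_spectrum].
#' @param config a [peak_detection_config].
#' @return A data.frame of class `peak_list` with columns `position`
#'   (cm^-1, on-grid), `height` (a.u.), `width` (cm^-1 FWHM), ordered by
#'   increasing position; zero rows when nothing passes the filters.
#' @export
detect_peaks <- function(spectrum, config = peak_detection_config()) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(config, "peak_detection_config"))
  wn <- spectrum$grid$wavenumbers
  y <- spectrum$intensities
  if (config$min_separation > 0 && config$min_separation < spectrum$grid$step) {
    stop("detect_peaks: min_separation must be at least the grid step")
  }
  ys <- moving_average(y, config$smoothing_window)
  n <- length(ys)
  if (n < 3) return(empty_peak_list())
  idx <- which(ys[2:(n - 1)] > ys[1:(n - 2)] & ys[2:(n - 1)] >= ys[3:n]) + 1L

  # height filter on the unsmoothed corrected spectrum
  idx <- idx[y[idx] > config$min_height]
  if (length(idx) == 0) return(empty_peak_list())

  # merge apexes closer than min_separation, keeping the higher
  idx <- idx[order(wn[idx])]
  kept <- integer(0)
  for (i in idx) {
    if (length(kept) > 0 && wn[i] - wn[kept[length(kept)]] < config$min_separation) {
      if (y[i] > y[kept[length(kept)]]) kept[length(kept)] <- i
    } else {
      kept <- c(kept, i)
    }
  }

  width <- vapply(kept, function(i) fwhm_at(wn, y, i), numeric(1))
  ok <- !is.na(width) & width < config$max_width
  kept <- kept[ok]
  width <- width[ok]
  if (length(kept) == 0) return(empty_peak_list())
  out <- data.frame(position = wn[kept], height = y[kept], width = width)
  class(out) <- c("peak_list", "data.frame")
  out
}

empty_peak_list <- function() {
  out <- data.frame(position = numeric(0), height = numeric(0),
                    width = numeric(0))
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Normalize detected peaks into a pattern
#'
#' Divides every peak height by the maximum height among the detected
#' peaks, so the strongest peak has normalized intensity exactly 1; peak
#' order by position is preserved. An empty peak list yields an empty
#' pattern with a warning.
#'
#' @param peaks a `peak_list` from [detect_peaks()] (data.frame with
#'   `position`, `height`, and optionally `width` columns).
#' @param cultivar name recorded on the pattern.
#' @return A [peak_pattern].
#' @export
normalize_pattern <- function(peaks, cultivar) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) == 0) {
    warning(sprintf("normalize_pattern: no peaks for '%s'; returning an empty pattern",
                    cultivar))
    return(peak_pattern(cultivar))
  }
  if (any(peaks$height <= 0)) {
    stop("normalize_pattern: peak heights must be positive")
  }
  o <- order(peaks$position)
  peaks <- peaks[o, , drop = FALSE]
  peak_pattern(cultivar,
               position = peaks$position,
               normalized_intensity = peaks$height / max(peaks$height),
               height = peaks$height,
               width = if ("width" %in% names(peaks)) peaks$width else NULL)
}

#' Extract a peak pattern from raw replicates
#'
#' The one-call pipeline: baseline-correct each replicate
#' ([correct_baseline()]), average into the mean spectrum
#' ([average_replicates()]), detect characteristic peaks ([detect_peaks()]),
#' and max-normalize into a [peak_pattern] ([normalize_pattern()]).
#'
#' @param set a raw [replicate_set].
#' @param detection a [peak_detection_config].
#' @param order,max_iterations,tolerance,noise_margin baseline parameters
#'   passed to [correct_baseline()].
#' @return A [peak_pattern] named after the set's sample.
#' @export
extract_pattern <- function(set, detection = peak_detection_config(),
                            order = 5, max_iterations = 100,
                            tolerance = 1e-4, noise_margin = 0) {
  stopifnot(inherits(set, "replicate_set"))
  corrected <- lapply(set$spectra, function(s) {
    correct_baseline(s, order = order, max_iterations = max_iterations,
                     tolerance = tolerance,
                     noise_margin = noise_margin)$corrected
  })
  mean_spec <- average_replicates(replicate_set(set$sample_name, corrected))
  normalize_pattern(detect_peaks(mean_spec, detection), set$sample_name)
}
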