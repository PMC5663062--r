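#' Build a spectral library from patterns
#'
#' Wraps a sequence of validated [peak_pattern]s into a [spectral_library]
#' with creation metadata; cultivar names must be unique.
#'
#' @param patterns list of [peak_pattern] objects.
#' @param name library name.
#' @param notes free text.
#' @return A [spectral_library].
#' @export
build_library <- function(patterns, name = "library", notes = "") {
  spectral_library(patterns, name = name, notes = notes)
}

#' Find cross-cultivar common bands
#'
#' Pools all peak positions across cultivars, sorts them, and splits the
#' pooled sequence wherever two consecutive positions differ by more than
#' `gap_threshold`; each run becomes a band cluster. The clusters partition
#' the pooled peaks, so every peak of every cultivar belongs to exactly one
#' cluster and cluster bounds are the min/max of member positions. A
#' cluster's `support` counts the distinct cultivars represented in it.
#'
#' @param library a non-empty [spectral_library].
#' @param gap_threshold split gap in cm^-1 (default 8: wide enough to keep
#'   1 cm^-1-spaced shared bands together, narrow enough to separate
#'   neighbouring bands tens of cm^-1 apart).
#' @return A data.frame of class `band_clusters` with columns `lower`,
#'   `upper`, `support`, `n_peaks`, and a list-column `members` (named
#'   numeric vector cultivar -> position), ordered by `lower`.
#' @export
find_common_bands <- function(library, gap_threshold = 8) {
  stopifnot(inherits(library, "spectral_library"))
  if (length(library$patterns) == 0) {
    stop("find_common_bands: empty library")
  }
  if (gap_threshold < 0) stop("find_common_bands: gap_threshold must be >= 0")
  pooled <- do.call(rbind, lapply(library$patterns, function(p) {
    if (n_peaks(p) == 0) return(NULL)
    data.frame(cultivar = p$cultivar, position = p$peaks$position)
  }))
  if (is.null(pooled) || nrow(pooled) == 0) {
    out <- data.frame(lower = numeric(0), upper = numeric(0),
                      support = integer(0), n_peaks = integer(0))
    out$members <- list()
    class(out) <- c("band_clusters", "data.frame")
    return(out)
  }
  pooled <- pooled[order(pooled$position), , drop = FALSE]
  gaps <- diff(pooled$position)
  cluster_id <- cumsum(c(1, as.integer(gaps > gap_threshold)))
  split_rows <- split(pooled, cluster_id)
  out <- data.frame(
    lower = vapply(split_rows, function(d) min(d$position), numeric(1)),
    upper = vapply(split_rows, function(d) max(d$position), numeric(1)),
    support = vapply(split_rows, function(d)
      length(unique(d$cultivar)), integer(1)),
    n_peaks = vapply(split_rows, nrow, integer(1))
  )
  out$members <- lapply(split_rows, function(d)
    stats::setNames(d$position, d$cultivar))
  rownames(out) <- NULL
  class(out) <- c("band_clusters", "data.frame")
  out
}

#' Map a normalized intensity to a hue angle
#'
#' The pattern map encodes normalized intensity as hue: a value of 1 maps
#' to red (0 degrees) and values approaching 0 map to violet (270 degrees),
#' linearly in between at full saturation and value. Hue is strictly
#' decreasing in the intensity value.
#'
#' @param value normalized intensity in \[0, 1\].
#' @return Hue angle in degrees on the 270 -> 0 sweep.
#' @examples
#' value_to_hue(1)  # 0 (red)
#' value_to_hue(0)  # 270 (violet)
#' @export
value_to_hue <- function(value) {
  if (any(value < 0 | value > 1)) {
    stop("value_to_hue: value must lie in [0, 1]")
  }
  270 * (1 - value)
}

intensity_color <- function(value) {
  grDevices::hsv(h = value_to_hue(value) / 360, s = 1, v = 1)
}

#' Render the characteristic-peak pattern map
#'
#' Draws the library as a color-block image: one row per cultivar (library
#' order, first pattern on the top row), horizontal axis 400--1800 cm^-1,
#' each peak a colored block at its position whose hue encodes the
#' normalized intensity on the violet-to-red sweep of [value_to_hue()].
#' Output format follows the file extension (`.png` or `.svg`).
#'
#' @param library a non-empty [spectral_library].
#' @param output image file path ending in `.png` or `.svg`.
#' @param block_width full width of each peak block in cm^-1 (default 8).
#' @param width,height device size in pixels (png) or inches (svg).
#' @return Invisibly, a list with `file`, `n_rows` (cultivars drawn) and
#'   `n_blocks` (peaks drawn).
#' @export
render_pattern_map <- function(library, output, block_width = 8,
                               width = if (grepl("\\.svg$", output)) 10 else 1000,
                               height = if (grepl("\\.svg$", output)) 7 else 700) {
  stopifnot(inherits(library, "spectral_library"))
  if (length(library$patterns) == 0) {
    stop("render_pattern_map: empty library")
  }
  ext <- tolower(tools::file_ext(output))
  dev_ok <- tryCatch({
    if (ext == "svg") {
      grDevices::svg(output, width = width, height = height)
    } else if (ext == "png") {
      grDevices::png(output, width = width, height = height, type = "cairo")
    } else {
      stop(sprintf("render_pattern_map: unsupported extension '.%s' (use .png or .svg)",
                   ext))
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(dev_ok)) {
    stop(sprintf("render_pattern_map: cannot open device for %s: %s",
                 output, conditionMessage(dev_ok)))
  }
  on.exit(grDevices::dev.off(), add = TRUE)

  cultivars <- names(library$patterns)
  n <- length(cultivars)
  xlim <- c(400, 1800)
  # par settings die with the device; restoring them after dev.off() would
  # open a spurious default device
  graphics::par(mar = c(4.5, 10, 2.5, 1))
  graphics::plot.new()
  graphics::plot.window(xlim = xlim, ylim = c(0, n), xaxs = "i", yaxs = "i")
  graphics::rect(xlim[1], 0, xlim[2], n, col = "grey92", border = NA)
  n_blocks <- 0L
  for (i in seq_len(n)) {
    p <- library$patterns[[i]]
    ytop <- n - i + 1   # first cultivar on the top row
    ybot <- n - i
    if (n_peaks(p) > 0) {
      graphics::rect(p$peaks$position - block_width / 2, ybot + 0.08,
                     p$peaks$position + block_width / 2, ytop - 0.08,
                     col = intensity_color(p$peaks$normalized_intensity),
                     border = NA)
      n_blocks <- n_blocks + n_peaks(p)
    }
  }
  graphics::abline(h = seq_len(n - 1), col = "white", lwd = 0.5)
  graphics::axis(1, at = seq(400, 1800, by = 200))
  graphics::axis(2, at = seq_len(n) - 0.5, labels = rev(cultivars),
                 las = 2, cex.axis = 0.7, tick = FALSE)
  graphics::title(main = library$name,
                  xlab = expression(paste("Raman shift (", cm^-1, ")")))
  graphics::box()
  invisible(list(file = output, n_rows = n, n_blocks = n_blocks))
}
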