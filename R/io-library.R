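LIBRARY_SCHEMA_VERSION <- "1.0"

#' Save a spectral library as JSON
#'
#' Versioned structured-text schema:
#' `{schema_version, name, created, notes, patterns: [{cultivar,
#' peaks: [{position, normalized_intensity, height?, width?}]}]}`.
#' Round trip through [load_library()] is lossless for cultivar names,
#' positions and normalized intensities.
#'
#' @param library a [spectral_library].
#' @param path destination `.json` file.
#' @return `path`, invisibly.
#' @export
save_library <- function(library, path) {
  stopifnot(inherits(library, "spectral_library"))
  patterns <- lapply(library$patterns, function(p) {
    peaks <- lapply(seq_len(n_peaks(p)), function(i) {
      row <- p$peaks[i, ]
      entry <- list(position = row$position,
                    normalized_intensity = row$normalized_intensity)
      if (!is.na(row$height)) entry$height <- row$height
      if (!is.na(row$width)) entry$width <- row$width
      entry
    })
    list(cultivar = p$cultivar, peaks = peaks)
  })
  doc <- list(schema_version = LIBRARY_SCHEMA_VERSION,
              name = library$name, created = library$created,
              notes = library$notes, patterns = unname(patterns))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a spectral library from JSON
#'
#' Validates the schema written by [save_library()]: unique non-empty
#' cultivar names, strictly increasing peak positions, normalized
#' intensities in (0, 1] with the per-pattern maximum exactly 1. Stored
#' intensities are taken verbatim; no re-normalization is applied.
#'
#' @param path a `.json` file produced by [save_library()] or hand-written
#'   in the same schema.
#' @return A [spectral_library].
#' @export
load_library <- function(path) {
  if (!file.exists(path)) stop(sprintf("load_library: file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version)) {
    stop("load_library: missing 'schema_version' field")
  }
  patterns <- lapply(doc$patterns, function(p) {
    peaks <- p$peaks
    num_or_na <- function(entry, field) {
      if (is.null(entry[[field]])) NA_real_ else as.numeric(entry[[field]])
    }
    peak_pattern(
      cultivar = p$cultivar,
      position = vapply(peaks, function(e) as.numeric(e$position), numeric(1)),
      normalized_intensity = vapply(peaks, function(e)
        as.numeric(e$normalized_intensity), numeric(1)),
      height = vapply(peaks, num_or_na, numeric(1), "height"),
      width = vapply(peaks, num_or_na, numeric(1), "width")
    )
  })
  spectral_library(patterns,
                   name = if (is.null(doc$name)) "library" else doc$name,
                   created = if (is.null(doc$created)) "" else doc$created,
                   notes = if (is.null(doc$notes)) "" else doc$notes)
}

#' Export a library as flat CSV
#'
#' One row per peak with columns `cultivar,position,normalized_intensity`,
#' for spreadsheet use. The JSON schema of [save_library()] remains the
#' lossless interchange format.
#'
#' @param library a [spectral_library].
#' @param path destination `.csv` file.
#' @return `path`, invisibly.
#' @export
export_library_csv <- function(library, path) {
  stopifnot(inherits(library, "spectral_library"))
  rows <- do.call(rbind, c(list(data.frame(cultivar = character(0),
                                           position = numeric(0),
                                           normalized_intensity = numeric(0))),
                           lapply(library$patterns, function(p) {
    if (n_peaks(p) == 0) return(NULL)
    data.frame(cultivar = p$cultivar, position = p$peaks$position,
               normalized_intensity = p$peaks$normalized_intensity)
  })))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
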