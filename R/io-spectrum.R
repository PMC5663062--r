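#' Read a two-column spectrum file
#'
#' Reads a (wavenumber, intensity) text file and resamples it by linear
#' interpolation onto `grid` if the native axis differs. Lines starting with
#' `#` are treated as comment headers; `# key: value` lines written by
#' [write_spectrum()] are restored into the metadata list. The native axis
#' extent is recorded in metadata (`native_min`, `native_max`, `native_n`)
#' whenever resampling occurred.
#'
#' @param path file to read.
#' @param dialect `"auto"` (default) sniffs the delimiter;
#'   `"two-column-text"` forces whitespace splitting; `"delimited-with-header"`
#'   expects a delimited file whose first non-comment line is a header row.
#' @param grid target [wavenumber_grid].
#' @return A [raman_spectrum] on `grid`.
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, dialect = c("auto", "two-column-text",
                                            "delimited-with-header"),
                          grid = wavenumber_grid()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("read_spectrum: file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  metadata <- list()
  label <- ""
  is_comment <- startsWith(trimws(lines), "#")
  for (cl in lines[is_comment]) {
    body <- sub("^\\s*#\\s*", "", cl)
    m <- regmatches(body, regexec("^([^:]+):\\s*(.*)$", body))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2]); val <- trimws(m[3])
      if (key == "label") label <- val else metadata[[key]] <- val
    }
  }
  data_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (dialect == "delimited-with-header" && length(data_idx) > 0) {
    data_idx <- data_idx[-1]  # drop header row
  }
  if (length(data_idx) == 0) stop(sprintf("read_spectrum: no data rows in %s", path))

  split_row <- function(line) {
    if (grepl(",", line, fixed = TRUE)) {
      strsplit(trimws(line), "\\s*,\\s*")[[1]]
    } else {
      strsplit(trimws(line), "\\s+")[[1]]
    }
  }
  wn <- numeric(length(data_idx))
  y <- numeric(length(data_idx))
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    fields <- split_row(lines[i])
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2 || any(is.na(vals))) {
      stop(sprintf("read_spectrum: malformed row at line %d of %s: '%s'",
                   i, path, lines[i]))
    }
    wn[k] <- vals[1]; y[k] <- vals[2]
  }
  o <- order(wn)
  wn <- wn[o]; y <- y[o]

  target <- grid$wavenumbers
  native <- length(wn) == length(target) && max(abs(wn - target)) < 1e-9
  if (!native) {
    if (min(wn) > min(target) || max(wn) < max(target)) {
      stop(sprintf(paste0("read_spectrum: wavenumber coverage %g-%g of %s is ",
                          "narrower than the requested grid %g-%g"),
                   min(wn), max(wn), path, min(target), max(target)))
    }
    y <- stats::approx(wn, y, xout = target, method = "linear")$y
    metadata$native_min <- min(wn)
    metadata$native_max <- max(wn)
    metadata$native_n <- length(wn)
  }
  raman_spectrum(y, grid = grid, label = label, metadata = metadata)
}

#' Write a spectrum as two-column text
#'
#' Writes `# key: value` comment headers (label plus metadata) followed by
#' whitespace-separated (wavenumber, intensity) rows at 8 significant
#' digits, so that [read_spectrum()] recovers the spectrum to better than
#' 1e-6 relative.
#'
#' @param spectrum a [raman_spectrum].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  header <- character(0)
  if (nzchar(spectrum$label)) {
    header <- c(header, sprintf("# label: %s", spectrum$label))
  }
  for (key in names(spectrum$metadata)) {
    header <- c(header, sprintf("# %s: %s", key,
                                format(spectrum$metadata[[key]])))
  }
  rows <- sprintf("%.10g %.8g", spectrum$grid$wavenumbers, spectrum$intensities)
  ok <- tryCatch({
    writeLines(c(header, rows), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("write_spectrum: cannot write %s: %s", path,
                 conditionMessage(ok)))
  }
  invisible(path)
}
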