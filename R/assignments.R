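#' Compound assignment table
#'
#' Reference vibrational bands for tentative compound assignment. Each entry
#' carries a compound name, its compound class, a reference position —
#' either a single wavenumber or an inclusive interval — and a vibration
#' label (stretching/deformation/rocking plus conformation). Point
#' references are matched within `tolerance` cm^-1; interval references
#' match any position they contain.
#'
#' @param compound character vector of compound names.
#' @param compound_class character vector of compound classes.
#' @param ref_lower,ref_upper numeric reference bounds in cm^-1
#'   (`ref_lower == ref_upper` for a point reference); all within
#'   100--4000 cm^-1.
#' @param vibration character vector of vibration-mode labels ("" if the
#'   source gives none).
#' @param tolerance half-window in cm^-1 applied to point references
#'   (default 3, the window within which nearby peaks are treated as the
#'   same band).
#' @return An object of class `assignment_table`; `$entries` is a data.frame.
#' @export
assignment_table <- function(compound, compound_class, ref_lower, ref_upper,
                             vibration = "", tolerance = 3) {
  n <- length(compound)
  vibration <- rep_len(vibration, n)
  stopifnot(length(compound_class) == n, length(ref_lower) == n,
            length(ref_upper) == n)
  if (tolerance < 0) stop("assignment_table: tolerance must be >= 0")
  if (any(ref_lower > ref_upper)) {
    stop("assignment_table: interval bounds must be ordered (lower <= upper)")
  }
  if (any(ref_lower < 100) || any(ref_upper > 4000)) {
    stop("assignment_table: reference positions must lie within 100-4000 cm^-1")
  }
  entries <- data.frame(compound = as.character(compound),
                        compound_class = as.character(compound_class),
                        ref_lower = as.numeric(ref_lower),
                        ref_upper = as.numeric(ref_upper),
                        vibration = as.character(vibration))
  structure(list(entries = entries, tolerance = as.numeric(tolerance)),
            class = "assignment_table")
}

#' @export
print.assignment_table <- function(x, ...) {
  cat(sprintf("<assignment_table> %d entries, tolerance %g cm^-1\n",
              nrow(x$entries), x$tolerance))
  invisible(x)
}

#' Save / load an assignment table (JSON)
#'
#' Schema: `{schema_version, tolerance, entries: [{compound, compound_class,
#' reference: number | [lower, upper], vibration}]}`.
#'
#' @param table an [assignment_table].
#' @param path a `.json` file.
#' @return `path` (save) or an [assignment_table] (load).
#' @export
save_assignment_table <- function(table, path) {
  stopifnot(inherits(table, "assignment_table"))
  entries <- lapply(seq_len(nrow(table$entries)), function(i) {
    e <- table$entries[i, ]
    ref <- if (e$ref_lower == e$ref_upper) e$ref_lower else
      c(e$ref_lower, e$ref_upper)
    list(compound = e$compound, compound_class = e$compound_class,
         reference = ref, vibration = e$vibration)
  })
  doc <- list(schema_version = LIBRARY_SCHEMA_VERSION,
              tolerance = table$tolerance, entries = entries)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_assignment_table
#' @export
load_assignment_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("load_assignment_table: file not found: %s", path))
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  refs <- lapply(doc$entries, function(e) as.numeric(unlist(e$reference)))
  assignment_table(
    compound = vapply(doc$entries, function(e) e$compound, character(1)),
    compound_class = vapply(doc$entries, function(e) e$compound_class,
                            character(1)),
    ref_lower = vapply(refs, min, numeric(1)),
    ref_upper = vapply(refs, max, numeric(1)),
    vibration = vapply(doc$entries, function(e)
      if (is.null(e$vibration)) "" else e$vibration, character(1)),
    tolerance = if (is.null(doc$tolerance)) 3 else as.numeric(doc$tolerance)
  )
}
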