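#' Pipeline run configuration
#'
#' Bundles the stage parameters of the end-to-end pipeline: baseline
#' correction, peak detection, matching, and (for synthetic inputs) the
#' spectrum generator, plus the seed recorded with every run.
#'
#' @param detection a [peak_detection_config].
#' @param baseline_order,baseline_max_iterations,baseline_tolerance,noise_margin
#'   parameters of [correct_baseline()].
#' @param match_tolerance pairing window of [identify_cultivar()] in cm^-1.
#' @param synthetic a [synthetic_config] used when the input is a cultivar
#'   name; its seed is overridden by `seed`.
#' @param seed integer seed governing all randomness of the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(detection = peak_detection_config(),
                       baseline_order = 5, baseline_max_iterations = 100,
                       baseline_tolerance = 1e-4, noise_margin = 0,
                       match_tolerance = 4,
                       synthetic = synthetic_config(), seed = 7) {
  stopifnot(inherits(detection, "peak_detection_config"),
            inherits(synthetic, "synthetic_config"))
  synthetic$seed <- as.integer(seed)
  structure(list(detection = detection, baseline_order = baseline_order,
                 baseline_max_iterations = baseline_max_iterations,
                 baseline_tolerance = baseline_tolerance,
                 noise_margin = noise_margin,
                 match_tolerance = match_tolerance,
                 synthetic = synthetic, seed = as.integer(seed)),
            class = "run_config")
}

read_replicate_dir <- function(path) {
  files <- sort(list.files(path, full.names = TRUE,
                           pattern = "\\.(txt|csv|dat|tsv)$"))
  if (length(files) == 0) {
    stop(sprintf("run_pipeline: no spectrum files (*.txt|*.csv|*.dat|*.tsv) in %s",
                 path))
  }
  replicate_set(basename(normalizePath(path)),
                lapply(files, read_spectrum))
}

#' Run the end-to-end pipeline
#'
#' Resolves the input to a replicate set (a [replicate_set] object, a
#' directory of two-column spectrum files, or — for synthetic runs — a
#' cultivar name present in `library`), then baseline-corrects every
#' replicate, averages them into the mean spectrum, extracts and normalizes
#' the characteristic-peak pattern, identifies the cultivar against the
#' library, and tentatively assigns compounds. When `out_dir` is given,
#' corrected spectra, the mean spectrum, the pattern (one-pattern library
#' JSON), the identification and assignment tables (CSV), and the
#' configuration actually used (JSON, including the seed) are written
#' there, so every run is reproducible from its emitted config.
#'
#' @param input a [replicate_set], a directory path, or a library cultivar
#'   name.
#' @param config a [run_config].
#' @param library reference [spectral_library] (default: the bundled
#'   26-cultivar library).
#' @param assignments an [assignment_table] (default: the bundled reference
#'   bands).
#' @param out_dir optional output directory (created if missing).
#' @return A list with `pattern` ([peak_pattern]), `mean_spectrum`,
#'   `identification` (ranked data.frame), `assignments` (data.frame),
#'   `top_hit` (character), and `files` (named character vector of written
#'   paths, empty when `out_dir` is NULL).
#' @export
run_pipeline <- function(input, config = run_config(),
                         library = chrysanthemum_library(),
                         assignments = compound_assignments(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  set <- if (inherits(input, "replicate_set")) {
    input
  } else if (is.character(input) && length(input) == 1 && dir.exists(input)) {
    read_replicate_dir(input)
  } else if (is.character(input) && length(input) == 1 &&
             input %in% names(library$patterns)) {
    generate_replicate_set(library$patterns[[input]], config$synthetic)
  } else {
    stop(sprintf(paste0("run_pipeline: input '%s' is neither a replicate ",
                        "set, an existing directory, nor a library cultivar"),
                 if (is.character(input)) input else class(input)[1]))
  }

  corrected <- lapply(set$spectra, function(s) {
    correct_baseline(s, order = config$baseline_order,
                     max_iterations = config$baseline_max_iterations,
                     tolerance = config$baseline_tolerance,
                     noise_margin = config$noise_margin)$corrected
  })
  corrected_set <- replicate_set(set$sample_name, corrected)
  mean_spec <- average_replicates(corrected_set)
  pattern <- normalize_pattern(detect_peaks(mean_spec, config$detection),
                               set$sample_name)
  identification <- if (n_peaks(pattern) > 0) {
    identify_cultivar(pattern, library, tolerance = config$match_tolerance)
  } else NULL
  assigned <- assign_compounds(pattern, assignments)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(corrected)) {
      f <- file.path(out_dir, sprintf("corrected_%02d.txt", i))
      write_spectrum(corrected[[i]], f)
      files[sprintf("corrected_%02d", i)] <- f
    }
    files["mean_spectrum"] <- file.path(out_dir, "mean_spectrum.txt")
    write_spectrum(mean_spec, files["mean_spectrum"])
    files["pattern"] <- file.path(out_dir, "pattern.json")
    save_library(build_library(list(pattern), name = set$sample_name),
                 files["pattern"])
    if (!is.null(identification)) {
      files["identification"] <- file.path(out_dir, "identification.csv")
      utils::write.csv(as.data.frame(identification)[
        , c("rank", "cultivar", "score", "n_matched",
            "total_position_deviation")],
        files["identification"], row.names = FALSE)
    }
    files["assignments"] <- file.path(out_dir, "assignments.csv")
    utils::write.csv(as.data.frame(assigned), files["assignments"],
                     row.names = FALSE)
    files["config"] <- file.path(out_dir, "run_config.json")
    jsonlite::write_json(list(
      seed = config$seed,
      baseline = list(order = config$baseline_order,
                      max_iterations = config$baseline_max_iterations,
                      tolerance = config$baseline_tolerance,
                      noise_margin = config$noise_margin),
      detection = unclass(config$detection),
      match_tolerance = config$match_tolerance,
      synthetic = unclass(config$synthetic)
    ), files["config"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(pattern = pattern, mean_spectrum = mean_spec,
       identification = identification,
       assignments = assigned,
       top_hit = if (!is.null(identification)) identification$cultivar[1]
                 else NA_character_,
       files = files)
}
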