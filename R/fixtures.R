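#' Bundled 26-cultivar chrysanthemum pattern library
#'
#' The reference SERS peak-pattern library for 26 Chinese ornamental
#' chrysanthemum cultivars: characteristic peak positions (cm^-1) and
#' max-normalized intensities per cultivar, transcribed from the published
#' reference table. Patterns carry positions and normalized intensities
#' only (absolute heights/widths were not published). One intensity (White
#' Jade, 1022 cm^-1) is recorded to four decimals, 0.0422, exactly as
#' printed in the source table.
#'
#' @return A [spectral_library] of 26 patterns, in the reference table's
#'   row order.
#' @examples
#' lib <- chrysanthemum_library()
#' length(lib)
#' @export
chrysanthemum_library <- function() {
  path <- system.file("extdata", "chrysanthemum_patterns.json",
                      package = "chrysoraman", mustWork = TRUE)
  load_library(path)
}

#' Bundled compound reference-band table
#'
#' Tentative vibrational-band assignments for plant metabolites: amino
#' acids (cysteine 512, methionine 630--670 and 700--745), solvated
#' disordered protein structure 1245, lipids/fatty acids 800--1100, sucrose
#' 1462, the bicyclic monoterpenes 1,8-cineol and sabinene (both 652),
#' crocetin 1020, chlorophyll a/b 1326 and chlorophyll a 1549, and
#' carotenoid 956--957 cm^-1. Default point-reference tolerance: 3 cm^-1.
#'
#' @return An [assignment_table].
#' @examples
#' tab <- compound_assignments()
#' nrow(tab$entries)
#' @export
compound_assignments <- function() {
  path <- system.file("extdata", "compound_assignments.json",
                      package = "chrysoraman", mustWork = TRUE)
  load_assignment_table(path)
}
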