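# Shared study conditions for synthetic round-trip experiments: Gaussian
# peaks (FWHM 12 cm^-1) at 4000 a.u. base amplitude on the fifth-order
# background (800, 400, -300, 100, 0, 0), noise SD 20 a.u., 6 replicates
# with 5% amplitude jitter. Detection for spectra at this scale uses a
# 100 a.u. height floor (above the averaged noise floor ~8 a.u., below the
# weakest library peak at 0.0422 x 4000 = 168.8 a.u.) and a 5-point
# smoothing window for apex localization; the baseline iteration cap is
# raised to 200 for headroom on noisy replicates.

roundtrip_synthetic_config <- function(seed = 7, ...) {
  synthetic_config(background_coefficients = c(800, 400, -300, 100, 0, 0),
                   seed = seed, ...)
}

roundtrip_detection_config <- function() {
  peak_detection_config(min_height = 100, smoothing_window = 5)
}

roundtrip_extract <- function(pattern, seed = 7) {
  set <- generate_replicate_set(pattern, roundtrip_synthetic_config(seed))
  extract_pattern(set, roundtrip_detection_config(), max_iterations = 200)
}

# Analytic Gaussian lineshape: the independent oracle for generator and
# peak-detection checks.
gauss_peak <- function(x, position, height, fwhm) {
  height * exp(-4 * log(2) * (x - position)^2 / fwhm^2)
}

noise_free_config <- function(...) {
  synthetic_config(noise_sd = 0, replicate_jitter = 0, ...)
}
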