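test_that("replicate averaging is the pointwise mean", {
  g <- wavenumber_grid()
  s <- raman_spectrum(runif(1401, 0, 100), g)
  set6 <- replicate_set("same", rep(list(s), 6))
  expect_equal(average_replicates(set6)$intensities, s$intensities)
  expect_equal(average_replicates(set6)$label, "same")

  z <- raman_spectrum(numeric(1401), g)
  c2 <- raman_spectrum(rep(24, 1401), g)
  expect_true(all(average_replicates(replicate_set("x", list(z, c2)))$intensities == 12))
})

test_that("averaging shrinks noise roughly sqrt(n)-fold", {
  gq <- chrysanthemum_library()$patterns[["Golden Queen"]]
  cfg <- synthetic_config(noise_sd = 20, replicate_jitter = 0, seed = 21)
  set <- generate_replicate_set(gq, cfg)
  clean <- generate_spectrum(gq, noise_free_config(), 1)$intensities
  single_sd <- sd(set$spectra[[1]]$intensities - clean)
  mean_sd <- sd(average_replicates(set)$intensities - clean)
  expect_equal(single_sd / mean_sd, sqrt(6), tolerance = 0.15)
})

test_that("a flat spectrum yields no peaks", {
  expect_equal(nrow(detect_peaks(raman_spectrum(numeric(1401)))), 0)
})

test_that("an isolated Gaussian is measured at its analytic height and width", {
  g <- wavenumber_grid()
  y <- gauss_peak(g$wavenumbers, 731, 1000, 12)
  pk <- detect_peaks(raman_spectrum(y, g))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$position, 731)
  expect_lt(abs(pk$height - 1000) / 1000, 0.01)
  expect_lt(abs(pk$width - 12), 1)
})

test_that("a noise-free synthetic Golden Queen gives exactly the table peaks", {
  gq <- chrysanthemum_library()$patterns[["Golden Queen"]]
  s <- generate_spectrum(gq, noise_free_config(), 1)
  pk <- detect_peaks(s, peak_detection_config(min_height = 100))
  expect_equal(pk$position, c(569, 624, 652, 731, 958, 1324, 1462))
})

test_that("height and width filters discard what they should", {
  g <- wavenumber_grid()
  wn <- g$wavenumbers
  y <- gauss_peak(wn, 700, 350, 12) +     # below the 400 a.u. floor
    gauss_peak(wn, 1000, 1000, 12) +      # passes
    gauss_peak(wn, 1400, 1000, 150)       # too wide
  pk <- detect_peaks(raman_spectrum(y, g))
  expect_equal(pk$position, 1000)

  # raising min_height never increases the peak count
  counts <- vapply(c(50, 200, 400, 900, 1500), function(h)
    nrow(detect_peaks(raman_spectrum(y, g),
                      peak_detection_config(min_height = h))), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("apexes closer than the separation radius merge keeping the higher", {
  g <- wavenumber_grid()
  wn <- g$wavenumbers
  # two grid-adjacent spikes on a shared shoulder: one apex pair 3 cm^-1 apart
  y <- gauss_peak(wn, 900, 1000, 12)
  y[wn == 903] <- y[wn == 903] + 120  # noise-split side apex
  pk <- detect_peaks(raman_spectrum(y, g),
                     peak_detection_config(min_separation = 5))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$position, 900)
  pk2 <- detect_peaks(raman_spectrum(y, g),
                      peak_detection_config(min_separation = 1))
  expect_equal(nrow(pk2), 2)
})

test_that("normalization divides by the maximum height", {
  pk <- data.frame(position = c(652, 731), height = c(620, 4000),
                   width = c(12, 12))
  pat <- normalize_pattern(pk, "Golden Queen")
  expect_equal(pat$peaks$normalized_intensity, c(0.155, 1))

  single <- normalize_pattern(data.frame(position = 732, height = 777,
                                         width = 12), "x")
  expect_equal(single$peaks$normalized_intensity, 1)

  ties <- normalize_pattern(data.frame(position = c(500, 600, 700),
                                       height = c(5, 5, 5),
                                       width = c(12, 12, 12)), "x")
  expect_equal(ties$peaks$normalized_intensity, c(1, 1, 1))

  expect_warning(empty <- normalize_pattern(empty_peaks <- data.frame(
    position = numeric(0), height = numeric(0)), "x"), "empty")
  expect_equal(nrow(empty$peaks), 0)
  expect_error(normalize_pattern(data.frame(position = 1, height = -2), "x"),
               "positive")
})

test_that("extract_pattern recovers published single- and two-peak cultivars", {
  lib <- chrysanthemum_library()
  bp <- roundtrip_extract(lib$patterns[["Beautiful Purple"]])
  expect_equal(nrow(bp$peaks), 1)
  expect_lte(abs(bp$peaks$position - 732), 1)
  expect_equal(bp$peaks$normalized_intensity, 1)

  mrp <- roundtrip_extract(lib$patterns[["Mini Red Peach"]])
  expect_equal(nrow(mrp$peaks), 2)
  expect_lte(max(abs(mrp$peaks$position - c(731, 1335))), 1)
  expect_lt(abs(mrp$peaks$normalized_intensity[2] - 0.188), 0.02)
})

test_that("a set whose peaks sit under the height floor yields an empty pattern", {
  weak <- peak_pattern("weak", c(700, 1100), c(0.5, 1))
  cfg <- synthetic_config(base_amplitude = 401, noise_sd = 0,
                          replicate_jitter = 0, replicate_count = 2)
  set <- generate_replicate_set(weak, cfg)
  expect_warning(pat <- extract_pattern(set,
                                        peak_detection_config(min_height = 800)),
                 "empty")
  expect_equal(nrow(pat$peaks), 0)
})

test_that("recovered patterns are invariant to the fluorescence background", {
  lib <- chrysanthemum_library()
  base <- roundtrip_extract(lib$patterns[["Afric Ju"]])
  for (cf in list(c(0, 0, 0, 0, 0, 0), c(1800, 100, -600, 50, -30, 15))) {
    cfg <- synthetic_config(background_coefficients = cf, seed = 7)
    set <- generate_replicate_set(lib$patterns[["Afric Ju"]], cfg)
    # background-free spectra converge slowest: the clipping refit creeps
    # toward the lower noise envelope, so allow extra iterations
    pat <- extract_pattern(set, roundtrip_detection_config(),
                           max_iterations = 300)
    expect_equal(pat$peaks$position, base$peaks$position)
    expect_lt(max(abs(pat$peaks$normalized_intensity -
                        base$peaks$normalized_intensity)), 0.02)
  }
})
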