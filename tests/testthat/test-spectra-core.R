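test_that("domain constructors enforce their invariants", {
  expect_error(wavenumber_grid(1800, 400), "start")
  expect_error(wavenumber_grid(400, 1800, 0), "step")
  expect_equal(length(wavenumber_grid()$wavenumbers), 1401)

  g <- wavenumber_grid()
  expect_error(raman_spectrum(numeric(10), g), "expected 1401")
  expect_error(raman_spectrum(c(rep(0, 1400), NA), g), "finite")

  s1 <- raman_spectrum(numeric(1401), g)
  s2 <- raman_spectrum(numeric(141), wavenumber_grid(400, 1800, 10))
  expect_error(replicate_set("x", list()), "at least one")
  expect_error(replicate_set("x", list(s1, s2)), "one grid")

  expect_error(peak_pattern("x", c(732, 652), c(1, 0.5)), "increasing")
  expect_error(peak_pattern("x", c(652, 732), c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(peak_pattern("x", c(652, 732), c(0.5, 0.9)), "exactly 1")
  expect_silent(peak_pattern("x", c(652, 732), c(0.5, 1)))

  p <- peak_pattern("Same", 732, 1)
  expect_error(spectral_library(list(p, p)), "duplicate")
  expect_error(spectral_library(list(peak_pattern("", 732, 1))), "non-empty")
  expect_equal(length(spectral_library(list())), 0)
})

test_that("spectrum write/read round-trips within 1e-6 relative", {
  g <- wavenumber_grid()
  tmp <- withr::local_tempfile(fileext = ".txt")

  # zero spectrum: one row per grid point
  write_spectrum(raman_spectrum(numeric(1401), g), tmp)
  expect_equal(length(readLines(tmp)), 1401)
  expect_true(all(read_spectrum(tmp)$intensities == 0))

  # arbitrary spectrum round-trips, with metadata emitted as '#' headers
  set.seed(42)
  s <- raman_spectrum(runif(1401, 0, 5000), g, label = "Golden Queen",
                      metadata = list(excitation_nm = 785, power_mW = 3.3))
  write_spectrum(s, tmp)
  lines <- readLines(tmp)
  expect_true(all(startsWith(lines[1:3], "#")))
  back <- read_spectrum(tmp)
  expect_equal(back$intensities, s$intensities, tolerance = 1e-6)
  expect_equal(back$label, "Golden Queen")
  expect_equal(back$metadata$excitation_nm, "785")
})

test_that("reading resamples a finer native axis by linear interpolation", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  wn <- seq(399, 1801, by = 0.5)
  writeLines(sprintf("%.2f %.2f", wn, wn), tmp)  # f(nu) = nu
  s <- read_spectrum(tmp)
  # a linear function is interpolation-exact
  expect_equal(s$intensities, s$grid$wavenumbers)
  expect_equal(s$metadata$native_n, length(wn))
})

test_that("malformed rows and narrow coverage are rejected with context", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("400 1.0", "401 oops", "402 2.0"), tmp)
  expect_error(read_spectrum(tmp), "line 2")

  writeLines(sprintf("%d %d", 500:1800, 500:1800), tmp)
  expect_error(read_spectrum(tmp), "narrower")

  expect_error(read_spectrum(file.path(tempdir(), "absent.txt")), "not found")
})

test_that("comma-delimited files with a header row are read", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,intensity",
               sprintf("%d,%d", 400:1800, rep(7, 1401))), tmp)
  s <- read_spectrum(tmp, dialect = "delimited-with-header")
  expect_true(all(s$intensities == 7))
})

test_that("library JSON save/load round-trips losslessly", {
  lib <- chrysanthemum_library()
  tmp <- withr::local_tempfile(fileext = ".json")
  save_library(lib, tmp)
  back <- load_library(tmp)
  expect_equal(names(back$patterns), names(lib$patterns))
  for (cv in names(lib$patterns)) {
    expect_identical(back$patterns[[cv]]$peaks$position,
                     lib$patterns[[cv]]$peaks$position)
    expect_identical(back$patterns[[cv]]$peaks$normalized_intensity,
                     lib$patterns[[cv]]$peaks$normalized_intensity)
  }
  expect_equal(back$name, lib$name)

  # empty library is a valid file
  save_library(spectral_library(list(), name = "empty"), tmp)
  expect_equal(length(load_library(tmp)), 0)
})

test_that("library files violating the schema are rejected", {
  tmp <- withr::local_tempfile(fileext = ".json")
  doc <- list(schema_version = "1.0", name = "bad", created = "", notes = "",
              patterns = list(
                list(cultivar = "X", peaks = list(list(position = 732,
                                                       normalized_intensity = 1))),
                list(cultivar = "X", peaks = list(list(position = 733,
                                                       normalized_intensity = 1)))))
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE)
  expect_error(load_library(tmp), "duplicate")

  doc$patterns[[2]]$cultivar <- "Y"
  doc$patterns[[2]]$peaks[[1]]$normalized_intensity <- 1.7
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE)
  expect_error(load_library(tmp), "\\(0, 1\\]")

  jsonlite::write_json(list(name = "no version"), tmp, auto_unbox = TRUE)
  expect_error(load_library(tmp), "schema_version")
})

test_that("CSV export flattens the library one row per peak", {
  lib <- chrysanthemum_library()
  tmp <- withr::local_tempfile(fileext = ".csv")
  export_library_csv(lib, tmp)
  csv <- read.csv(tmp)
  expect_equal(names(csv), c("cultivar", "position", "normalized_intensity"))
  expect_equal(nrow(csv), sum(vapply(lib$patterns,
                                     function(p) nrow(p$peaks), integer(1))))
  expect_equal(csv$position[csv$cultivar == "Beautiful Purple"], 732)
})
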