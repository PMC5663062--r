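Package: chrysoraman
Title: SERS Peak-Pattern Chemotaxonomy for Ornamental Chrysanthemum Cultivars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for cultivar-level chemotaxonomy of ornamental Flos
    Chrysanthemum from surface-enhanced Raman scattering (SERS) spectra.
    Implements iterative fifth-order modified-polynomial fluorescence
    baseline removal (Vancouver-style peak-clipping refit), replicate
    averaging, characteristic-peak detection with height and width filters,
    max-normalization into peak distribution patterns, construction and
    visualization of a 26-cultivar spectral pattern library, cultivar
    identification by tolerance-window peak matching, and tentative
    vibrational-band compound assignment. A synthetic-spectrum generator
    (Gaussian or Lorentzian peaks on a polynomial fluorescence background
    with replicate jitter and noise) makes every stage testable without
    instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
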