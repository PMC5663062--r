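test_that("self-matches score exactly 1 with zero deviation", {
  lib <- chrysanthemum_library()
  for (p in lib$patterns) {
    m <- match_pattern(p, p)
    expect_equal(m$score, 1)
    expect_equal(m$total_position_deviation, 0)
    expect_equal(nrow(m$matched_pairs), nrow(p$peaks))
  }
})

test_that("patterns with no peaks in tolerance score zero", {
  a <- peak_pattern("a", c(500, 600), c(0.5, 1))
  b <- peak_pattern("b", c(900, 1400), c(1, 0.5))
  m <- match_pattern(a, b)
  expect_equal(m$score, 0)
  expect_equal(nrow(m$matched_pairs), 0)
})

test_that("near-duplicate single-peak patterns match fully but keep deviation", {
  bp <- peak_pattern("Beautiful Purple", 732, 1)
  br <- peak_pattern("Beijing Red", 733, 1)
  m <- match_pattern(bp, br)
  expect_equal(m$score, 1)
  expect_equal(m$total_position_deviation, 1)
  expect_equal(match_pattern(bp, bp)$total_position_deviation, 0)
})

test_that("matching is symmetric", {
  lib <- chrysanthemum_library()
  pairs <- list(c("Golden Queen", "Mini Red Peach"),
                c("Red Frost", "Red Jinbei"),
                c("Jade Feng", "Green Window"),
                c("Beautiful Purple", "Beijing Red"))
  for (pr in pairs) {
    ab <- match_pattern(lib$patterns[[pr[1]]], lib$patterns[[pr[2]]])
    ba <- match_pattern(lib$patterns[[pr[2]]], lib$patterns[[pr[1]]])
    expect_equal(ab$score, ba$score)
    expect_equal(ab$total_position_deviation, ba$total_position_deviation)
  }
})

test_that("raising the tolerance never lowers a score", {
  lib <- chrysanthemum_library()
  q <- lib$patterns[["Red Frost"]]
  r <- lib$patterns[["Red Jinbei"]]
  scores <- vapply(c(0, 1, 2, 4, 8), function(tol)
    match_pattern(q, r, tolerance = tol)$score, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("identification ranks the true cultivar first for every fixture", {
  lib <- chrysanthemum_library()
  for (cv in names(lib$patterns)) {
    id <- identify_cultivar(lib$patterns[[cv]], lib)
    expect_equal(id$cultivar[1], cv)
    expect_equal(id$score[1], 1)
  }
})

test_that("score ties are broken by position deviation", {
  lib <- chrysanthemum_library()
  id <- identify_cultivar(peak_pattern("query", 732, 1), lib)
  expect_equal(id$cultivar[1], "Beautiful Purple")  # deviation 0
  expect_equal(id$cultivar[2], "Beijing Red")       # same score, deviation 1
  expect_equal(id$score[1], id$score[2])
  expect_lt(id$total_position_deviation[1], id$total_position_deviation[2])
  # full ranking is returned
  expect_equal(nrow(id), 26)
})

test_that("compound assignment reproduces the published inferences", {
  lib <- chrysanthemum_library()
  tab <- compound_assignments()

  wl <- assign_compounds(lib$patterns[["White Lion"]], tab)
  croc <- wl[wl$compound == "Crocetin", ]
  expect_equal(croc$position, 1020)
  expect_equal(croc$deviation, 0)

  gq <- assign_compounds(lib$patterns[["Golden Queen"]], tab)
  expect_true(any(gq$compound == "Sucrose" & gq$position == 1462 &
                    gq$deviation == 0))

  # the 652 band is shared by two monoterpenes -> ambiguous
  cineol <- gq[gq$compound_class == "Bicyclic monoterpenes", ]
  expect_equal(sort(cineol$compound), c("1,8-Cineol", "Sabinene"))
  expect_true(all(cineol$ambiguous))

  # a peak outside every band yields nothing
  lone <- assign_compounds(peak_pattern("x", 787, 1), tab)
  expect_equal(nrow(lone), 0)
})

test_that("the crocetin inference set matches tolerance 3 and collapses at 0", {
  lib <- chrysanthemum_library()
  tab3 <- compound_assignments()
  crocetin_cultivars <- function(tab) {
    hits <- vapply(lib$patterns, function(p)
      any(assign_compounds(p, tab)$compound == "Crocetin"), logical(1))
    sort(names(hits)[hits])
  }
  expect_equal(crocetin_cultivars(tab3),
               sort(c("White Lion", "Red Jinbei", "Madame Guo", "Mini Ju",
                      "Gushui Liuxia", "Green Zhaoyun", "White Jade",
                      "Red Frost")))
  tab0 <- tab3; tab0$tolerance <- 0
  expect_equal(crocetin_cultivars(tab0), "White Lion")
})

test_that("raising the assignment tolerance never removes an assignment", {
  lib <- chrysanthemum_library()
  tab <- compound_assignments()
  p <- lib$patterns[["Red Frost"]]
  prev <- NULL
  for (tol in c(0, 1, 3, 6)) {
    tab$tolerance <- tol
    cur <- assign_compounds(p, tab)
    key <- paste(cur$position, cur$compound)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})
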