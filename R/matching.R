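#' Match a query pattern against a reference pattern
#'
#' Pairs query and reference peaks greedily in order of increasing position
#' difference, one-to-one, allowing a pair only when the positions differ by
#' at most `tolerance`. The score is a cosine similarity with unmatched mass
#' penalized: `sum(q_i * r_i) / (||q|| * ||r||)` where the products run over
#' matched pairs but the norms run over ALL peaks of each pattern, so
#' unmatched peaks dilute the score without contributing to it. The score
#' is symmetric, lies in \[0, 1\], and equals 1 exactly for self-matches.
#'
#' @param query,reference non-empty [peak_pattern]s.
#' @param tolerance pairing window in cm^-1 (default 4: wide enough to
#'   absorb band drift between samples of one cultivar, narrow enough not
#'   to bridge neighbouring bands).
#' @return An object of class `match_result` with fields `cultivar`
#'   (reference name), `score`, `matched_pairs` (data.frame of
#'   query/reference positions and intensities), and
#'   `total_position_deviation` (sum of |query - reference| over pairs).
#' @export
match_pattern <- function(query, reference, tolerance = 4) {
  stopifnot(inherits(query, "peak_pattern"), inherits(reference, "peak_pattern"))
  if (n_peaks(query) == 0 || n_peaks(reference) == 0) {
    stop("match_pattern: query and reference patterns must be non-empty")
  }
  if (tolerance < 0) stop("match_pattern: tolerance must be >= 0")
  qp <- query$peaks$position
  rp <- reference$peaks$position
  qv <- query$peaks$normalized_intensity
  rv <- reference$peaks$normalized_intensity

  cand <- expand.grid(qi = seq_along(qp), ri = seq_along(rp))
  cand$dev <- abs(qp[cand$qi] - rp[cand$ri])
  cand <- cand[cand$dev <= tolerance, , drop = FALSE]
  # deterministic, symmetric order: deviation, then the pair's positions
  cand <- cand[order(cand$dev, pmin(qp[cand$qi], rp[cand$ri]),
                     pmax(qp[cand$qi], rp[cand$ri])), , drop = FALSE]
  used_q <- rep(FALSE, length(qp))
  used_r <- rep(FALSE, length(rp))
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    qi <- cand$qi[k]; ri <- cand$ri[k]
    if (!used_q[qi] && !used_r[ri]) {
      used_q[qi] <- TRUE; used_r[ri] <- TRUE
      pairs[[length(pairs) + 1]] <- c(qi, ri)
    }
  }
  if (length(pairs) > 0) {
    pm <- do.call(rbind, pairs)
    matched <- data.frame(query_position = qp[pm[, 1]],
                          reference_position = rp[pm[, 2]],
                          query_intensity = qv[pm[, 1]],
                          reference_intensity = rv[pm[, 2]])
    matched <- matched[order(matched$query_position), , drop = FALSE]
    rownames(matched) <- NULL
    score <- sum(matched$query_intensity * matched$reference_intensity) /
      (sqrt(sum(qv^2)) * sqrt(sum(rv^2)))
    deviation <- sum(abs(matched$query_position - matched$reference_position))
  } else {
    matched <- data.frame(query_position = numeric(0),
                          reference_position = numeric(0),
                          query_intensity = numeric(0),
                          reference_intensity = numeric(0))
    score <- 0
    deviation <- 0
  }
  structure(list(cultivar = reference$cultivar, score = score,
                 matched_pairs = matched,
                 total_position_deviation = deviation),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> '%s': score %.4f, %d pair(s), total deviation %g cm^-1\n",
              x$cultivar, x$score, nrow(x$matched_pairs),
              x$total_position_deviation))
  invisible(x)
}

#' Identify a cultivar from a query pattern
#'
#' Scores the query against every library pattern with [match_pattern()]
#' and returns the full ranking: score descending, ties broken by smaller
#' total position deviation, then lexicographic cultivar name.
#'
#' @param query a non-empty [peak_pattern].
#' @param library a non-empty [spectral_library].
#' @param tolerance pairing window in cm^-1 (default 4).
#' @return A data.frame of class `identification` with columns `rank`,
#'   `cultivar`, `score`, `n_matched`, `total_position_deviation`; the
#'   per-reference `match_result`s are attached as attribute `"matches"`.
#' @export
identify_cultivar <- function(query, library, tolerance = 4) {
  stopifnot(inherits(library, "spectral_library"))
  if (length(library$patterns) == 0) stop("identify_cultivar: empty library")
  matches <- lapply(library$patterns, function(ref)
    match_pattern(query, ref, tolerance = tolerance))
  tab <- data.frame(
    cultivar = vapply(matches, function(m) m$cultivar, character(1)),
    score = vapply(matches, function(m) m$score, numeric(1)),
    n_matched = vapply(matches, function(m) nrow(m$matched_pairs), integer(1)),
    total_position_deviation = vapply(matches, function(m)
      m$total_position_deviation, numeric(1))
  )
  o <- order(-tab$score, tab$total_position_deviation, tab$cultivar)
  tab <- tab[o, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  attr(tab, "matches") <- matches
  class(tab) <- c("identification", "data.frame")
  tab
}

#' Tentatively assign compounds to pattern peaks
#'
#' For each peak of the pattern, every table entry whose point reference
#' lies within `table$tolerance` cm^-1, or whose interval reference
#' contains the position, yields an assignment. Deviation is
#' |position - reference| for point references and 0 for in-interval
#' matches. Entries that share one reference position (e.g. two compounds
#' quoted at the same band) are flagged `ambiguous`, since the band alone
#' cannot separate them. Peaks matching no entry yield no row.
#'
#' @param pattern a [peak_pattern].
#' @param table an [assignment_table] (default: the bundled
#'   [compound_assignments()] reference table).
#' @return A data.frame of class `compound_assignments` with columns
#'   `position`, `compound`, `compound_class`, `reference` (text:
#'   `"x"` or `"lower-upper"`), `vibration`, `deviation`, `ambiguous`,
#'   ordered by position then deviation.
#' @export
assign_compounds <- function(pattern, table = compound_assignments()) {
  stopifnot(inherits(pattern, "peak_pattern"),
            inherits(table, "assignment_table"))
  e <- table$entries
  ref_key <- paste(e$ref_lower, e$ref_upper)
  shared_ref <- ref_key %in% ref_key[duplicated(ref_key)]
  rows <- list()
  for (pos in pattern$peaks$position) {
    is_point <- e$ref_lower == e$ref_upper
    dev_point <- abs(pos - e$ref_lower)
    hit <- (is_point & dev_point <= table$tolerance) |
      (!is_point & pos >= e$ref_lower & pos <= e$ref_upper)
    for (j in which(hit)) {
      rows[[length(rows) + 1]] <- data.frame(
        position = pos,
        compound = e$compound[j],
        compound_class = e$compound_class[j],
        reference = if (is_point[j]) format(e$ref_lower[j]) else
          sprintf("%g-%g", e$ref_lower[j], e$ref_upper[j]),
        vibration = e$vibration[j],
        deviation = if (is_point[j]) dev_point[j] else 0,
        ambiguous = shared_ref[j]
      )
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(position = numeric(0), compound = character(0),
               compound_class = character(0), reference = character(0),
               vibration = character(0), deviation = numeric(0),
               ambiguous = logical(0))
  out <- out[order(out$position, out$deviation, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("compound_assignments", "data.frame")
  out
}
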