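#' Iterative polynomial fluorescence-baseline correction
#'
#' Removes the broad fluorescence background underlying sharp Raman peaks by
#' the iterative modified-polynomial (peak-clipping) method: a polynomial of
#' degree `order` is least-squares fitted to the spectrum on a wavenumber
#' axis rescaled to \[-1, 1\]; every point of the working signal lying above
#' the current fit is replaced by the fit value (suppressing peaks) while
#' points at or below are kept; the fit is repeated on the clipped signal
#' until the root-mean-square change of the fitted curve between successive
#' iterations — relative to the larger of the baseline's and the input's RMS
#' scale, so that near-zero baselines register as converged — falls below
#' `tolerance` or `max_iterations` is reached. The final fit is the baseline; the corrected spectrum is the
#' input minus the baseline, reconstructing the input to machine precision when added
#' back. Negative corrected values are kept, not clipped.
#'
#' An optional `noise_margin` (a.u.) generalizes the clipping rule: points
#' are kept wherever they lie below `fit + noise_margin`, so that at a
#' positive margin pure noise above the fit is no longer treated as peak
#' signal. The default margin of 0 is the plain peak-clipping rule.
#'
#' @param spectrum a [raman_spectrum] with finite intensities.
#' @param order polynomial degree (default 5, the fluorescence model used
#'   throughout this package); must satisfy `order >= 1` and
#'   `order + 2 <=` number of grid points.
#' @param max_iterations iteration cap (default 100).
#' @param tolerance relative RMS change of the fitted baseline at which
#'   iteration stops (default 1e-4).
#' @param noise_margin a.u. added to the fit in the keep/clip comparison
#'   (default 0).
#' @return An object of class `baseline_result` with fields
#'   `corrected` and `baseline` ([raman_spectrum]s whose sum reconstructs
#'   the input to machine precision), `iterations_used`,
#'   `converged`, and `rms_trace` (per-iteration RMS of working signal minus
#'   fit, non-increasing). Non-convergence within `max_iterations` returns
#'   `converged = FALSE` with a warning, never an error.
#' @examples
#' g <- wavenumber_grid()
#' bg <- generate_background(g, c(800, 400, -300, 100, 0, 0))
#' res <- correct_baseline(bg)
#' max(abs(res$corrected$intensities))  # ~0: the model fits itself
#' @export
correct_baseline <- function(spectrum, order = 5, max_iterations = 100,
                             tolerance = 1e-4, noise_margin = 0) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  y <- spectrum$intensities
  n <- length(y)
  if (order < 1) stop("correct_baseline: 'order' must be >= 1")
  if (n <= order + 1) {
    stop("correct_baseline: grid length must exceed order + 1")
  }
  if (max_iterations < 1) stop("correct_baseline: 'max_iterations' must be >= 1")

  x <- scale_axis(spectrum$grid$wavenumbers)
  vand <- outer(x, 0:order, `^`)
  polyfit <- function(w) {
    fit <- stats::lm.fit(vand, w)
    as.numeric(fit$fitted.values)
  }

  working <- y
  fit <- polyfit(working)
  iterations <- 1L
  converged <- FALSE
  yscale <- sqrt(mean(y^2))
  rms_trace <- sqrt(mean((working - fit)^2))
  while (iterations < max_iterations) {
    working <- pmin(working, fit + noise_margin)
    new_fit <- polyfit(working)
    iterations <- iterations + 1L
    rms_trace <- c(rms_trace, sqrt(mean((working - new_fit)^2)))
    change <- sqrt(mean((new_fit - fit)^2))
    # relative to the larger of the baseline scale and the spectrum scale:
    # a near-zero baseline would otherwise never register as converged
    ref <- max(sqrt(mean(fit^2)), yscale, 1e-12)
    rel <- change / ref
    fit <- new_fit
    if (rel < tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max_iterations == 1L) {
    # a single fit was requested; nothing to compare against
    converged <- FALSE
  }
  if (!converged) {
    warning(sprintf(paste0("correct_baseline: no convergence within %d ",
                           "iterations (label '%s')"),
                    max_iterations, spectrum$label))
  }

  baseline <- raman_spectrum(fit, grid = spectrum$grid,
                             label = paste0(spectrum$label, " [baseline]"))
  corrected <- raman_spectrum(y - fit, grid = spectrum$grid,
                              label = spectrum$label,
                              metadata = spectrum$metadata)
  structure(list(corrected = corrected, baseline = baseline,
                 iterations_used = iterations, converged = converged,
                 rms_trace = rms_trace),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("<baseline_result> '%s': %d iteration(s), %s\n",
              x$corrected$label, x$iterations_used,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
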