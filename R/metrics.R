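#' Shape summary of a tuning curve
#'
#' Extracts peak location and height, full width at half maximum, a
#' monotonicity flag and the support interval of a sampled curve.  The peak
#' is the grid argmax (ties broken toward the lowest intensity).  The FWHM
#' is the width of the connected region around the peak where the curve
#' stays at or above half the peak value, with linear interpolation between
#' grid points; it is `NA` when the half-maximum level is not crossed on
#' both sides of the peak within the grid (e.g. for monotonic curves).
#'
#' @param curve A [tuning_curve()], a [test_circuit()] result, or anything
#'   with `grid` and `values`/`out` fields.
#' @return A list of class `curve_shape` with fields `peak_intensity`,
#'   `peak_value`, `fwhm`, `is_monotonic` and `support` (range of
#'   intensities with positive values, or `NULL` for an all-zero curve).
#' @export
curve_shape <- function(curve) {
  g <- curve$grid
  v <- if (!is.null(curve$values)) curve$values else curve$out
  if (is.null(g) || is.null(v) || length(g) == 0L)
    stop("`curve` must carry a non-empty grid and values", call. = FALSE)
  pk <- which.max(v)
  shape <- list(peak_intensity = g[pk], peak_value = v[pk],
                fwhm = NA_real_,
                is_monotonic = !is.unsorted(v),
                support = NULL)
  if (v[pk] > 0) {
    pos <- which(v > 0)
    shape$support <- c(g[min(pos)], g[max(pos)])
    half <- v[pk] / 2
    left <- which(v[seq_len(pk)] < half)
    right <- which(v[pk:length(v)] < half)
    if (length(left) && length(right)) {
      li <- max(left)                 # last sub-half point left of the peak
      ri <- pk + min(right) - 1L      # first sub-half point right of it
      xl <- g[li] + (half - v[li]) / (v[li + 1L] - v[li]) *
        (g[li + 1L] - g[li])
      xr <- g[ri - 1L] + (v[ri - 1L] - half) / (v[ri - 1L] - v[ri]) *
        (g[ri] - g[ri - 1L])
      shape$fwhm <- xr - xl
    }
  }
  class(shape) <- "curve_shape"
  shape
}

#' @export
print.curve_shape <- function(x, ...) {
  cat(sprintf(
    "<curve_shape> peak %s at %g; fwhm %s; monotonic: %s\n",
    format(signif(x$peak_value, 4)), x$peak_intensity,
    if (is.na(x$fwhm)) "undefined" else format(signif(x$fwhm, 4)),
    x$is_monotonic))
  invisible(x)
}

#' Pairwise nestedness of tuning curves
#'
#' A set of curves is nested when it admits a total pointwise-dominance
#' order: for every pair, one curve is at least as large as the other at
#' every grid point (within an absolute tolerance).  Nested tuning means a
#' higher intensity activates a superset of what a lower intensity
#' activates, which precludes intensity-specific memories.
#'
#' @param curves List of at least two [tuning_curve()]s on a common grid.
#' @param tol Absolute dominance tolerance.
#' @return A list of class `nestedness_report` with `pair_dominance` (a
#'   K x K logical matrix; entry (j, k) says curve j dominates curve k
#'   pointwise) and `fully_nested`.
#' @export
nestedness <- function(curves, tol = 1e-12) {
  if (!is.list(curves) || length(curves) < 2L)
    stop("need at least two curves", call. = FALSE)
  g <- curves[[1L]]$grid
  if (!all(vapply(curves, function(cv) isTRUE(all.equal(cv$grid, g)),
                  logical(1))))
    stop("curves must share a common grid", call. = FALSE)
  V <- vapply(curves, `[[`, numeric(length(g)), "values")
  K <- ncol(V)
  dom <- matrix(FALSE, K, K)
  for (j in seq_len(K)) for (k in seq_len(K))
    dom[j, k] <- all(V[, j] >= V[, k] - tol)
  # a dominance chain exists iff every pair is comparable
  comparable <- dom | t(dom)
  structure(list(pair_dominance = dom, fully_nested = all(comparable)),
            class = "nestedness_report")
}

#' @export
print.nestedness_report <- function(x, ...) {
  cat(sprintf("<nestedness_report> fully nested: %s\n", x$fully_nested))
  invisible(x)
}

#' Intensity-specificity score of an experiment battery
#'
#' The score is the worst-case distance between the output peak and the
#' trained intensity across the battery, `max_j |peak_j - i_training_j|`
#' (log10 units); smaller means more intensity-specific memory.
#'
#' @param battery List of [test_circuit()] results (each carries its
#'   training intensity).
#' @return A single non-negative number.
#' @export
specificity_score <- function(battery) {
  if (!is.list(battery) || length(battery) == 0L)
    stop("`battery` must be a non-empty list of test results",
         call. = FALSE)
  if (!all(vapply(battery, inherits, logical(1), "test_result")))
    stop("`battery` must contain test_result objects", call. = FALSE)
  max(vapply(battery, function(r) abs(r$peak_intensity - r$i_training),
             numeric(1)))
}
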