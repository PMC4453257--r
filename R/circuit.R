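#' Specification of the three-layer feed-forward circuit
#'
#' Bundles the input layer (K excitatory logistic units plus one shared
#' inhibitory logistic unit), the synaptic weights onto the intermediate
#' layer, the homeostasis mode and the homeostasis parameters.  Each
#' excitatory unit is connected one-to-one with an intermediate neuron; the
#' inhibitory unit projects to all of them.  The intermediate neurons apply
#' a rectified (threshold-linear) activation to the weighted sum of their
#' inputs.
#'
#' @param exc_units List of [logistic_unit()]s with asymptote 1, ordered by
#'   increasing turning point.
#' @param inh_unit A [logistic_unit()] with asymptote (`inh_max`) greater
#'   than 1 and a slope strictly smaller than every excitatory slope.
#' @param w_exc,w_inh Per-neuron excitatory (>= 0) and inhibitory (<= 0)
#'   weights used when `homeostasis_mode = "none"`.  Scalars are recycled.
#' @param homeostasis_mode One of `"none"`, `"excitatory"`, `"inhibitory"`.
#' @param alpha,alpha_tilde Scale factors of the two homeostatic scenarios.
#' @param d Offset of the excitatory homeostasis rule.  If `NULL`, it is set
#'   at resolution time to `s(min a) + 0.5`, which guarantees positive
#'   weights for every configured unit.
#' @param c0,c1 Bounds of the intensity window over which the sensitivity
#'   integral is taken (`c0 < c1`).
#'
#' @return An object of class `circuit_spec`.
#' @seealso [default_circuit_spec()] for calibrated ready-to-use circuits,
#'   [resolve_weights()], [tuning_curves()].
#' @export
circuit_spec <- function(exc_units, inh_unit,
                         w_exc = 1, w_inh = -1,
                         homeostasis_mode = c("none", "excitatory",
                                              "inhibitory"),
                         alpha = 1, alpha_tilde = 1, d = NULL,
                         c0 = -4, c1 = 4) {
  homeostasis_mode <- match.arg(homeostasis_mode)
  if (!is.list(exc_units) || length(exc_units) == 0L ||
      !all(vapply(exc_units, inherits, logical(1), "logistic_unit")))
    stop("`exc_units` must be a non-empty list of logistic_unit objects",
         call. = FALSE)
  if (any(vapply(exc_units, `[[`, numeric(1), "asymptote") != 1))
    stop("all excitatory units must have asymptote 1", call. = FALSE)
  if (!inherits(inh_unit, "logistic_unit"))
    stop("`inh_unit` must be a logistic_unit", call. = FALSE)
  if (inh_unit$asymptote <= 1)
    stop("constraint violated: inh_max > 1 is required", call. = FALSE)
  b_exc <- vapply(exc_units, `[[`, numeric(1), "b")
  if (any(b_exc <= inh_unit$b))
    stop("constraint violated: every excitatory slope b must exceed b_inh",
         call. = FALSE)
  K <- length(exc_units)
  w_exc <- rep_len(as.numeric(w_exc), K)
  w_inh <- rep_len(as.numeric(w_inh), K)
  if (any(!is.finite(w_exc)) || any(w_exc < 0))
    stop("`w_exc` must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(w_inh)) || any(w_inh > 0))
    stop("`w_inh` must be finite and non-positive", call. = FALSE)
  if (!is.numeric(c0) || !is.numeric(c1) || c0 >= c1)
    stop("constraint violated: c0 < c1 is required", call. = FALSE)
  if (is.null(d)) {
    a_min <- min(vapply(exc_units, `[[`, numeric(1), "a"))
    b_min <- exc_units[[which.min(vapply(exc_units, `[[`, numeric(1),
                                         "a"))]]$b
    d <- s_integral(a_min, b_min, c0, c1) + 0.5
  }
  spec <- structure(list(exc_units = exc_units, inh_unit = inh_unit,
                         w_exc = w_exc, w_inh = w_inh,
                         homeostasis_mode = homeostasis_mode,
                         alpha = alpha, alpha_tilde = alpha_tilde, d = d,
                         c0 = c0, c1 = c1),
                    class = "circuit_spec")
  # fail early if homeostatic weights would be invalid
  resolve_weights(spec)
  spec
}

#' @export
print.circuit_spec <- function(x, ...) {
  a <- vapply(x$exc_units, `[[`, numeric(1), "a")
  w <- resolve_weights(x)
  cat(sprintf("<circuit_spec> %d excitatory units, mode = %s\n",
              length(a), x$homeostasis_mode))
  cat(sprintf("  a_k: %s (b = %s)\n", paste(format(a), collapse = ", "),
              paste(format(unique(vapply(x$exc_units, `[[`, numeric(1),
                                         "b"))), collapse = ", ")))
  cat(sprintf("  inhibition: a_inh = %g, b_inh = %g, inh_max = %g\n",
              x$inh_unit$a, x$inh_unit$b, x$inh_unit$asymptote))
  cat(sprintf("  effective w_exc: %s\n",
              paste(format(round(w$w_exc, 4)), collapse = ", ")))
  cat(sprintf("  effective w_inh: %s\n",
              paste(format(round(w$w_inh, 4)), collapse = ", ")))
  invisible(x)
}

#' Calibrated default circuits
#'
#' Returns a circuit specification whose parameters are calibrated so that
#' the qualitative regime associated with each homeostasis scenario is
#' realized on the default intensity grid: without homeostasis the
#' intermediate tuning curves are nested and the trained output peaks at a
#' common intensity regardless of the training intensity; with either
#' homeostatic scenario the tuning curves tile the training range and the
#' trained output peaks near the respective training intensity.  The three
#' scenarios are calibrated independently (they represent different
#' simulated preparations); see the package vignette for the calibration
#' rationale.
#'
#' All circuits use K = 3 excitatory units with turning points at -1, 0 and
#' 1 (steps of one log10 unit).
#'
#' @param homeostasis_mode One of `"none"`, `"excitatory"`, `"inhibitory"`.
#' @return A [circuit_spec()].
#' @examples
#' spec <- default_circuit_spec("excitatory")
#' resolve_weights(spec)$w_exc   # increases with the turning point
#' @export
default_circuit_spec <- function(homeostasis_mode = c("none", "excitatory",
                                                      "inhibitory")) {
  homeostasis_mode <- match.arg(homeostasis_mode)
  a_k <- c(-1, 0, 1)
  mk_exc <- function(b) lapply(a_k, logistic_unit, b = b)
  switch(homeostasis_mode,
    none = circuit_spec(
      exc_units = mk_exc(6),
      inh_unit = logistic_unit(a = -0.86, b = 0.35, asymptote = 1.05),
      w_exc = 1, w_inh = -1, homeostasis_mode = "none",
      c0 = -4, c1 = 4),
    excitatory = circuit_spec(
      exc_units = mk_exc(6),
      inh_unit = logistic_unit(a = 2.3846, b = 0.325, asymptote = 3.5),
      homeostasis_mode = "excitatory",
      alpha = 0.6887, d = 6.55, c0 = -0.3774, c1 = 6),
    inhibitory = circuit_spec(
      exc_units = mk_exc(8.4355),
      inh_unit = logistic_unit(a = 2.9078, b = 0.4626, asymptote = 4.383),
      homeostasis_mode = "inhibitory",
      alpha_tilde = 3.9579, c0 = -4.0033, c1 = 1.0636)
  )
}

#' Default evaluation grid
#'
#' Intensities from -4 to 4 log10 units in steps of 0.01, the grid used by
#' the simulated experiments.
#'
#' @param min,max,step Grid bounds and spacing (log10 intensity units).
#' @return Numeric vector of strictly increasing intensities.
#' @export
default_grid <- function(min = -4, max = 4, step = 0.01) {
  if (!is.finite(min) || !is.finite(max) || !is.finite(step) ||
      step <= 0 || min >= max)
    stop("invalid grid settings", call. = FALSE)
  seq(min, max, by = step)
}

#' Intermediate-layer response
#'
#' Activity of intermediate neuron `k` at intensity `i`:
#' `Rect(w_exc[k] * exc_k(i) + w_inh[k] * inh(i))`, where `Rect(x)` is 0 for
#' x < 0 and x otherwise (threshold-linear activation).  Weights are the
#' effective weights after applying the circuit's homeostasis mode.
#'
#' @param spec A [circuit_spec()].
#' @param k Intermediate neuron index (1-based).
#' @param i Odour intensity (log10 units); may be a vector.
#' @return Numeric vector of non-negative activities.
#' @export
intermediate_response <- function(spec, k, i) {
  stopifnot(inherits(spec, "circuit_spec"))
  K <- length(spec$exc_units)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > K || k != round(k))
    stop(sprintf("neuron index k must be an integer in 1..%d", K),
         call. = FALSE)
  check_intensity(i)
  w <- resolve_weights(spec)
  pmax(0, w$w_exc[k] * exc_response(spec$exc_units[[k]], i) +
          w$w_inh[k] * inh_response(spec$inh_unit, i))
}

# all intermediate responses on a grid, as a length(grid) x K matrix
intermediate_matrix <- function(spec, grid) {
  w <- resolve_weights(spec)
  inh <- inh_response(spec$inh_unit, grid)
  vapply(seq_along(spec$exc_units), function(k)
    pmax(0, w$w_exc[k] * exc_response(spec$exc_units[[k]], grid) +
            w$w_inh[k] * inh),
    numeric(length(grid)))
}

#' Tuning curve container
#'
#' @param grid Strictly increasing intensities (log10 units).
#' @param values Non-negative activities aligned with `grid`.
#' @return An object of class `tuning_curve`.
#' @export
tuning_curve <- function(grid, values) {
  if (!is.numeric(grid) || length(grid) == 0L || any(!is.finite(grid)) ||
      any(diff(grid) <= 0))
    stop("`grid` must be non-empty, finite and strictly increasing",
         call. = FALSE)
  if (length(values) != length(grid) || any(!is.finite(values)) ||
      any(values < 0))
    stop("`values` must be non-negative and aligned with `grid`",
         call. = FALSE)
  structure(list(grid = grid, values = values), class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  sh <- curve_shape(x)
  cat(sprintf("<tuning_curve> %d points on [%g, %g]; peak %g at %g\n",
              length(x$grid), min(x$grid), max(x$grid),
              signif(sh$peak_value, 4), sh$peak_intensity))
  invisible(x)
}

#' Intermediate-layer tuning curves
#'
#' Evaluates every intermediate neuron on an intensity grid.
#'
#' @param spec A [circuit_spec()].
#' @param grid Strictly increasing intensities; see [default_grid()].
#' @return A list of [tuning_curve()]s, one per intermediate neuron.
#' @export
tuning_curves <- function(spec, grid = default_grid()) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (length(grid) == 0L)
    stop("`grid` must not be empty", call. = FALSE)
  if (any(diff(grid) <= 0))
    stop("`grid` must be strictly increasing", call. = FALSE)
  M <- intermediate_matrix(spec, grid)
  lapply(seq_len(ncol(M)), function(k) tuning_curve(grid, M[, k]))
}
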