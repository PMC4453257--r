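#' Sensitivity of a logistic input neuron
#'
#' The sensitivity score of an excitatory input neuron is the integral of its
#' logistic response over a reference exposure window \eqn{[c_0, c_1]} of
#' intensities, a scalar proxy for how strongly the neuron is driven, on
#' average, by the odour environment preceding training.  It has the closed
#' form
#' \deqn{s(a) = \frac{1}{4b}\,
#'   \ln\frac{1 + e^{4b(c_1 - a)}}{1 + e^{4b(c_0 - a)}},}
#' which approaches \eqn{c_1 - c_0} as \eqn{a \to -\infty} and 0 as
#' \eqn{a \to \infty}, decreasing monotonically (and roughly linearly for
#' \eqn{c_0 < a < c_1}) in between.
#'
#' @param a Turning-point intensity of the unit (log10 units); vectorised.
#' @param b Slope at the turning point; positive.
#' @param c0,c1 Lower and upper bounds of the exposure window (log10 units),
#'   with `c0 < c1`.
#'
#' @return For scalar `a`, an object of class `sensitivity_score` with fields
#'   `a` and `s`; for vector `a`, a plain numeric vector of scores.
#' @examples
#' sensitivity(0, b = 1, c0 = -4, c1 = 4)$s  # = (c1 - c0) / 2 by symmetry
#' @export
sensitivity <- function(a, b, c0, c1) {
  s <- s_integral(a, b, c0, c1)
  if (length(a) == 1L)
    structure(list(a = a, s = s), class = "sensitivity_score")
  else s
}

#' @export
print.sensitivity_score <- function(x, ...) {
  cat(sprintf("<sensitivity_score> a = %g, s = %g\n", x$a, x$s))
  invisible(x)
}

# numeric core; vectorised over a.  Uses log1p on the exponential with the
# smaller magnitude to stay finite for |4b(c - a)| >> 700.
s_integral <- function(a, b, c0, c1) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("`b` must be a single positive number", call. = FALSE)
  if (!is.numeric(c0) || !is.numeric(c1) || length(c0) != 1L ||
      length(c1) != 1L || !is.finite(c0) || !is.finite(c1) || c0 >= c1)
    stop("integration bounds must satisfy c0 < c1", call. = FALSE)
  if (any(!is.finite(a)))
    stop("`a` must be finite", call. = FALSE)
  # log(1 + e^x) computed stably: x + log1p(e^-x) for x > 0
  log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
  (log1pexp(4 * b * (c1 - a)) - log1pexp(4 * b * (c0 - a))) / (4 * b)
}

#' Homeostatic excitatory weight
#'
#' Mean-effect homeostatic scaling of an excitatory synapse onto the
#' intermediate layer: \eqn{w_{exc}(a) = -\alpha\,(s(a) - d)}.  The more
#' sensitive the input neuron (smaller `a`, larger `s`), the weaker its
#' synapse.  The offset `d` must be chosen so that every configured unit
#' keeps a strictly positive weight.
#'
#' @param a Turning point(s) of the excitatory unit(s).
#' @param alpha Positive scale factor.
#' @param d Offset, in the same units as the sensitivity score.
#' @inheritParams sensitivity
#' @return Numeric vector of positive weights.
#' @export
homeostatic_w_exc <- function(a, alpha, d, b, c0, c1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("`alpha` must be a single positive number", call. = FALSE)
  w <- -alpha * (s_integral(a, b, c0, c1) - d)
  bad <- which(w <= 0)
  if (length(bad))
    stop(sprintf(paste0("homeostatic excitatory weight is not positive for ",
                        "unit(s) with a = %s; increase `d`"),
                 paste(format(a[bad]), collapse = ", ")),
         call. = FALSE)
  w
}

#' Homeostatic inhibitory weight
#'
#' Mean-effect homeostatic scaling of the inhibitory synapse onto the
#' intermediate neuron whose excitatory partner has turning point `a`:
#' \eqn{w_{inh}(a) = -\tilde\alpha\, s(a)}.  The smaller the excitatory
#' drive (larger `a`), the weaker the inhibition.
#'
#' @param a Turning point(s) of the cognate excitatory unit(s).
#' @param alpha_tilde Positive scale factor.
#' @inheritParams sensitivity
#' @return Numeric vector of negative weights.
#' @export
homeostatic_w_inh <- function(a, alpha_tilde, b, c0, c1) {
  if (!is.numeric(alpha_tilde) || length(alpha_tilde) != 1L ||
      alpha_tilde <= 0)
    stop("`alpha_tilde` must be a single positive number", call. = FALSE)
  -alpha_tilde * s_integral(a, b, c0, c1)
}

#' Resolve effective synaptic weights of a circuit
#'
#' Applies the circuit's homeostasis mode to produce the effective
#' excitatory and inhibitory weight vectors used by the intermediate layer:
#' mode `"none"` returns the stored weights unchanged; mode `"excitatory"`
#' fixes all inhibitory weights at -1 and computes each excitatory weight
#' from the sensitivity of its input neuron; mode `"inhibitory"` fixes all
#' excitatory weights at 1 and scales each inhibitory weight by the
#' sensitivity of the cognate excitatory unit.
#'
#' @param spec A [circuit_spec()].
#' @return A list with components `w_exc` and `w_inh` (numeric vectors, one
#'   entry per intermediate neuron).
#' @export
resolve_weights <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  a <- vapply(spec$exc_units, `[[`, numeric(1), "a")
  b <- vapply(spec$exc_units, `[[`, numeric(1), "b")
  switch(spec$homeostasis_mode,
    none = list(w_exc = spec$w_exc, w_inh = spec$w_inh),
    excitatory = list(
      w_exc = vapply(seq_along(a), function(k)
        homeostatic_w_exc(a[k], spec$alpha, spec$d, b[k], spec$c0, spec$c1),
        numeric(1)),
      w_inh = rep(-1, length(a))),
    inhibitory = list(
      w_exc = rep(1, length(a)),
      w_inh = vapply(seq_along(a), function(k)
        homeostatic_w_inh(a[k], spec$alpha_tilde, b[k], spec$c0, spec$c1),
        numeric(1)))
  )
}
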