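#' Logistic input neuron
#'
#' Constructs a monotonic input neuron whose firing rate follows a logistic
#' function of odour intensity (log10 concentration).  The response is
#' \deqn{r(i) = \frac{A}{e^{-4 b (i - a)} + 1},}
#' where `a` is the intensity at the turning point, `b` the slope at the
#' turning point and `A` the asymptotic (maximal) activity.  The factor 4 in
#' the exponent makes `b` exactly the derivative of the response at `i = a`.
#'
#' @param a Turning-point intensity, in log10 concentration units.  A large
#'   negative `a` means a highly sensitive neuron.
#' @param b Slope of the response at the turning point (activity per log10
#'   intensity unit); must be positive.
#' @param asymptote Maximal activity; 1 for excitatory units, greater than 1
#'   for the inhibitory unit (where it plays the role of the inhibitory
#'   ceiling `inh_max`).
#'
#' @return An object of class `logistic_unit`.
#' @examples
#' u <- logistic_unit(a = 0, b = 1)
#' exc_response(u, 0)   # 0.5 at the turning point
#' @export
logistic_unit <- function(a, b, asymptote = 1) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
    stop("`a` must be a single finite number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("`b` must be a single positive number", call. = FALSE)
  if (!is.numeric(asymptote) || length(asymptote) != 1L ||
      !is.finite(asymptote) || asymptote <= 0)
    stop("`asymptote` must be a single positive number", call. = FALSE)
  structure(list(a = a, b = b, asymptote = asymptote),
            class = "logistic_unit")
}

#' @export
print.logistic_unit <- function(x, ...) {
  cat(sprintf("<logistic_unit> a = %g, b = %g, asymptote = %g\n",
              x$a, x$b, x$asymptote))
  invisible(x)
}

# core logistic evaluation, vectorised over i
logistic_value <- function(a, b, asymptote, i) {
  asymptote / (exp(-4 * b * (i - a)) + 1)
}

check_intensity <- function(i) {
  if (!is.numeric(i) || length(i) == 0L || any(!is.finite(i)))
    stop("intensity `i` must be finite numeric", call. = FALSE)
  i
}

#' Excitatory input response
#'
#' Activity of an excitatory input neuron (asymptote 1) at intensity `i`:
#' `1 / (exp(-4 b (i - a)) + 1)`.  Strictly increasing in `i`, bounded in
#' (0, 1).
#'
#' @param unit A [logistic_unit()] with `asymptote == 1`.
#' @param i Odour intensity (log10 units); may be a vector.
#' @return Numeric vector of activities in (0, 1).
#' @export
exc_response <- function(unit, i) {
  stopifnot(inherits(unit, "logistic_unit"))
  if (unit$asymptote != 1)
    stop("excitatory units must have asymptote 1", call. = FALSE)
  check_intensity(i)
  logistic_value(unit$a, unit$b, 1, i)
}

#' Inhibitory input response
#'
#' Activity of the shared inhibitory input neuron at intensity `i`:
#' `inh_max / (exp(-4 b_inh (i - a_inh)) + 1)`, where `inh_max` is the
#' unit's asymptote (> 1).  Strictly increasing in `i`, bounded in
#' (0, `inh_max`).
#'
#' @param unit A [logistic_unit()] with `asymptote > 1`.
#' @param i Odour intensity (log10 units); may be a vector.
#' @return Numeric vector of activities in (0, `inh_max`).
#' @export
inh_response <- function(unit, i) {
  stopifnot(inherits(unit, "logistic_unit"))
  if (unit$asymptote <= 1)
    stop("the inhibitory unit must have asymptote (inh_max) > 1",
         call. = FALSE)
  check_intensity(i)
  logistic_value(unit$a, unit$b, unit$asymptote, i)
}
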