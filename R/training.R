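#' Associative odour-shock training
#'
#' Simulates a single training trial.  Output-synapse weights start at zero
#' and change according to the reinforcement-gated rule
#' \deqn{\Delta w_{training,k} = \Theta(shock)\, inter_k(i_{training}),}
#' where \eqn{\Theta} is the Heaviside step (0 for x <= 0, 1 otherwise): the
#' weight of each intermediate-to-output synapse grows by the presynaptic
#' activity evoked by the trained intensity, but only when the reinforcement
#' (shock) is present.  An unpaired control (`shock = FALSE`) leaves all
#' weights at zero.
#'
#' @param spec A [circuit_spec()].
#' @param i_training Trained odour intensity (log10 units).
#' @param shock Logical (or reinforcement magnitude); gated through the
#'   Heaviside step, so only its sign matters.
#' @return An object of class `training_state` with fields `w_training`,
#'   `i_training` and `shock`.
#' @export
train_circuit <- function(spec, i_training, shock = TRUE) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (!is.numeric(i_training) || length(i_training) != 1L ||
      !is.finite(i_training))
    stop("`i_training` must be a single finite intensity", call. = FALSE)
  gate <- heaviside(as.numeric(shock))
  M <- intermediate_matrix(spec, i_training)
  structure(list(w_training = gate * as.numeric(M),
                 i_training = i_training,
                 shock = gate > 0),
            class = "training_state")
}

# Heaviside step: 0 if x <= 0, 1 otherwise
heaviside <- function(x) as.numeric(x > 0)

#' @export
print.training_state <- function(x, ...) {
  cat(sprintf("<training_state> i_training = %g, shock = %s\n  w: %s\n",
              x$i_training, x$shock,
              paste(format(signif(x$w_training, 4)), collapse = ", ")))
  invisible(x)
}

#' Test the trained circuit over an intensity series
#'
#' Output-neuron activity at each test intensity is the weighted sum of the
#' intermediate-layer activities, \eqn{out(i) = \sum_k w_{training,k}\,
#' inter_k(i)}.  The peak is located by the grid argmax; exact ties are
#' broken toward the lowest intensity.
#'
#' @param spec A [circuit_spec()].
#' @param state A [train_circuit()] result; its weight vector must match the
#'   number of intermediate neurons.
#' @param grid Strictly increasing test intensities.
#' @return An object of class `test_result` with fields `grid`, `out`,
#'   `peak_intensity`, `peak_value` and `i_training`.
#' @export
test_circuit <- function(spec, state, grid = default_grid()) {
  stopifnot(inherits(spec, "circuit_spec"),
            inherits(state, "training_state"))
  if (length(state$w_training) != length(spec$exc_units))
    stop("weight vector length does not match the number of intermediate ",
         "neurons", call. = FALSE)
  if (any(diff(grid) <= 0))
    stop("`grid` must be strictly increasing", call. = FALSE)
  M <- intermediate_matrix(spec, grid)
  out <- as.numeric(M %*% state$w_training)
  pk <- which.max(out)  # which.max returns the first (lowest-i) maximum
  structure(list(grid = grid, out = out,
                 peak_intensity = grid[pk], peak_value = out[pk],
                 i_training = state$i_training),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf(
    "<test_result> trained at %g; peak %s at %g over [%g, %g]\n",
    x$i_training, format(signif(x$peak_value, 4)), x$peak_intensity,
    min(x$grid), max(x$grid)))
  invisible(x)
}

#' Battery of independent train/test experiments
#'
#' Runs one experiment per training intensity: weights are reset to zero
#' before each training trial (the experiments are independent), the circuit
#' is trained once, and the output neuron is then probed over the full test
#' grid.
#'
#' @param spec A [circuit_spec()].
#' @param training_intensities Numeric vector of trained intensities.
#' @param grid Test intensities.
#' @param shock Reinforcement flag applied to every experiment.
#' @return A list of [test_circuit()] results, one per training intensity.
#' @examples
#' spec <- default_circuit_spec("excitatory")
#' batt <- run_experiment_battery(spec, c(-1, 0, 1))
#' vapply(batt, `[[`, numeric(1), "peak_intensity")
#' @export
run_experiment_battery <- function(spec, training_intensities,
                                   grid = default_grid(), shock = TRUE) {
  if (length(training_intensities) < 1L)
    stop("at least one training intensity is required", call. = FALSE)
  lapply(training_intensities, function(it)
    test_circuit(spec, train_circuit(spec, it, shock), grid))
}
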