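#' Specification of a parameter-robustness sweep
#'
#' Defines a grid of circuit parameters over which intensity-specific
#' learning is re-evaluated.  Each grid point overrides the named
#' parameters of a base circuit (by default the calibrated circuit of the
#' chosen homeostasis mode), re-resolves the weights, runs the training
#' battery and records whether the specificity score stays below the
#' threshold.  Grid points that violate the model constraints
#' (`b_inh >= b`, `inh_max <= 1`, or a non-positive homeostatic excitatory
#' weight) are recorded as skipped rather than failed.
#'
#' @param ranges Named list of numeric vectors; recognized names are
#'   `b`, `b_inh`, `a_inh`, `inh_max`, `alpha`, `alpha_tilde`, `d`,
#'   `a_step` (spacing of the excitatory turning points) and `K` (number of
#'   excitatory units).  Defaults to a coarse grid scaling `b`, `b_inh`,
#'   `inh_max` and the active homeostatic scale by 0.95, 1 and 1.05.
#' @param homeostasis_mode Mode of the base circuit.
#' @param training_intensities Trained intensities of the battery.
#' @param threshold Pass criterion on the specificity score (log10 units).
#'   The default of 0.25 reflects the model's intrinsic peak-localization
#'   resolution (see the vignette).
#' @param grid Test grid used by the batteries.
#' @param max_points Safety cap on the number of grid points.
#' @param base_spec Optional base [circuit_spec()] overriding the mode
#'   default.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(ranges = NULL,
                       homeostasis_mode = c("excitatory", "inhibitory"),
                       training_intensities = c(-1, 0, 1),
                       threshold = 0.25,
                       grid = default_grid(),
                       max_points = 1e4,
                       base_spec = NULL) {
  homeostasis_mode <- match.arg(homeostasis_mode)
  base <- if (is.null(base_spec)) default_circuit_spec(homeostasis_mode)
          else base_spec
  if (is.null(ranges)) {
    f <- c(0.95, 1, 1.05)
    ranges <- list(
      b = base$exc_units[[1L]]$b * f,
      b_inh = base$inh_unit$b * f,
      inh_max = base$inh_unit$asymptote * f)
    ranges[[if (homeostasis_mode == "excitatory") "alpha"
            else "alpha_tilde"]] <-
      (if (homeostasis_mode == "excitatory") base$alpha
       else base$alpha_tilde) * f
  }
  known <- c("b", "b_inh", "a_inh", "inh_max", "alpha", "alpha_tilde",
             "d", "a_step", "K")
  if (length(ranges) == 0L || is.null(names(ranges)) ||
      any(!names(ranges) %in% known))
    stop("`ranges` must be a named list using names: ",
         paste(known, collapse = ", "), call. = FALSE)
  if (any(vapply(ranges, length, integer(1)) == 0L))
    stop("every range must contain at least one value", call. = FALSE)
  npts <- prod(vapply(ranges, length, integer(1)))
  if (npts > max_points)
    stop(sprintf("sweep would evaluate %d points (cap %d)", npts,
                 max_points), call. = FALSE)
  structure(list(ranges = ranges, homeostasis_mode = homeostasis_mode,
                 training_intensities = training_intensities,
                 threshold = threshold, grid = grid,
                 base_spec = base),
            class = "sweep_spec")
}

# build a circuit from the base spec with one grid point's overrides;
# returns NULL for constraint-violating combinations
apply_overrides <- function(base, row) {
  K <- if (!is.null(row$K)) as.integer(row$K) else length(base$exc_units)
  a_step <- if (!is.null(row$a_step)) row$a_step else {
    a <- vapply(base$exc_units, `[[`, numeric(1), "a")
    if (length(a) > 1L) a[2L] - a[1L] else 1
  }
  b <- if (!is.null(row$b)) row$b else base$exc_units[[1L]]$b
  b_inh <- if (!is.null(row$b_inh)) row$b_inh else base$inh_unit$b
  a_inh <- if (!is.null(row$a_inh)) row$a_inh else base$inh_unit$a
  inh_max <- if (!is.null(row$inh_max)) row$inh_max
             else base$inh_unit$asymptote
  if (b_inh >= b || inh_max <= 1 || K < 1 || a_step <= 0) return(NULL)
  a_k <- (seq_len(K) - (K + 1) / 2) * a_step
  tryCatch(
    circuit_spec(
      exc_units = lapply(a_k, logistic_unit, b = b),
      inh_unit = logistic_unit(a_inh, b_inh, inh_max),
      w_exc = base$w_exc[1L], w_inh = base$w_inh[1L],
      homeostasis_mode = base$homeostasis_mode,
      alpha = if (!is.null(row$alpha)) row$alpha else base$alpha,
      alpha_tilde = if (!is.null(row$alpha_tilde)) row$alpha_tilde
                    else base$alpha_tilde,
      d = if (!is.null(row$d)) row$d else base$d,
      c0 = base$c0, c1 = base$c1),
    error = function(e) NULL)
}

#' Run a parameter-robustness sweep
#'
#' Evaluates every parameter combination of a [sweep_spec()]: the circuit
#' is rebuilt with the overridden parameters, the training battery is run,
#' and the specificity score is compared against the threshold.  The sweep
#' is fully deterministic (the model has no randomness).
#'
#' @param spec A [sweep_spec()].
#' @return A list of class `sweep_result` with `points` (a data frame of
#'   parameter values, `score` and `status` in pass/fail/skipped) and
#'   `pass_fraction` (passes over non-skipped points).
#' @examples
#' res <- run_sweep(sweep_spec(list(b = 6, inh_max = c(0.9, 3.5))))
#' res$points$status
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  pts <- expand.grid(spec$ranges, KEEP.OUT.ATTRS = FALSE)
  score <- rep(NA_real_, nrow(pts))
  status <- character(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cs <- apply_overrides(spec$base_spec, as.list(pts[i, , drop = FALSE]))
    if (is.null(cs)) { status[i] <- "skipped"; next }
    batt <- run_experiment_battery(cs, spec$training_intensities,
                                   spec$grid)
    # a training intensity that evokes no response cannot express a
    # peak; count such points as failed, not specific
    if (any(vapply(batt, `[[`, numeric(1), "peak_value") <= 0)) {
      score[i] <- Inf; status[i] <- "fail"; next
    }
    score[i] <- specificity_score(batt)
    status[i] <- if (score[i] <= spec$threshold) "pass" else "fail"
  }
  evaluated <- status != "skipped"
  structure(list(points = cbind(pts, score = score, status = status),
                 pass_fraction = if (any(evaluated))
                   mean(status[evaluated] == "pass") else NA_real_,
                 threshold = spec$threshold),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  tb <- table(factor(x$points$status,
                     levels = c("pass", "fail", "skipped")))
  cat(sprintf(
    "<sweep_result> %d points: %d pass, %d fail, %d skipped (threshold %g)\n",
    nrow(x$points), tb[["pass"]], tb[["fail"]], tb[["skipped"]],
    x$threshold))
  cat(sprintf("  pass fraction (evaluated points): %.3f\n",
              x$pass_fraction))
  invisible(x)
}
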