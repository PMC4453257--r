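#' Load and validate a run configuration
#'
#' Reads a YAML configuration file describing a circuit and run settings,
#' fills defaults for everything not given, and validates the result.  A
#' minimal configuration only needs the homeostasis mode.  Recognized
#' sections and keys:
#'
#' * `circuit`: `mode`, `b`, `b_inh`, `a_inh`, `inh_max`, `a` (explicit
#'   vector of excitatory turning points) or `K` plus `a_step`, `w_exc`,
#'   `w_inh`, `alpha`, `alpha_tilde`, `d`, `c0`, `c1`.  Keys that are not
#'   given default to the calibrated circuit of the chosen mode.
#' * `grid`: `min`, `max`, `step`.
#' * `training`: `intensities`, `shock`.
#' * `seed`: integer, used only by the synthetic CAS generator.
#'
#' Errors are signalled with distinct condition classes:
#' `config_missing_error` (unreadable file), `config_schema_error`
#' (unknown or malformed keys) and `config_constraint_error` (model
#' constraint violations such as `inh_max <= 1`).
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config` with elements `circuit` (a
#'   [circuit_spec()]), `grid`, `training`, `seed` and `resolved` (a flat
#'   named list of every resolved value, suitable for provenance headers).
#' @export
load_config <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(config_error("config_missing_error",
                      sprintf("config file not found: %s", path)))
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop(config_error("config_schema_error",
                      sprintf("cannot parse YAML: %s",
                              conditionMessage(e)))))
  if (is.null(raw)) raw <- list()
  build_config(raw)
}

config_error <- function(class, msg) {
  structure(class = c(class, "config_error", "error", "condition"),
            list(message = msg, call = NULL))
}

build_config <- function(raw) {
  known_top <- c("circuit", "grid", "training", "seed")
  if (length(raw) && any(!names(raw) %in% known_top))
    stop(config_error("config_schema_error",
      paste("unknown top-level keys:",
            paste(setdiff(names(raw), known_top), collapse = ", "))))
  cc <- raw$circuit %||% list()
  known_cc <- c("mode", "b", "b_inh", "a_inh", "inh_max", "a", "K",
                "a_step", "w_exc", "w_inh", "alpha", "alpha_tilde", "d",
                "c0", "c1")
  if (length(cc) && any(!names(cc) %in% known_cc))
    stop(config_error("config_schema_error",
      paste("unknown circuit keys:",
            paste(setdiff(names(cc), known_cc), collapse = ", "))))
  mode <- cc$mode %||% "none"
  if (!mode %in% c("none", "excitatory", "inhibitory"))
    stop(config_error("config_schema_error",
      "circuit mode must be one of none, excitatory, inhibitory"))
  base <- default_circuit_spec(mode)
  a_k <- if (!is.null(cc$a)) as.numeric(cc$a) else {
    K <- as.integer(cc$K %||% length(base$exc_units))
    step <- as.numeric(cc$a_step %||% 1)
    (seq_len(K) - (K + 1) / 2) * step
  }
  b <- as.numeric(cc$b %||% base$exc_units[[1L]]$b)
  b_inh <- as.numeric(cc$b_inh %||% base$inh_unit$b)
  a_inh <- as.numeric(cc$a_inh %||% base$inh_unit$a)
  inh_max <- as.numeric(cc$inh_max %||% base$inh_unit$asymptote)
  if (inh_max <= 1)
    stop(config_error("config_constraint_error",
      "constraint violated: inh_max > 1 is required"))
  if (b_inh >= b)
    stop(config_error("config_constraint_error",
      "constraint violated: b_inh < b is required"))
  spec <- tryCatch(
    circuit_spec(
      exc_units = lapply(a_k, logistic_unit, b = b),
      inh_unit = logistic_unit(a_inh, b_inh, inh_max),
      w_exc = as.numeric(cc$w_exc %||% base$w_exc),
      w_inh = as.numeric(cc$w_inh %||% base$w_inh),
      homeostasis_mode = mode,
      alpha = as.numeric(cc$alpha %||% base$alpha),
      alpha_tilde = as.numeric(cc$alpha_tilde %||% base$alpha_tilde),
      d = if (!is.null(cc$d)) as.numeric(cc$d) else base$d,
      c0 = as.numeric(cc$c0 %||% base$c0),
      c1 = as.numeric(cc$c1 %||% base$c1)),
    error = function(e)
      stop(config_error("config_constraint_error", conditionMessage(e))))
  gr <- raw$grid %||% list()
  grid <- list(min = as.numeric(gr$min %||% -4),
               max = as.numeric(gr$max %||% 4),
               step = as.numeric(gr$step %||% 0.01))
  if (grid$step <= 0 || grid$min >= grid$max)
    stop(config_error("config_constraint_error",
                      "grid must satisfy min < max and step > 0"))
  tr <- raw$training %||% list()
  training <- list(
    intensities = as.numeric(tr$intensities %||%
                               vapply(spec$exc_units, `[[`, numeric(1),
                                      "a")),
    shock = as.logical(tr$shock %||% TRUE))
  seed <- as.integer(raw$seed %||% 1L)
  w <- resolve_weights(spec)
  resolved <- list(
    mode = mode, K = length(a_k), a = a_k, b = b, b_inh = b_inh,
    a_inh = a_inh, inh_max = inh_max,
    w_exc = w$w_exc, w_inh = w$w_inh,
    alpha = spec$alpha, alpha_tilde = spec$alpha_tilde, d = spec$d,
    c0 = spec$c0, c1 = spec$c1,
    grid_min = grid$min, grid_max = grid$max, grid_step = grid$step,
    training_intensities = training$intensities, shock = training$shock,
    seed = seed)
  structure(list(circuit = spec, grid = grid, training = training,
                 seed = seed, resolved = resolved),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a resolved configuration back to YAML
#'
#' Serializes every resolved value of a [load_config()] result so that
#' reloading the file reproduces the configuration exactly.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  r <- config$resolved
  yaml::write_yaml(list(
    circuit = list(mode = r$mode, a = r$a, b = r$b, b_inh = r$b_inh,
                   a_inh = r$a_inh, inh_max = r$inh_max,
                   alpha = r$alpha, alpha_tilde = r$alpha_tilde, d = r$d,
                   c0 = r$c0, c1 = r$c1,
                   w_exc = config$circuit$w_exc,
                   w_inh = config$circuit$w_inh),
    grid = config$grid,
    training = config$training,
    seed = config$seed), path,
    precision = 15L)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  print(x$circuit)
  cat(sprintf("  grid: [%g, %g] step %g;  training at %s (shock %s)\n",
              x$grid$min, x$grid$max, x$grid$step,
              paste(x$training$intensities, collapse = ", "),
              x$training$shock))
  invisible(x)
}

# full-precision formatting that round-trips through as.numeric()
format_full <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

#' Write a table as TSV with provenance comments
#'
#' Writes a data frame as tab-separated values.  Numbers are written at
#' full precision (17 significant digits), so reading the file back
#' reproduces the values bitwise.  Provenance entries are embedded as
#' leading `# key: value` comment lines, making a run reproducible from
#' its own output file.
#'
#' @param records Data frame (may have zero rows).
#' @param path Output path.
#' @param provenance Named list written as comment lines.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, provenance = list()) {
  if (!is.data.frame(records))
    stop("`records` must be a data frame", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(provenance))
    writeLines(sprintf("# %s: %s", key,
                       paste(format_full(provenance[[key]]),
                             collapse = " ")), con)
  writeLines(paste(names(records), collapse = "\t"), con)
  if (nrow(records)) {
    cols <- lapply(records, format_full)
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path Input path.
#' @return A data frame (comment lines are skipped).
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read a CAS table from TSV
#'
#' Expects columns `odour`, `i_training`, `i_test`, `median_cas`, `n`.
#' @param path Input path.
#' @return A validated [cas_table()].
#' @export
read_cas_table <- function(path) {
  cas_table(read_table_tsv(path))
}
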