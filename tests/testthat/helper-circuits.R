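# shared fixtures, built in code

# broad, gently inhibited circuit in which all three intermediate neurons
# express substantial bell-shaped tuning (used for shape/aliveness
# properties that need visible bells)
broad_circuit <- function(mode = "none") {
  circuit_spec(
    exc_units = lapply(c(-1, 0, 1), logistic_unit, b = 1),
    inh_unit = logistic_unit(a = 2, b = 0.25, asymptote = 1.5),
    w_exc = 1, w_inh = -1, homeostasis_mode = mode)
}

# intensity at which a logistic unit attains a given activity level
intensity_for <- function(unit, level) {
  unit$a + log(level / (unit$asymptote - level)) / (4 * unit$b)
}

peaks_of <- function(battery)
  vapply(battery, `[[`, numeric(1), "peak_intensity")

# write a small text fixture into the test temp dir
withr_local_file <- function(name, text, env = parent.frame()) {
  path <- file.path(tempdir(), name)
  writeLines(text, path)
  withr::defer(unlink(path), envir = env)
  path
}
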