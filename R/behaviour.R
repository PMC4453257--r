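#' Conditioned-avoidance-score table
#'
#' Validates a data frame of behavioural generalization data.  Each row
#' holds the median conditioned avoidance score (CAS, dimensionless, in
#' [-100, 100]) of one group of animals trained at concentration
#' `i_training` and tested at concentration `i_test` of the same odour.
#' For every odour exactly one row must have matching training and test
#' concentrations (the self-test that anchors the normalization).
#'
#' @param df Data frame with columns `odour`, `i_training`, `i_test`,
#'   `median_cas`, `n` (sample size, >= 1).  Concentrations are on the
#'   linear (dilution) scale, not log-transformed.
#' @return The validated data frame with class `cas_table` prepended.
#' @export
cas_table <- function(df) {
  need <- c("odour", "i_training", "i_test", "median_cas", "n")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop("a CAS table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$i_training)) || any(df$i_training <= 0) ||
      any(!is.finite(df$i_test)) || any(df$i_test <= 0))
    stop("concentrations must be positive and finite", call. = FALSE)
  if (any(!is.finite(df$median_cas)) || any(abs(df$median_cas) > 100))
    stop("`median_cas` must lie in [-100, 100]", call. = FALSE)
  if (any(df$n < 1))
    stop("sample sizes `n` must be >= 1", call. = FALSE)
  for (od in unique(df$odour)) {
    sub <- df[df$odour == od, ]
    if (sum(sub$i_test == sub$i_training) != 1L)
      stop(sprintf(
        "odour '%s' must have exactly one matched-intensity record", od),
        call. = FALSE)
  }
  class(df) <- c("cas_table", class(df))
  df
}

#' Normalize a generalization table
#'
#' Aligns the generalization data of the different odours: test
#' concentrations are divided by the training concentration
#' (`x = i_test / i_training`), and median scores by the score of the
#' matched-intensity group (`y = median_cas / median_cas_matched`), so the
#' matched point maps to (1, 1) for every odour.  Because the matched score
#' is itself (typically negative) avoidance, the normalized response is
#' positive at the anchor regardless of the sign convention.  Applying the
#' normalization twice is the identity.
#'
#' @param table A [cas_table()].
#' @return A data frame of class `cas_normalized` with columns `odour`,
#'   `x` (relative concentration), `y` (relative response) and `n`.
#' @export
normalize_cas <- function(table) {
  if (!inherits(table, "cas_table")) table <- cas_table(table)
  out <- do.call(rbind, lapply(unique(table$odour), function(od) {
    sub <- table[table$odour == od, ]
    anchor <- sub$median_cas[sub$i_test == sub$i_training]
    if (anchor == 0)
      stop(sprintf(
        "odour '%s' has a zero matched-intensity score; cannot normalize",
        od), call. = FALSE)
    data.frame(odour = od,
               x = sub$i_test / sub$i_training,
               y = sub$median_cas / anchor,
               n = sub$n)
  }))
  rownames(out) <- NULL
  class(out) <- c("cas_normalized", class(out))
  out
}

#' HWHM/sigma conversion factor
#'
#' The half width at half maximum of a Gaussian is `sigma * sqrt(2 ln 2)`.
#' @return `sqrt(2 * log(2))`, approximately 1.1774.
#' @export
hwhm_factor <- function() sqrt(2 * log(2))

#' Fit a Gaussian to a normalized generalization curve
#'
#' Least-squares fit of `y = A exp(-(x - mu)^2 / (2 sigma^2))` to a
#' normalized CAS table.  By default the abscissa is the log10 of the
#' relative concentration (intensities are handled logarithmically
#' throughout), so the matched point sits at x = 0.  The half width at half
#' maximum is `sigma * sqrt(2 ln 2)`.
#'
#' @param points A [normalize_cas()] result (or data frame with `x`, `y`).
#' @param log_axis Fit on `log10(x)` (default) or on `x` directly.
#' @param start Optional named list overriding the starting values
#'   `list(A = 1, mu = 0, sigma = 1)`.
#' @return A list of class `gaussian_fit` with `amplitude`, `mean`,
#'   `sigma`, `hwhm` and the `nls` fit object in `fit`.
#' @examples
#' tab <- generate_cas(synthetic_cas_config(noise_sd = 0, seed = 1))
#' fit_cas_gaussian(normalize_cas(tab))$hwhm   # recovers the true HWHM
#' @export
fit_cas_gaussian <- function(points, log_axis = TRUE, start = NULL) {
  if (!all(c("x", "y") %in% names(points)))
    stop("`points` must have columns x and y (see normalize_cas)",
         call. = FALSE)
  x <- if (log_axis) log10(points$x) else points$x
  y <- points$y
  if (length(unique(x)) < 3L)
    stop("need at least 3 distinct test positions to fit a Gaussian",
         call. = FALSE)
  st <- list(A = 1, mu = 0, sigma = 1)
  st[names(start)] <- start
  dat <- data.frame(x = x, y = y)
  run_fit <- function(st) minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
    data = dat, start = st,
    lower = c(A = -Inf, mu = -Inf, sigma = 1e-3),
    upper = c(A = Inf, mu = Inf, sigma = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  # a start that already interpolates the data makes the gradient
  # singular; retry from a displaced start before giving up
  fit <- tryCatch(run_fit(st), error = function(e1) tryCatch(
    run_fit(list(A = st$A * 1.2 + 0.1, mu = st$mu + 0.2,
                 sigma = st$sigma * 1.5)),
    error = function(e2)
      stop("Gaussian fit did not converge: ", conditionMessage(e2),
           call. = FALSE)))
  cf <- stats::coef(fit)
  structure(list(amplitude = unname(cf["A"]), mean = unname(cf["mu"]),
                 sigma = unname(cf["sigma"]),
                 hwhm = unname(cf["sigma"]) * hwhm_factor(),
                 log_axis = log_axis, fit = fit),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "<gaussian_fit> A = %.4g, mean = %.4g, sigma = %.4g, HWHM = %.4g%s\n",
    x$amplitude, x$mean, x$sigma, x$hwhm,
    if (x$log_axis) " (log10 relative intensity)" else ""))
  invisible(x)
}

#' Configuration of the synthetic CAS generator
#'
#' @param true_hwhm Half width at half maximum of the generating Gaussian,
#'   in log10 relative-intensity units.  The default of 1.1 is a plausible
#'   behavioural scale for odour-intensity generalization in flies.
#' @param peak_cas Score of the matched-intensity group (negative =
#'   avoidance).
#' @param noise_sd Standard deviation of the additive Gaussian noise,
#'   expressed as a fraction of `|peak_cas|`.
#' @param test_intensity_offsets Log10 offsets of the test concentrations
#'   relative to training; must include 0 (the matched group).
#' @param i_training Training concentration on the dilution scale.
#' @param odour Odour label.
#' @param n Sample size recorded per group.
#' @param seed Integer seed making the table reproducible.
#' @return A list of class `synthetic_cas_config`.
#' @export
synthetic_cas_config <- function(true_hwhm = 1.1, peak_cas = -60,
                                 noise_sd = 0.05,
                                 test_intensity_offsets =
                                   c(-2, -1, -0.5, 0, 0.5, 1, 2),
                                 i_training = 1e-3, odour = "synthetic",
                                 n = 24, seed = 1) {
  if (!is.numeric(true_hwhm) || true_hwhm <= 0)
    stop("`true_hwhm` must be positive", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!any(test_intensity_offsets == 0))
    stop("`test_intensity_offsets` must include 0 (the matched group)",
         call. = FALSE)
  structure(list(true_hwhm = true_hwhm, peak_cas = peak_cas,
                 noise_sd = noise_sd,
                 test_intensity_offsets = test_intensity_offsets,
                 i_training = i_training, odour = odour, n = n,
                 seed = as.integer(seed)),
            class = "synthetic_cas_config")
}

# evaluate code under a temporary RNG state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic CAS table
#'
#' Draws a CAS-like generalization table whose median scores follow a
#' Gaussian profile over log10 relative intensity,
#' `peak_cas * exp(-offset^2 / (2 sigma_true^2))` with
#' `sigma_true = true_hwhm / sqrt(2 ln 2)`, plus additive Gaussian noise.
#' The table is deterministic given the seed and always contains the
#' matched-intensity record.  Scores are clamped to the valid CAS range
#' [-100, 100].
#'
#' @param config A [synthetic_cas_config()].
#' @return A [cas_table()].
#' @export
generate_cas <- function(config = synthetic_cas_config()) {
  stopifnot(inherits(config, "synthetic_cas_config"))
  off <- config$test_intensity_offsets
  sigma_true <- config$true_hwhm / hwhm_factor()
  mu <- config$peak_cas * exp(-off^2 / (2 * sigma_true^2))
  noise <- with_local_seed(config$seed,
    stats::rnorm(length(off), 0, config$noise_sd * abs(config$peak_cas)))
  cas <- pmin(100, pmax(-100, mu + noise))
  cas_table(data.frame(
    odour = config$odour,
    i_training = config$i_training,
    i_test = config$i_training * 10^off,
    median_cas = cas,
    n = config$n))
}
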