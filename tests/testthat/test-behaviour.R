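test_that("normalization anchors the matched group at (1, 1)", {
  tab <- cas_table(data.frame(
    odour = "OCT",
    i_training = 1e-3,
    i_test = c(1e-4, 1e-3, 1e-2),
    median_cas = c(-20, -40, -20),
    n = 20))
  nm <- normalize_cas(tab)
  expect_equal(nm$x, c(0.1, 1, 10))
  expect_equal(nm$y, c(0.5, 1, 0.5))
  # a ten-fold test intensity with half the matched score maps to (10, 0.5)
  expect_equal(nm$y[nm$x == 10], 0.5)
})

test_that("normalization is idempotent", {
  tab <- generate_cas(synthetic_cas_config(seed = 3))
  nm <- normalize_cas(tab)
  again <- cas_table(data.frame(odour = nm$odour, i_training = 1,
                                i_test = nm$x, median_cas = nm$y,
                                n = nm$n))
  nm2 <- normalize_cas(again)
  expect_equal(nm2$x, nm$x)
  expect_equal(nm2$y, nm$y)
})

test_that("malformed tables are rejected with the odour named", {
  base <- data.frame(odour = "AM", i_training = 1e-3,
                     i_test = c(1e-4, 1e-2), median_cas = c(-10, -20),
                     n = 20)
  expect_error(cas_table(base), "AM.*matched")
  zero <- data.frame(odour = "MCH", i_training = 1e-3,
                     i_test = c(1e-3, 1e-2), median_cas = c(0, -20),
                     n = 20)
  expect_error(normalize_cas(zero), "MCH.*zero matched")
})

test_that("the Gaussian fit recovers noiseless parameters exactly", {
  x <- seq(-3, 3, 0.5)
  for (sg in c(1, 0.9)) {
    pts <- data.frame(x = 10^x, y = exp(-x^2 / (2 * sg^2)))
    fit <- fit_cas_gaussian(pts)
    expect_equal(fit$sigma, sg, tolerance = 1e-6)
    expect_equal(fit$hwhm, sg * sqrt(2 * log(2)), tolerance = 1e-6)
    expect_equal(fit$mean, 0, tolerance = 1e-6)
  }
  expect_equal(hwhm_factor(), 1.1774, tolerance = 1e-4)
  expect_error(fit_cas_gaussian(data.frame(x = c(1, 10), y = c(1, 0.5))),
               "3 distinct")
})

test_that("the synthetic generator is deterministic and exact at zero noise", {
  cfg <- synthetic_cas_config(noise_sd = 0, seed = 5)
  tab <- generate_cas(cfg)
  sg <- cfg$true_hwhm / hwhm_factor()
  off <- log10(tab$i_test / tab$i_training)
  expect_equal(tab$median_cas, cfg$peak_cas * exp(-off^2 / (2 * sg^2)))
  cfg2 <- synthetic_cas_config(noise_sd = 0.1, seed = 9)
  expect_identical(generate_cas(cfg2), generate_cas(cfg2))
  expect_false(identical(
    generate_cas(cfg2),
    generate_cas(synthetic_cas_config(noise_sd = 0.1, seed = 10))))
})

test_that("the generator does not disturb the session RNG stream", {
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_cas(synthetic_cas_config(seed = 42)))
  expect_identical(rnorm(1), before)
})

test_that("the pipeline recovers the generating HWHM from noisy tables", {
  true_hwhm <- 1.1
  err <- vapply(1:20, function(s) {
    tab <- generate_cas(synthetic_cas_config(true_hwhm = true_hwhm,
                                             noise_sd = 0.05, seed = s))
    abs(fit_cas_gaussian(normalize_cas(tab))$hwhm - true_hwhm)
  }, numeric(1))
  expect_lt(stats::median(err) / true_hwhm, 0.1)
})
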