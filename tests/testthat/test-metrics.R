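test_that("curve_shape recognizes monotonic curves", {
  g <- seq(-3, 3, 0.05)
  cv <- tuning_curve(g, exc_response(logistic_unit(0, 1), g))
  sh <- curve_shape(cv)
  expect_true(sh$is_monotonic)
  expect_equal(sh$peak_intensity, max(g))
  expect_true(is.na(sh$fwhm))   # half-max never crossed on the right
})

test_that("fwhm of a symmetric triangle is half its base", {
  g <- seq(0, 2, 0.01)
  cv <- tuning_curve(g, pmax(0, 1 - abs(g - 1)))   # base 2, apex 1
  expect_equal(curve_shape(cv)$fwhm, 1, tolerance = 1e-9)
  expect_equal(curve_shape(cv)$peak_intensity, 1)
})

test_that("curve_shape of an all-zero curve has no width", {
  cv <- tuning_curve(1:5, rep(0, 5))
  sh <- curve_shape(cv)
  expect_equal(sh$peak_value, 0)
  expect_true(is.na(sh$fwhm))
  expect_null(sh$support)
})

test_that("tuning curves agree with direct evaluation of the circuit rule", {
  sp <- broad_circuit()
  g <- seq(-4, 4, 0.1)
  cv <- tuning_curves(sp, g)[[1L]]
  # independent re-evaluation from the constituent logistic responses
  direct <- pmax(0, exc_response(sp$exc_units[[1L]], g) -
                    inh_response(sp$inh_unit, g))
  expect_equal(cv$values, direct)
})

test_that("nestedness detects chains and their absence", {
  curves0 <- tuning_curves(default_circuit_spec("none"))
  expect_true(nestedness(curves0)$fully_nested)
  for (m in c("excitatory", "inhibitory"))
    expect_false(nestedness(tuning_curves(default_circuit_spec(m)))$fully_nested)
  # identical curves dominate each other
  cv <- curves0[[1L]]
  expect_true(nestedness(list(cv, cv))$fully_nested)
  # invariant under a common positive rescaling
  curvesE <- tuning_curves(default_circuit_spec("excitatory"))
  scaled <- lapply(curvesE, function(x)
    tuning_curve(x$grid, 3.7 * x$values))
  expect_equal(nestedness(scaled)$fully_nested,
               nestedness(curvesE)$fully_nested)
  expect_error(nestedness(list(cv)), "at least two")
  expect_error(
    nestedness(list(cv, tuning_curve(cv$grid + 1, cv$values))),
    "common grid")
})

test_that("specificity score contrasts the homeostatic and plain circuits", {
  its <- c(-1, 0, 1)
  s_none <- specificity_score(
    run_experiment_battery(default_circuit_spec("none"), its))
  for (m in c("excitatory", "inhibitory")) {
    s_m <- specificity_score(
      run_experiment_battery(default_circuit_spec(m), its))
    expect_lt(s_m, s_none)
    expect_lt(s_m, 0.25)
  }
  expect_gt(s_none, 0.5)  # off-peak trainings land far from their intensity
  expect_error(specificity_score(list()), "non-empty")
})

test_that("a single experiment trained at the circuit's peak scores ~0", {
  sp <- default_circuit_spec("none")
  pk0 <- curve_shape(tuning_curves(sp)[[1L]])$peak_intensity
  batt <- run_experiment_battery(sp, pk0)
  expect_lt(specificity_score(batt), 0.011)
})
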