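test_that("intermediate response is the rectified weighted input sum", {
  # engineer intensities at which exc = 0.3 / 0.9 and inh = 0.5 / 0.4
  exc <- logistic_unit(0, 1)
  inh1 <- logistic_unit(0, 0.5, 1.5)
  # case 1: exc 0.3, inh 0.5 with weights (1, -1) -> rectified to 0
  i_eval <- intensity_for(inh1, 0.5)               # inh = 0.5 here
  a1 <- i_eval - intensity_for(exc, 0.3)           # exc = 0.3 here
  sp1 <- circuit_spec(list(logistic_unit(a1, 1)), inh1,
                      w_exc = 1, w_inh = -1)
  expect_equal(intermediate_response(sp1, 1, i_eval), 0)
  # case 2: exc 0.9, inh 0.4 -> linear regime, 0.5
  i_eval2 <- intensity_for(inh1, 0.4)
  a2 <- i_eval2 - intensity_for(exc, 0.9)
  sp2 <- circuit_spec(list(logistic_unit(a2, 1)), inh1,
                      w_exc = 1, w_inh = -1)
  expect_equal(intermediate_response(sp2, 1, i_eval2), 0.5,
               tolerance = 1e-12)
})

test_that("index and grid validation", {
  sp <- broad_circuit()
  expect_error(intermediate_response(sp, 4, 0), "1..3")
  expect_error(intermediate_response(sp, 0, 0), "1..3")
  expect_error(tuning_curves(sp, numeric(0)), "empty")
  expect_error(tuning_curves(sp, c(0, 0, 1)), "strictly increasing")
})

test_that("uniform-weight bells rise and die within a wide grid", {
  curves <- tuning_curves(broad_circuit(), default_grid())
  for (cv in curves) {
    n <- length(cv$values)
    expect_lt(cv$values[1L], 1e-6)          # silent at the low end
    expect_lt(cv$values[n], 1e-3)           # silenced again at the top
    expect_gt(max(cv$values), 0.05)         # substantial bell in between
    pk <- which.max(cv$values)
    expect_true(pk > 1 && pk < n)           # interior maximum
  }
})

test_that("without homeostasis more sensitive units dominate pointwise", {
  set.seed(31)
  for (rep in 1:5) {
    b <- runif(1, 0.6, 3)
    spec <- circuit_spec(
      exc_units = lapply(sort(runif(3, -2, 2)), logistic_unit, b = b),
      inh_unit = logistic_unit(runif(1, -1, 2), b * runif(1, 0.2, 0.8),
                               1 + runif(1, 0.1, 1)),
      w_exc = 1, w_inh = -1)
    V <- vapply(tuning_curves(spec, seq(-5, 5, 0.05)), `[[`,
                numeric(201), "values")
    expect_true(all(V[, 1] >= V[, 2] - 1e-12))
    expect_true(all(V[, 2] >= V[, 3] - 1e-12))
  }
})

test_that("homeostasis breaks the nested ordering", {
  for (m in c("excitatory", "inhibitory")) {
    curves <- tuning_curves(default_circuit_spec(m))
    V <- vapply(curves, `[[`, numeric(length(curves[[1]]$grid)), "values")
    crossings <- 0
    for (j in 1:2) for (k in (j + 1):3) {
      djk <- V[, j] - V[, k]
      if (any(djk > 1e-9) && any(djk < -1e-9)) crossings <- crossings + 1
    }
    expect_gt(crossings, 0)
    # preferred intensities increase across the population
    pks <- vapply(curves, function(cv) cv$grid[which.max(cv$values)],
                  numeric(1))
    expect_true(all(diff(pks) > 0))
  }
})

test_that("a lone unit without inhibition reproduces its input curve", {
  sp <- circuit_spec(list(logistic_unit(0, 1)),
                     logistic_unit(0, 0.4, 1.5),
                     w_exc = 2, w_inh = 0)
  g <- seq(-3, 3, 0.1)
  cv <- tuning_curves(sp, g)[[1L]]
  expect_equal(cv$values, 2 * exc_response(logistic_unit(0, 1), g))
  expect_true(curve_shape(cv)$is_monotonic)
})

test_that("constraint violations are rejected at construction", {
  expect_error(
    circuit_spec(list(logistic_unit(0, 0.3)),
                 logistic_unit(0, 0.4, 1.5)),
    "exceed b_inh")
  expect_error(
    circuit_spec(list(logistic_unit(0, 1)), logistic_unit(0, 0.4, 0.9)),
    "inh_max > 1")
  expect_error(
    circuit_spec(list(logistic_unit(0, 1)), logistic_unit(0, 0.4, 1.5),
                 c0 = 2, c1 = -2),
    "c0 < c1")
})
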