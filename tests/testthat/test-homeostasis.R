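test_that("closed-form sensitivity matches adaptive quadrature", {
  set.seed(21)
  for (rep in 1:40) {
    a <- runif(1, -3, 3); b <- runif(1, 0.2, 4)
    c0 <- runif(1, -5, 0); c1 <- c0 + runif(1, 0.5, 8)
    s <- sensitivity(a, b, c0, c1)$s
    q <- stats::integrate(function(i) 1 / (exp(-4 * b * (i - a)) + 1),
                          c0, c1, rel.tol = 1e-12)$value
    expect_lt(abs(s - q), 1e-8)
  }
})

test_that("sensitivity limits and symmetry point", {
  b <- 1.3; c0 <- -2.5; c1 <- 3
  expect_equal(sensitivity(-50, b, c0, c1)$s, c1 - c0, tolerance = 1e-6)
  expect_equal(sensitivity(50, b, c0, c1)$s, 0, tolerance = 1e-6)
  # point symmetry of the logistic about its turning point
  expect_equal(sensitivity((c0 + c1) / 2, b, c0, c1)$s, (c1 - c0) / 2,
               tolerance = 1e-10)
})

test_that("sensitivity decreases strictly in a and stays in (0, c1 - c0)", {
  a <- seq(-6, 6, 0.25)
  s <- sensitivity(a, 0.8, -3, 3)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s < 6))
})

test_that("homeostatic excitatory weights grow with the turning point", {
  b <- 1; c0 <- -4; c1 <- 4
  a <- c(-1, 0, 1)
  d <- sensitivity(min(a), b, c0, c1)$s + 0.5
  w <- homeostatic_w_exc(a, alpha = 1, d = d, b = b, c0 = c0, c1 = c1)
  expect_true(all(w > 0))
  expect_true(all(diff(w) > 0))
  # boundary: a unit whose sensitivity equals d must be rejected
  expect_error(
    homeostatic_w_exc(min(a), alpha = 1,
                      d = sensitivity(min(a), b, c0, c1)$s,
                      b = b, c0 = c0, c1 = c1),
    "not positive")
  # limit from the sensitivity limit: s -> c1 - c0 as a -> -inf
  expect_equal(homeostatic_w_exc(-60, 1, d = (c1 - c0) + 0.25, b, c0, c1),
               0.25, tolerance = 1e-6)
})

test_that("homeostatic inhibitory weights weaken with the turning point", {
  b <- 1; c0 <- -4; c1 <- 4
  w <- homeostatic_w_inh(c(-1, 0, 1), alpha_tilde = 1, b, c0, c1)
  expect_true(all(w < 0))
  expect_true(all(diff(abs(w)) < 0))
  # symmetry value of s gives -alpha_tilde (c1 - c0)/2
  expect_equal(homeostatic_w_inh((c0 + c1) / 2, 0.5, b, c0, c1),
               -0.25 * (c1 - c0), tolerance = 1e-10)
  # far-insensitive unit: weight vanishes from below
  expect_lt(abs(homeostatic_w_inh(60, 1, b, c0, c1)), 1e-6)
})

test_that("resolve_weights applies the three modes correctly", {
  sp <- broad_circuit("none")
  w0 <- resolve_weights(sp)
  expect_equal(w0$w_exc, rep(1, 3))
  expect_equal(w0$w_inh, rep(-1, 3))

  se <- default_circuit_spec("excitatory")
  we <- resolve_weights(se)
  expect_equal(we$w_inh, rep(-1, 3))
  expect_true(all(diff(we$w_exc) > 0))   # less sensitive -> stronger

  si <- default_circuit_spec("inhibitory")
  wi <- resolve_weights(si)
  expect_equal(wi$w_exc, rep(1, 3))
  expect_true(all(diff(abs(wi$w_inh)) < 0))  # less drive -> weaker inhibition
})
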