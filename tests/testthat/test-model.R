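test_that("activation function satisfies its normalization and values", {
  expect_identical(sigmoid_act(0, 1), 0)
  expect_equal(sigmoid_act_deriv(0, 1, 1), 1)
  # frozen high-precision values: tanh(1)*cosh(1)^2 and the x -> Inf limit
  expect_equal(sigmoid_act(1, 1), 1.8134302039235095, tolerance = 1e-12)
  lim <- (1 + tanh(1)) * cosh(1)^2
  expect_equal(sigmoid_act(50, 1), lim, tolerance = 1e-12)
  expect_equal(lim, 4.1945280494653251, tolerance = 1e-12)
})

test_that("activation is strictly increasing and bounded", {
  set.seed(11)
  for (a in c(0.5, 1, 2)) {
    x <- sort(stats::runif(200, -8, 8))
    v <- sigmoid_act(x, a)
    expect_true(all(diff(v) > 0))
    expect_true(all(abs(v) < (1 + tanh(a)) * cosh(a)^2 + 1e-12))
  }
})

test_that("closed-form derivatives match finite differences", {
  grid <- seq(-5, 5, by = 0.25)
  steps <- c(1e-3, 5e-3, 2e-2)   # balance truncation vs roundoff per order
  for (a in c(0.7, 1, 1.5)) {
    for (ord in 1:3) {
      exact <- sigmoid_act_deriv(grid, a, ord)
      num <- vapply(grid, function(x)
        fd_central(function(y) sigmoid_act(y, a), x, ord, h = steps[ord]), 0)
      expect_lt(max(abs(exact - num)) / max(abs(exact)), 1e-6)
    }
    expect_true(all(sigmoid_act_deriv(grid, a, 1) > 0))
  }
})

test_that("right-hand side vanishes at equilibria and is swap-equivariant", {
  p <- paper_params()
  expect_equal(model_rhs(p, c(0, 0), c(0, 0), c(0, 0)), c(0, 0))
  # nontrivial equilibrium from the bisection oracle
  xs <- bisect_equilibrium(p, 1.2, 5)
  e <- c(xs, xs)
  expect_lt(max(abs(model_rhs(p, e, e, e))), 1e-11)
  set.seed(21)
  for (i in 1:25) {
    u <- stats::rnorm(2); v <- stats::rnorm(2); w <- stats::rnorm(2)
    lhs <- model_rhs(p, swap_state(u), swap_state(v), swap_state(w))
    rhs <- swap_state(model_rhs(p, u, v, w))
    expect_identical(lhs, rhs)
  }
})

test_that("swap is an involution with the diagonal as fixed space", {
  expect_identical(swap_state(c(1, 2)), c(2, 1))
  expect_identical(swap_state(c(3.5, 3.5)), c(3.5, 3.5))
  set.seed(5)
  v <- stats::rnorm(2)
  expect_identical(swap_state(swap_state(v)), v)
})

test_that("parameter validation rejects nonpositive values and delay misorder", {
  expect_error(pop_model(alpha1 = -0.1, alpha2 = 0.5), "positive")
  expect_error(pop_model(alpha1 = 0.1, alpha2 = 0.5, tau1 = 21, tau2 = 20),
               "tau2")
  expect_s3_class(pop_model(0.069, 0.55), "pop_model")
})

test_that("plain-text config round-trips and presets resolve", {
  p <- pop_model(alpha1 = 0.07, alpha2 = 0.61, beta1 = 1.9, beta2 = 1.25,
                 tau1 = 10, tau2 = 19, a = 0.8)
  f <- withr::local_tempfile(fileext = ".cfg")
  write_model_config(p, f)
  q <- read_model_config(f)
  expect_equal(unclass(q), unclass(p))
  # preset line plus override
  writeLines(c("# comment", "preset = paper-default", "alpha2 = 0.6"), f)
  r <- read_model_config(f)
  expect_equal(r$alpha2, 0.6)
  expect_equal(r$tau2, 20.3)
})
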