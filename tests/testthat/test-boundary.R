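test_that("Hopf curves solve the imaginary-root system to tight residual", {
  set.seed(71)
  om <- stats::runif(1000, 0.01, 3)
  om <- om[abs(sin(om * (20.3 - 11.6))) > 1e-3]
  for (fam in c("plus", "minus")) {
    k <- hopf_curve(om, 11.6, 20.3, fam)
    res <- Mod(char_factor(1i * om, k$k1, k$k2, 11.6, 20.3, fam))
    expect_lt(max(res), 1e-10)
  }
  expect_error(hopf_curve(pi / 8.7, 11.6, 20.3, "minus"), "asymptote")
})

test_that("steady-state lines: the plus line never reaches positive gains", {
  mline <- steady_state_line("minus")
  expect_true(mline$reachable)
  k1 <- 0.138
  expect_equal(mline$intercept + mline$slope * k1, 1.138)
  expect_equal(Mod(char_factor(0, k1, 1 + k1, 11.6, 20.3, "minus")), 0)
  pline <- steady_state_line("plus")
  expect_false(pline$reachable)
  # k2 = -1 - k1 < 0 whenever k1 > -1: no intersection with the quadrant
  expect_true(all(pline$intercept + pline$slope * seq(0, 10, 0.5) < 0))
})

test_that("degenerate Hopf frequencies are absent for the reference delays", {
  dl <- degenerate_hopf_lines(11.6, 20.3, omega_max = 3)
  expect_equal(nrow(dl$lines), 0)
  expect_true(all(dl$near_misses$residual > 1e-6))
})

test_that("stability region geometry reproduces the reference values", {
  reg <- stability_region(11.6, 20.3)
  expect_equal(round(reg$omega_ranges$plus, 3), c(0.148, 0.150))
  expect_equal(round(reg$omega_ranges$minus, 3), c(0.250, 0.294))
  zh <- reg$codim2[reg$codim2$kind == "ZH", ]
  hh <- reg$codim2[reg$codim2$kind == "HH", ]
  expect_equal(round(c(zh$k1, zh$k2), 3), c(0.008, 1.008))
  expect_equal(round(c(hh$k1, hh$k2), 3), c(0.056, 0.995))
  # HH really is a simultaneous root of both factors
  expect_lt(Mod(char_factor(1i * hh$omega1, hh$k1, hh$k2, 11.6, 20.3, "plus")),
            1e-9)
  expect_lt(Mod(char_factor(1i * hh$omega2, hh$k1, hh$k2, 11.6, 20.3, "minus")),
            1e-9)
  # square containment: the boundary never dips inside |k1| + |k2| < 1
  expect_gte(min(abs(reg$boundary$k1) + abs(reg$boundary$k2)), 1 - 1e-9)
})

test_that("boundary points are spectrally neutral, interior stable, exterior unstable", {
  reg <- stability_region(11.6, 20.3)
  b <- reg$boundary
  idx <- round(seq(2, nrow(b) - 1, length.out = 25))
  for (i in idx) {
    # the neutral root: lambda = 0 on the fold segment, an imaginary
    # pair on the Hopf arcs
    if (b$label[i] == "fold") {
      expect_lt(abs(1 + b$k1[i] - b$k2[i]), 1e-9)
    } else {
      fam <- if (b$label[i] == "h+") "plus" else "minus"
      r <- delaypop:::axis_nearest_root(b$k1[i], b$k2[i], 11.6, 20.3, fam)
      expect_lt(abs(Re(r)), 1e-6)
    }
    nin <- count_unstable_roots(0.97 * b$k1[i], 0.97 * b$k2[i], 11.6, 20.3,
                                "minus") +
      count_unstable_roots(0.97 * b$k1[i], 0.97 * b$k2[i], 11.6, 20.3, "plus")
    expect_equal(nin, 0L)
    nout <- count_unstable_roots(1.03 * b$k1[i], 1.03 * b$k2[i], 11.6, 20.3,
                                 "minus") +
      count_unstable_roots(1.03 * b$k1[i], 1.03 * b$k2[i], 11.6, 20.3, "plus")
    expect_gt(nout, 0L)
  }
})

test_that("gain-plane points map linearly to coupling parameters", {
  p <- paper_params()
  expect_equal(unname(gains_to_alphas(0.056, 0.995, p)),
               c(0.056 / 2, 0.995 / 1.2))
  expect_equal(round(unname(gains_to_alphas(0.008, 1.008, p)), 3),
               c(0.004, 0.840))
  expect_equal(round(unname(gains_to_alphas(0.491, 0.614, p)), 3),
               c(0.246, 0.512), tolerance = 0.002)
})

test_that("a branch that never leaves the region has zero crossings", {
  p <- paper_params()
  inside <- data.frame(k1 = seq(0.05, 0.3, length.out = 40),
                       k2 = seq(0.2, 0.6, length.out = 40))
  cc <- count_hopf_crossings(inside, p, refine = 0)
  expect_identical(cc$hopf, 0L)
  expect_identical(cc$steady, 0L)
})

test_that("the trivial-branch line exits the region once through the symmetric arc", {
  p <- paper_params()
  tb <- equilibrium_branch(p, range = c(0.6, 0.8), trivial = TRUE, n = 150)
  cc <- count_hopf_crossings(tb, p, refine = 0)
  expect_identical(cc$hopf, 1L)
  hop <- tb$events[tb$events$type == "hopf", ]
  expect_equal(hop$alpha2[1] * p$beta2, 0.9252, tolerance = 1e-3)
})
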