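test_that("equilibrium search always contains the origin and matches bisection", {
  set.seed(31)
  for (i in 1:5) {
    p <- pop_model(alpha1 = stats::runif(1, 0.01, 0.3),
                   alpha2 = stats::runif(1, 0.2, 1))
    eq <- find_equilibria(p)
    expect_true(any(abs(eq$x_star) < 1e-10))
    expect_lt(max(abs(equilibrium_residual(eq$x_star, p))), 1e-10)
  }
  p <- paper_params()                       # alpha2 = 0.55
  eq <- find_equilibria(p)
  pos <- eq$x_star[eq$x_star > 1e-3]
  oracle <- bisect_equilibrium(p, 1.2, 5)
  expect_true(any(abs(pos - oracle) < 1e-9))
})

test_that("every equilibrium is a fixed point of the self-consistency map", {
  p <- paper_params()
  eq <- find_equilibria(p)
  for (x in eq$x_star[abs(eq$x_star) > 1e-6])
    expect_lt(abs(x - delaypop:::equilibrium_map_H(x, p)), 1e-10)
})

test_that("planar Newton from asymmetric starts lands on the diagonal", {
  p <- paper_params()
  F <- function(z) c(
    -z[1] - p$alpha1 * sigmoid_act(p$beta1 * z[1]) +
      p$alpha2 * sigmoid_act(p$beta2 * z[2]),
    -z[2] - p$alpha1 * sigmoid_act(p$beta1 * z[2]) +
      p$alpha2 * sigmoid_act(p$beta2 * z[1]))
  set.seed(41)
  hits <- 0
  for (i in 1:50) {
    z <- stats::runif(2, -1.5, 3)
    for (it in 1:200) {
      f0 <- F(z)
      if (sqrt(sum(f0^2)) < 1e-13) break
      J <- matrix(0, 2, 2); h <- 1e-7
      for (j in 1:2) { zp <- z; zp[j] <- zp[j] + h; J[, j] <- (F(zp) - f0) / h }
      st <- tryCatch(solve(J, f0), error = function(e) NULL)
      if (is.null(st)) break
      if (sqrt(sum(st^2)) > 1) st <- st / sqrt(sum(st^2))
      z <- z - st
    }
    if (sqrt(sum(F(z)^2)) < 1e-10) {
      hits <- hits + 1
      expect_lt(abs(z[1] - z[2]), 1e-8)
    }
  }
  expect_gt(hits, 30)      # most starts converge; all converged ones symmetric
})

test_that("gains at the origin are linear in the couplings", {
  p <- paper_params()
  k <- equilibrium_gains(p, 0)
  expect_equal(unname(k), c(p$alpha1 * p$beta1, p$alpha2 * p$beta2))
  expect_equal(unname(k[1]), 0.138)
  tb <- equilibrium_branch(p, range = c(0.5, 1.0), trivial = TRUE, n = 60)
  expect_equal(tb$points$k2, tb$points$alpha2 * p$beta2)
  expect_true(all(tb$points$k1 == 0.138))
})

test_that("trivial branch carries the closed-form transcritical point", {
  p <- paper_params()
  tb <- equilibrium_branch(p, range = c(0.9, 1.0), trivial = TRUE, n = 40)
  bp <- tb$events[tb$events$type == "branch-point", ]
  expect_equal(nrow(bp), 1)
  expect_equal(bp$alpha2, (1 + p$alpha1 * p$beta1) / p$beta2, tolerance = 1e-12)
})

test_that("nontrivial branch fold agrees with the scalar minimization oracle", {
  p <- paper_params()
  nb <- equilibrium_branch(p, range = c(0.5, 2.2), trivial = FALSE, n = 200)
  fold <- nb$events[nb$events$type == "fold", ]
  expect_gte(nrow(fold), 1)
  oracle <- stats::optimize(function(x) delaypop:::branch_alpha2_of_x(x, p),
                            c(0.5, 2.2))
  expect_equal(fold$alpha2[1], oracle$objective, tolerance = 1e-7)
  # the fold satisfies the zero-eigenvalue condition of the minus factor
  pf <- p; pf$alpha2 <- fold$alpha2[1]
  k <- equilibrium_gains(pf, fold$x_star[1])
  expect_lt(abs(1 + k[1] - k[2]), 1e-5)
})

test_that("fold-Hopf Newton refines a seed to a tight simultaneous root", {
  p <- paper_params()
  zh2 <- locate_codim2(p, "fold-hopf",
                       seed = list(alpha1 = 0.009, alpha2 = 0.442,
                                   x_star = 1.235, omega = 0.148))
  expect_lt(zh2$residual, 1e-10)
  pz <- p; pz$alpha1 <- zh2$alpha1; pz$alpha2 <- zh2$alpha2
  k <- equilibrium_gains(pz, zh2$x_star)
  expect_lt(abs(equilibrium_residual(zh2$x_star, pz)), 1e-10)
  expect_lt(abs(1 + k[1] - k[2]), 1e-10)
  expect_lt(Mod(char_factor(1i * zh2$omega, k[1], k[2], p$tau1, p$tau2,
                            "plus")), 1e-9)
})
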