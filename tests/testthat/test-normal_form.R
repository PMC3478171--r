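test_that("eigenvector normalization identity holds along the symmetric curve", {
  set.seed(81)
  # q^T Delta'(i omega) p = 1 with the derivative taken numerically, so
  # the identity is checked independently of the closed form of q0
  dmat <- function(lam, k1, k2) {
    h <- 1e-6
    (char_matrix(lam + h, k1, k2, 11.6, 20.3) -
       char_matrix(lam - h, k1, k2, 11.6, 20.3)) / (2 * h)
  }
  for (om in stats::runif(25, 0.251, 0.293)) {
    k <- hopf_curve(om, 11.6, 20.3, "minus")
    q0 <- hopf_q0(om, k$k1, k$k2, 11.6, 20.3)
    pair <- q0 * sum(dmat(1i * om, k$k1, k$k2) %*% c(1, 1))
    expect_equal(pair, 1 + 0i, tolerance = 1e-7)
  }
  # with both delays zero the normalization reduces to 1/2
  expect_equal(hopf_q0(0.3, 0.4, 0.7, 0, 0), 0.5 + 0i)
})

test_that("closed-form cubic coefficient matches the multilinear assembly", {
  p <- paper_params()
  for (om in c(0.255, 0.2665, 0.281, 0.292)) {
    k <- hopf_curve(om, p$tau1, p$tau2, "minus")
    pp <- p; pp$alpha1 <- k$k1 / p$beta1; pp$alpha2 <- k$k2 / p$beta2
    c1a <- first_lyapunov(om, pp, method = "closed")$c1
    c1b <- first_lyapunov(om, pp, method = "multilinear")$c1
    expect_equal(c1a, c1b, tolerance = 1e-8)
  }
})

test_that("criticality flips from supercritical to subcritical along the arc", {
  p <- paper_params()
  mk <- function(om) {
    k <- hopf_curve(om, p$tau1, p$tau2, "minus")
    pp <- p; pp$alpha1 <- k$k1 / p$beta1; pp$alpha2 <- k$k2 / p$beta2
    first_lyapunov(om, pp)
  }
  expect_equal(mk(0.26)$criticality, "supercritical")
  expect_equal(mk(0.29)$criticality, "subcritical")
})

test_that("the generalized Hopf point sits at the reference location", {
  p <- paper_params()
  gh <- find_generalized_hopf(p)
  expect_equal(round(gh$omega, 3), 0.281)
  expect_equal(round(c(gh$k1, gh$k2), 3), c(0.491, 0.614))
  expect_lt(abs(gh$ell1), 1e-6)
})

test_that("off-curve points are rejected by the Hopf-condition guard", {
  p <- paper_params()       # (k1, k2) = (0.138, 0.66): not on the curve
  expect_error(first_lyapunov(0.27, p), "not on the symmetric Hopf curve")
})

test_that("simulation confirms the criticality convention at a supercritical Hopf", {
  # on the symmetric curve at omega = 0.26 the coefficient is negative:
  # just past the Hopf a small stable orbit must exist, just before it
  # perturbations must decay
  p <- paper_params()
  om <- 0.26
  k <- hopf_curve(om, p$tau1, p$tau2, "minus")
  base <- p; base$alpha1 <- k$k1 / p$beta1; base$alpha2 <- k$k2 / p$beta2
  expect_lt(first_lyapunov(om, base)$ell1, 0)
  # cross the boundary radially (both couplings scaled together): this
  # is transversal to the Hopf curve everywhere along the arc
  run_amp <- function(fac, t_end = 3000) {
    pp <- base
    pp$alpha1 <- base$alpha1 * fac; pp$alpha2 <- base$alpha2 * fac
    traj <- integrate_dde(pp, function(t) c(0.05, 0.05), t_end = t_end,
                          rtol = 1e-8, atol = 1e-10)
    win <- function(a, b) {
      i <- traj$times >= a & traj$times <= b
      (max(traj$x[i, 1]) - min(traj$x[i, 1])) / 2
    }
    c(early = win(800, 1100), late = win(t_end - 300, t_end))
  }
  below <- run_amp(0.97)                    # below threshold: decay
  expect_lt(below[["late"]], 0.1 * below[["early"]])
  a1 <- run_amp(1.02)                       # above: finite small orbit
  expect_gt(a1[["late"]], 0.02)
  expect_lt(a1[["late"]], 0.6)
  a2 <- run_amp(1.04)                       # amplitude ~ sqrt(excess)
  expect_equal(a2[["late"]] / a1[["late"]], sqrt(2), tolerance = 0.25)
})
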