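test_that("characteristic determinant factorizes exactly", {
  set.seed(51)
  for (i in 1:30) {
    lam <- complex(real = stats::rnorm(1), imaginary = stats::rnorm(1))
    k1 <- stats::runif(1, 0, 2); k2 <- stats::runif(1, 0, 2)
    d <- det2(char_matrix(lam, k1, k2, 11.6, 20.3))
    f <- char_factor(lam, k1, k2, 11.6, 20.3, "plus") *
      char_factor(lam, k1, k2, 11.6, 20.3, "minus")
    expect_equal(d, f, tolerance = 1e-12)
  }
})

test_that("zero-eigenvalue conditions come out of the factors at the origin", {
  expect_equal(char_factor(0, 0.3, 0.8, 11.6, 20.3, "minus"), 1 + 0.3 - 0.8)
  expect_equal(char_factor(0, 0.3, 0.8, 11.6, 20.3, "plus"), 1 + 0.3 + 0.8)
})

test_that("uncoupled linearization has its rightmost root at -1", {
  r <- rightmost_roots(0, 0, 11.6, 20.3, count = 2)
  expect_equal(r$rho[1], -1, tolerance = 1e-10)
  expect_equal(r$omega[1], 0, tolerance = 1e-10)
})

test_that("the delay-independent square implies spectral stability", {
  set.seed(61)
  for (i in 1:12) {
    k <- stats::runif(2, 0, 1); k <- 0.98 * k / max(1, sum(k))
    expect_true(sufficient_stability(k[1], k[2]))
    expect_equal(count_unstable_roots(k[1], k[2], 11.6, 20.3, "minus"), 0L)
    expect_equal(count_unstable_roots(k[1], k[2], 11.6, 20.3, "plus"), 0L)
    r <- rightmost_roots(k[1], k[2], 11.6, 20.3, count = 1)
    expect_lt(r$rho[1], 0)
  }
  expect_false(sufficient_stability(0.5, 0.6))
})

test_that("the extended region keeps points outside the square stable", {
  # the origin just before its Hopf: |k1| + |k2| > 1 yet still stable
  r <- rightmost_roots(0.138, 0.92, 11.6, 20.3, count = 1)
  expect_false(sufficient_stability(0.138, 0.92))
  expect_lt(r$rho[1], 0)
})

test_that("root sets agree with an argument-principle rectangle count", {
  # strongly unstable gains from the nontrivial branch: roots cluster in
  # a thin strip near the axis
  for (k in list(c(0.3007, 1.5597), c(0.2, 1.3))) {
    for (fam in c("plus", "minus")) {
      roots <- delaypop:::factor_roots(k[1], k[2], 11.6, 20.3, fam,
                                       cutoff = -0.4)
      inbox <- sum(roots$rho > 0.001 & roots$omega > 0.01 & roots$omega < 2 &
                     roots$rho < 0.3)
      oracle <- rect_root_count(k[1], k[2], 11.6, 20.3, fam,
                                0.001, 0.3, 0.01, 2)
      expect_equal(inbox, oracle)
    }
  }
})

test_that("symmetric Hopf curve points carry purely imaginary minus-factor roots", {
  for (om in c(0.255, 0.27, 0.29)) {
    k <- hopf_curve(om, 11.6, 20.3, "minus")
    expect_lt(Mod(char_factor(1i * om, k$k1, k$k2, 11.6, 20.3, "minus")),
              1e-10)
    r <- delaypop:::axis_nearest_root(k$k1, k$k2, 11.6, 20.3, "minus")
    expect_lt(abs(Re(r)), 1e-8)
    expect_equal(Im(r), om, tolerance = 1e-8)
  }
})

test_that("eigenvectors of the characteristic matrix classify by symmetry", {
  om <- 0.27
  k <- hopf_curve(om, 11.6, 20.3, "minus")
  M <- char_matrix(1i * om, k$k1, k$k2, 11.6, 20.3)
  # minus-factor root: null vector is the symmetric (1, 1) direction
  expect_lt(Mod(sum(M %*% c(1, 1))), 1e-9)
  kp <- hopf_curve(om, 11.6, 20.3, "plus")
  Mp <- char_matrix(1i * om, kp$k1, kp$k2, 11.6, 20.3)
  expect_lt(Mod(sum(Mp %*% c(1, -1))), 1e-9)
})

test_that("the frequency bound excludes fast imaginary roots", {
  expect_true(frequency_bound(0.7, 0.7, 1))
  # every Hopf-curve point at omega >= 1 lies outside the omega0 = 1 square
  for (fam in c("plus", "minus")) {
    oms <- seq(1.01, 5, by = 0.01)
    oms <- oms[abs(sin(oms * 8.7)) > 1e-3]
    k <- hopf_curve(oms, 11.6, 20.3, fam)
    expect_true(all(abs(k$k1) + abs(k$k2) >= sqrt(2) - 1e-9))
  }
})
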