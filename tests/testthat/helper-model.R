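# shared fixtures: the reference parameter set and a few oracles used
# across test files

paper_params <- function(...) pop_model_preset(...)

# independent bisection oracle for the scalar equilibrium equation
bisect_equilibrium <- function(params, lo, hi, tol = 1e-13) {
  g <- function(x) equilibrium_residual(x, params)
  stopifnot(g(lo) * g(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Richardson-extrapolated central differences, the derivative oracle
# (all three stencils have leading error ~ h^2)
fd_central <- function(f, x, order, h = 1e-3) {
  d1 <- function(h) switch(
    order,
    (f(x + h) - f(x - h)) / (2 * h),
    (f(x + h) - 2 * f(x) + f(x - h)) / h^2,
    (f(x + 2 * h) - 2 * f(x + h) + 2 * f(x - h) - f(x - 2 * h)) / (2 * h^3))
  (4 * d1(h / 2) - d1(h)) / 3
}

# determinant of a complex 2x2 matrix (base det rejects complex input)
det2 <- function(M) M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]

# argument-principle count over an explicit rectangle, used as an
# independent completeness oracle for the root finder
rect_root_count <- function(k1, k2, tau1, tau2, family, re0, re1, im0, im1,
                            n = 4000) {
  seg <- function(a, b) a + (b - a) * seq(0, 1, length.out = n)
  lam <- c(seg(re0 + 1i * im0, re1 + 1i * im0),
           seg(re1 + 1i * im0, re1 + 1i * im1),
           seg(re1 + 1i * im1, re0 + 1i * im1),
           seg(re0 + 1i * im1, re0 + 1i * im0))
  f <- char_factor(lam, k1, k2, tau1, tau2, family)
  d <- diff(Arg(f))
  d <- d - 2 * pi * round(d / (2 * pi))
  round(sum(d) / (2 * pi))
}
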