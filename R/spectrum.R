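#' Characteristic factors of the symmetric linearization
#'
#' At a symmetric equilibrium the planar linearization decouples, and the
#' characteristic determinant factorizes as
#' \deqn{\det\Delta(\lambda) = \Delta_+(\lambda)\,\Delta_-(\lambda),
#'   \qquad \Delta_\pm(\lambda) = \lambda + 1 + k_1 e^{-\lambda\tau_1}
#'   \pm k_2 e^{-\lambda\tau_2},}
#' where \eqn{(k_1, k_2)} are the linearization gains of
#' [equilibrium_gains()].  Roots of the minus factor carry symmetric
#' (in-phase) eigenmodes, roots of the plus factor antisymmetric
#' (anti-phase) ones.
#'
#' @param lambda complex argument (vectorized).
#' @param k1,k2 linearization gains.
#' @param tau1,tau2 the two delays.
#' @param family `"plus"` or `"minus"`.
#' @return Complex value(s) of the factor.
#' @export
char_factor <- function(lambda, k1, k2, tau1, tau2,
                        family = c("minus", "plus")) {
  s <- if (match.arg(family) == "plus") 1 else -1
  lambda + 1 + k1 * exp(-lambda * tau1) + s * k2 * exp(-lambda * tau2)
}

# derivative of the factor with respect to lambda
char_factor_deriv <- function(lambda, k1, k2, tau1, tau2, family = "minus") {
  s <- if (family == "plus") 1 else -1
  1 - k1 * tau1 * exp(-lambda * tau1) - s * k2 * tau2 * exp(-lambda * tau2)
}

#' Full 2x2 characteristic matrix
#'
#' The characteristic matrix of the planar linearization; its determinant
#' equals the product of the two factors of [char_factor()].  Needed in
#' matrix form by the normal-form computation.
#'
#' @inheritParams char_factor
#' @return A 2x2 complex matrix.
#' @export
char_matrix <- function(lambda, k1, k2, tau1, tau2) {
  d <- lambda + 1 + k1 * exp(-lambda * tau1)
  o <- -k2 * exp(-lambda * tau2)
  matrix(c(d, o, o, d), 2, 2)
}

# Chebyshev differentiation matrix on [-1, 1] (N+1 points), standard
# collocation construction; nodes ordered from 1 down to -1.
cheb_diff <- function(N) {
  x <- cos(pi * (0:N) / N)
  c <- c(2, rep(1, N - 1), 2) * (-1)^(0:N)
  X <- matrix(x, N + 1, N + 1)
  dX <- X - t(X)
  D <- (c %o% (1 / c)) / (dX + diag(N + 1))
  D <- D - diag(rowSums(D))
  list(x = x, D = D, w = c(1 / 2, rep(1, N - 1), 1 / 2) * (-1)^(0:N))
}

# barycentric interpolation row at point xx for Chebyshev nodes cb$x
cheb_interp_row <- function(cb, xx) {
  d <- xx - cb$x
  hit <- abs(d) < 1e-14
  if (any(hit)) {
    r <- numeric(length(cb$x)); r[which(hit)[1L]] <- 1
    return(r)
  }
  r <- cb$w / d
  r / sum(r)
}

#' Rightmost characteristic roots
#'
#' Locates the characteristic roots with largest real part of one or both
#' factors of the linearization.  A pseudospectral (Chebyshev) collocation
#' of the scalar delay operator on \eqn{[-\tau_2, 0]} supplies starting
#' values; each candidate is then polished by a damped Newton iteration on
#' the exact transcendental factor, so the returned roots carry no
#' discretization bias.  Completeness of the returned set in a right
#' half-plane window is cross-checked against an argument-principle count
#' ([count_unstable_roots()] machinery); a mismatch triggers a retry at
#' doubled collocation order and, failing that, an error.
#'
#' Only roots with nonnegative imaginary part are reported; complex roots
#' come in conjugate pairs.
#'
#' @inheritParams char_factor
#' @param count number of leading roots to return (per call, after
#'   merging both factors if `family = "both"`).
#' @param family `"minus"`, `"plus"` or `"both"`.
#' @param N collocation order of the discretized delay operator.
#' @param cutoff real part below which roots are not resolved.
#' @return A data frame with columns `rho` (real part), `omega`
#'   (imaginary part, >= 0), `factor` (`"plus"`/`"minus"`), sorted by
#'   decreasing `rho`.
#' @export
rightmost_roots <- function(k1, k2, tau1, tau2, count = 5,
                            family = c("both", "minus", "plus"),
                            N = 64, cutoff = -1.2) {
  family <- match.arg(family)
  fams <- if (family == "both") c("minus", "plus") else family
  out <- do.call(rbind, lapply(fams, function(f)
    factor_roots(k1, k2, tau1, tau2, f, N = N, cutoff = cutoff)))
  out <- out[order(-out$rho), , drop = FALSE]
  utils::head(out, count)
}

# all verified roots of one factor with Re > cutoff, Im >= 0
factor_roots <- function(k1, k2, tau1, tau2, family, N = 64, cutoff = -1.2) {
  sgn <- if (family == "plus") 1 else -1
  attempt <- function(N) {
    cb <- cheb_diff(N)
    A <- cb$D * 2 / tau2           # nodes map to [-tau2, 0]
    to_x <- function(tt) 2 * tt / tau2 + 1
    A[1, ] <- -cheb_interp_row(cb, to_x(0)) -
      k1 * cheb_interp_row(cb, to_x(-tau1)) +
      sgn * k2 * cheb_interp_row(cb, to_x(-tau2))
    ev <- eigen(A, only.values = TRUE)$values
    ev <- ev[Re(ev) > cutoff - 0.5 & abs(Im(ev)) < 0.7 * N / tau2]
    roots <- complex(0)
    for (l0 in ev) {
      lam <- l0; ok <- FALSE
      for (i in 1:60) {
        fv <- char_factor(lam, k1, k2, tau1, tau2, family)
        if (!is.finite(abs(fv))) break
        if (abs(fv) < 1e-13) { ok <- TRUE; break }
        step <- fv / char_factor_deriv(lam, k1, k2, tau1, tau2, family)
        if (abs(step) > 0.5) step <- 0.5 * step / abs(step)
        lam <- lam - step
      }
      if (ok) roots <- c(roots, lam)
    }
    roots <- roots[Re(roots) > cutoff & Im(roots) > -1e-9]
    roots[Im(roots) < 0] <- Conj(roots[Im(roots) < 0])
    if (length(roots)) {
      roots <- roots[order(-Re(roots))]
      keep <- complex(0)
      for (z in roots)
        if (!length(keep) || min(abs(z - keep)) > 1e-7) keep <- c(keep, z)
      roots <- keep
    }
    roots
  }
  polish_from <- function(seeds) {
    roots <- complex(0)
    for (l0 in seeds) {
      lam <- l0; ok <- FALSE
      for (i in 1:60) {
        fv <- char_factor(lam, k1, k2, tau1, tau2, family)
        if (!is.finite(abs(fv))) break
        if (abs(fv) < 1e-13) { ok <- TRUE; break }
        step <- fv / char_factor_deriv(lam, k1, k2, tau1, tau2, family)
        if (abs(step) > 0.5) step <- 0.5 * step / abs(step)
        lam <- lam - step
      }
      if (ok) roots <- c(roots, lam)
    }
    roots
  }
  dedupe <- function(roots) {
    roots <- roots[Re(roots) > cutoff & Im(roots) > -1e-9]
    roots[Im(roots) < 0] <- Conj(roots[Im(roots) < 0])
    if (!length(roots)) return(roots)
    roots <- roots[order(-Re(roots))]
    keep <- complex(0)
    for (z in roots)
      if (!length(keep) || min(abs(z - keep)) > 1e-7) keep <- c(keep, z)
    keep
  }
  roots <- attempt(N)
  # verify unstable-root completeness by winding count
  n_exp <- winding_count(k1, k2, tau1, tau2, sgn)
  n_got <- count_from_roots(roots)
  if (n_got != n_exp) {
    # long delays cluster roots in a thin strip along the axis where the
    # discretization can skip them; sweep Newton seeds along the strip
    om_bd <- sqrt(max((abs(k1) + abs(k2))^2 - 1, 0)) + 0.3
    seeds <- as.vector(outer(c(0.002, 0.01, 0.04, 0.1),
                             1i * seq(0.01, om_bd, by = pi / (4 * tau2)), `+`))
    roots <- dedupe(c(roots, polish_from(seeds)))
    n_got <- count_from_roots(roots)
  }
  if (n_got != n_exp) {
    roots <- dedupe(c(roots, attempt(2 * N)))
    n_got <- count_from_roots(roots)
  }
  if (n_got != n_exp) {
    # roots essentially on the imaginary axis make both counts ambiguous
    # by their own multiplicity; only a residual mismatch is an error
    near_axis <- sum(ifelse(Im(roots[abs(Re(roots)) < 1e-6]) > 1e-9, 2L, 1L))
    if (abs(n_got - n_exp) > near_axis)
      stop(sprintf(
        "root finder incomplete for %s factor (argument principle: %d, found: %d)",
        family, n_exp, n_got))
  }
  data.frame(rho = Re(roots), omega = Im(roots),
             factor = rep(family, length(roots)))
}

count_from_roots <- function(roots) {
  if (!length(roots)) return(0L)
  unstab <- roots[Re(roots) > 0]
  sum(ifelse(Im(unstab) > 1e-9, 2L, 1L))
}

# argument-principle count of roots with Re > 0 for one factor (conjugates
# included).  R chosen from the a-priori bound: imaginary parts of unstable
# roots satisfy |omega| < sqrt((|k1|+|k2|)^2 - 1) when that is real.
winding_count <- function(k1, k2, tau1, tau2, sgn, npts = 6000) {
  R <- max(2, 1.5 * sqrt(max((abs(k1) + abs(k2))^2 - 1, 0) + 1))
  y <- seq(R, -R, length.out = npts)
  lam <- c(1i * y, R * exp(1i * seq(-pi / 2, pi / 2, length.out = npts %/% 3)))
  f <- lam + 1 + k1 * exp(-lam * tau1) + sgn * k2 * exp(-lam * tau2)
  d <- diff(Arg(f))
  d <- d - 2 * pi * round(d / (2 * pi))
  as.integer(round(sum(d) / (2 * pi)))
}

# complex root of one factor closest to the imaginary axis (omega > 0),
# from Newton polishes seeded at the minima of |Delta(i*omega)|
axis_nearest_root <- function(k1, k2, tau1, tau2, family) {
  om_max <- sqrt(max((abs(k1) + abs(k2))^2 - 1, 0)) + 0.5
  oms <- seq(1e-3, om_max, length.out = 2000)
  v <- abs(char_factor(1i * oms, k1, k2, tau1, tau2, family))
  cand <- oms[which(diff(sign(diff(v))) > 0) + 1L]
  best <- NA_complex_
  for (om0 in cand) {
    lam <- 1i * om0
    for (i in 1:50) {
      fv <- char_factor(lam, k1, k2, tau1, tau2, family)
      if (abs(fv) < 1e-13) break
      lam <- lam - fv / char_factor_deriv(lam, k1, k2, tau1, tau2, family)
    }
    if (abs(fv) < 1e-11 && Im(lam) > 1e-6 &&
        (is.na(best) || abs(Re(lam)) < abs(Re(best)))) best <- lam
  }
  best
}

#' Count characteristic roots in the open right half-plane
#'
#' Argument-principle (winding-number) count of the unstable roots of one
#' characteristic factor, conjugate pairs counted twice.  Robust against
#' the clustering of roots near the imaginary axis that long delays
#' produce, and therefore used as the arbiter of stability along
#' continuation branches.
#'
#' @inheritParams char_factor
#' @return Integer number of roots with positive real part.
#' @export
count_unstable_roots <- function(k1, k2, tau1, tau2,
                                 family = c("minus", "plus")) {
  sgn <- if (match.arg(family) == "plus") 1 else -1
  winding_count(k1, k2, tau1, tau2, sgn)
}

#' Spectral abscissa of the linearization
#'
#' Largest real part over the roots of both characteristic factors.
#'
#' @inheritParams char_factor
#' @return A list with `max_re`, and the leading root's `omega` and
#'   `factor`.
#' @export
spectral_abscissa <- function(k1, k2, tau1, tau2) {
  r <- rightmost_roots(k1, k2, tau1, tau2, count = 1)
  list(max_re = r$rho[1], omega = r$omega[1], factor = r$factor[1])
}

#' Delay-independent sufficient stability test
#'
#' A symmetric equilibrium is asymptotically stable whenever
#' \eqn{|k_1| + |k_2| < 1}, for any delays.  The converse does not hold:
#' a `FALSE` result is inconclusive, since the true stability region
#' extends beyond this square up to the nearest bifurcation curve.
#'
#' @param k1,k2 linearization gains.
#' @return Logical.
#' @export
sufficient_stability <- function(k1, k2) abs(k1) + abs(k2) < 1

#' Frequency bound for imaginary-axis roots
#'
#' For \eqn{\omega_0 > 0}, the square
#' \eqn{|k_1| + |k_2| < \sqrt{1 + \omega_0^2}} contains no purely
#' imaginary characteristic roots \eqn{\pm i\omega} with
#' \eqn{\omega \ge \omega_0}.  Instabilities of the extended stability
#' region are therefore induced by low frequencies only, which caps the
#' frequency window that the boundary assembly must scan.
#'
#' @param k1,k2 linearization gains.
#' @param omega0 lower frequency bound (> 0).
#' @return `TRUE` if the gain pair lies inside the square for this
#'   `omega0` (hence excludes imaginary roots at or above it).
#' @export
frequency_bound <- function(k1, k2, omega0) {
  stopifnot(omega0 > 0)
  abs(k1) + abs(k2) < sqrt(1 + omega0^2)
}
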