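#' Equilibrium residual of the symmetric fixed-point equation
#'
#' All fixed points of the model are symmetric, \eqn{(x^*, x^*)}, and
#' solve the scalar equation
#' \deqn{g(x) = -x - \alpha_1 S(\beta_1 x) + \alpha_2 S(\beta_2 x) = 0.}
#'
#' @param x scalar activity (vectorized).
#' @param params a [pop_model()] object.
#' @return The residual `g(x)`.
#' @export
equilibrium_residual <- function(x, params) {
  -x - params$alpha1 * sigmoid_act(params$beta1 * x, params$a) +
    params$alpha2 * sigmoid_act(params$beta2 * x, params$a)
}

# closed-form inverse of the shifted tanh activation, with domain guard
sigmoid_act_inv <- function(y, a = 1) {
  u <- y / cosh(a)^2 - tanh(a)
  if (any(abs(u) >= 1)) stop("value outside the range of the activation")
  atanh(u) + a
}

# the self-consistency map H: fixed points satisfy x = H(x)
equilibrium_map_H <- function(x, params) {
  sigmoid_act_inv((x + params$alpha1 * sigmoid_act(params$beta1 * x, params$a)) /
                    params$alpha2, params$a) / params$beta2
}

#' Locate all symmetric equilibria
#'
#' Samples the scalar residual [equilibrium_residual()] on a grid over
#' `interval` and refines every sign change by bisection (to residual
#' magnitude below `tol`).  The origin is always a fixed point and is
#' always included.  Roots closer than `merge_tol` are merged.
#'
#' @param params a [pop_model()] object.
#' @param interval search interval for the activity level; the default
#'   covers all regimes arising for the delivered presets.
#' @param resolution number of grid points.
#' @param tol residual tolerance of the bisection refinement.
#' @param merge_tol duplicate-merge distance.
#' @return An object of class `"equilibria"`: data frame with columns
#'   `x_star`, `k1`, `k2`, `stable` (by [count_unstable_roots()]),
#'   sorted by `x_star`.
#' @export
find_equilibria <- function(params, interval = c(-2, 5), resolution = 2000,
                            tol = 1e-12, merge_tol = 1e-8) {
  stopifnot(resolution >= 2, diff(interval) > 0)
  xs <- seq(interval[1], interval[2], length.out = resolution)
  g <- equilibrium_residual(xs, params)
  roots <- 0
  flips <- which(diff(sign(g)) != 0)
  for (i in flips) {
    lo <- xs[i]; hi <- xs[i + 1]
    r <- stats::uniroot(equilibrium_residual, c(lo, hi),
                        params = params, tol = .Machine$double.eps)$root
    # secant polish in case uniroot stops at its x tolerance first
    for (it in 1:5) {
      g1 <- equilibrium_residual(r, params)
      if (abs(g1) < tol) break
      dg <- (equilibrium_residual(r + 1e-7, params) - g1) / 1e-7
      r <- r - g1 / dg
    }
    roots <- c(roots, r)
  }
  roots <- sort(roots)
  keep <- c(TRUE, diff(roots) > merge_tol)
  roots <- roots[keep]
  k <- t(vapply(roots, function(x) equilibrium_gains(params, x), c(k1 = 0, k2 = 0)))
  stable <- vapply(seq_along(roots), function(i)
    count_unstable_roots(k[i, 1], k[i, 2], params$tau1, params$tau2, "minus") +
      count_unstable_roots(k[i, 1], k[i, 2], params$tau1, params$tau2, "plus") == 0,
    TRUE)
  structure(data.frame(x_star = roots, k1 = k[, 1], k2 = k[, 2],
                       stable = stable),
            class = c("equilibria", "data.frame"), params = params)
}

#' Linearization gains at a symmetric equilibrium
#'
#' \deqn{k_1 = \alpha_1\beta_1 S'(\beta_1 x^*), \qquad
#'       k_2 = \alpha_2\beta_2 S'(\beta_2 x^*).}
#' Both are strictly positive; they are the natural coordinates of the
#' stability chart.
#'
#' @param params a [pop_model()] object.
#' @param x_star equilibrium activity level.
#' @return Named vector `c(k1, k2)`.
#' @export
equilibrium_gains <- function(params, x_star) {
  c(k1 = params$alpha1 * params$beta1 *
      sigmoid_act_deriv(params$beta1 * x_star, params$a),
    k2 = params$alpha2 * params$beta2 *
      sigmoid_act_deriv(params$beta2 * x_star, params$a))
}

# alpha2 parameterization of the nontrivial branch at fixed alpha1:
# g = 0 solved for alpha2 (x != 0)
branch_alpha2_of_x <- function(x, params) {
  (x + params$alpha1 * sigmoid_act(params$beta1 * x, params$a)) /
    sigmoid_act(params$beta2 * x, params$a)
}

#' Continue an equilibrium branch in one parameter
#'
#' Follows a branch of symmetric equilibria as one coupling parameter
#' varies, and detects the events along it: branch points (transcritical
#' intersections with the trivial branch), folds (turning points in the
#' free parameter, where \eqn{1 + k_1 - k_2 = 0}) and Hopf bifurcations
#' (imaginary-axis crossings monitored through the argument-principle
#' root count of each characteristic factor).  Events are refined by
#' bisection to parameter tolerance `ptol`.
#'
#' For the trivial branch (`trivial = TRUE`) the equilibrium is
#' identically zero, the gains are exactly linear in the parameters, and
#' the transcritical parameter value
#' \eqn{\alpha_2 = (1 + \alpha_1\beta_1)/\beta_2} is computed in closed
#' form.  A nontrivial branch at fixed `alpha1` is parameterized by its
#' activity level \eqn{x^*}, for which the excitation solves in closed
#' form: \eqn{\alpha_2(x) = (x + \alpha_1 S(\beta_1 x))/S(\beta_2 x)}.
#' This exact parameterization traverses folds without step-size control
#' and is used instead of pseudo-arclength steps; event bisection acts on
#' `x`.
#'
#' @param params a [pop_model()] object (`alpha2` entry ignored for the
#'   nontrivial branch; it is the branch parameter).
#' @param free free parameter, currently `"alpha2"`.
#' @param range for the trivial branch, the `alpha2` range; for a
#'   nontrivial branch, the range of the activity level `x_star`
#'   traversed.
#' @param n number of branch points sampled.
#' @param trivial continue the trivial branch instead of the nontrivial
#'   one.
#' @param ptol bisection tolerance for event refinement (in `x` or in
#'   `alpha2` for the trivial branch).
#' @return An object of class `"eq_branch"`: list with `points` (data
#'   frame `alpha2`, `x_star`, `k1`, `k2`, `n_unstable`) and `events`
#'   (data frame `type`, `factor`, `alpha2`, `x_star`, `omega`).
#' @export
equilibrium_branch <- function(params, free = "alpha2", range, n = 400,
                               trivial = FALSE, ptol = 1e-7) {
  stopifnot(free == "alpha2")
  tau1 <- params$tau1; tau2 <- params$tau2
  if (trivial) {
    a2 <- seq(range[1], range[2], length.out = n)
    k1 <- params$alpha1 * params$beta1
    pts <- data.frame(alpha2 = a2, x_star = 0, k1 = k1,
                      k2 = a2 * params$beta2)
    nu <- vapply(pts$k2, function(k2)
      winding_count(k1, k2, tau1, tau2, -1) +
        winding_count(k1, k2, tau1, tau2, 1), 0L)
    pts$n_unstable <- nu
    events <- refine_branch_events(
      function(x) x, function(x) c(k1, x * params$beta2),
      a2, nu, params, ptol)
    # closed-form transcritical crossing
    a2_bp <- (1 + params$alpha1 * params$beta1) / params$beta2
    if (a2_bp >= min(range) && a2_bp <= max(range))
      events <- rbind(events, data.frame(type = "branch-point",
                                         factor = "minus", alpha2 = a2_bp,
                                         x_star = 0, omega = 0))
  } else {
    xs <- seq(range[1], range[2], length.out = n)
    xs <- xs[abs(xs) > 1e-9]
    a2x <- function(x) branch_alpha2_of_x(x, params)
    gx <- function(x) {
      p2 <- params; p2$alpha2 <- a2x(x)
      equilibrium_gains(p2, x)
    }
    k <- t(vapply(xs, gx, c(0, 0)))
    pts <- data.frame(alpha2 = vapply(xs, a2x, 0), x_star = xs,
                      k1 = k[, 1], k2 = k[, 2])
    nu <- vapply(seq_along(xs), function(i)
      winding_count(k[i, 1], k[i, 2], tau1, tau2, -1) +
        winding_count(k[i, 1], k[i, 2], tau1, tau2, 1), 0L)
    pts$n_unstable <- nu
    events <- refine_branch_events(a2x, gx, xs, nu, params, ptol)
    # folds: zeros of the minus factor at lambda = 0 along the branch,
    # equivalently turning points of alpha2(x)
    fold_res <- function(x) { kk <- gx(x); 1 + kk[1] - kk[2] }
    fr <- vapply(xs, fold_res, 0)
    for (i in which(diff(sign(fr)) != 0)) {
      r <- stats::uniroot(fold_res, xs[c(i, i + 1)], tol = ptol)$root
      ev_type <- if (min(abs(xs[c(i, i + 1)])) < 1e-6) "branch-point" else "fold"
      events <- rbind(events, data.frame(type = ev_type, factor = "minus",
                                         alpha2 = a2x(r), x_star = r,
                                         omega = 0))
    }
  }
  events <- events[order(events$alpha2), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(points = pts, events = events, params = params,
                 trivial = trivial),
            class = "eq_branch")
}

# locate changes of the unstable-root count along a sampled branch and
# bisect them to parameter tolerance; Hopf events get their frequency
# from the purely imaginary root at the refined point
refine_branch_events <- function(a2_of, gains_of, s, nu, params, ptol) {
  tau1 <- params$tau1; tau2 <- params$tau2
  nu_of <- function(x) {
    k <- gains_of(x)
    c(winding_count(k[1], k[2], tau1, tau2, -1),
      winding_count(k[1], k[2], tau1, tau2, 1))
  }
  events <- data.frame(type = character(0), factor = character(0),
                       alpha2 = numeric(0), x_star = numeric(0),
                       omega = numeric(0))
  ch <- which(diff(nu) != 0)
  for (i in ch) {
    lo <- s[i]; hi <- s[i + 1]
    nlo <- nu_of(lo); nhi <- nu_of(hi)
    for (j in 1:2) {
      if (nlo[j] == nhi[j]) next
      d <- abs(nhi[j] - nlo[j])
      a <- lo; b <- hi; na <- nlo[j]
      while (abs(b - a) > ptol) {
        m <- (a + b) / 2
        nm <- nu_of(m)[j]
        if (nm != na) b <- m else a <- m
      }
      xev <- (a + b) / 2
      k <- gains_of(xev)
      fam <- c("minus", "plus")[j]
      if (d %% 2 == 0) {
        om <- hopf_frequency_at(k[1], k[2], tau1, tau2, fam)
        events <- rbind(events, data.frame(
          type = "hopf", factor = fam, alpha2 = a2_of(xev), x_star = xev,
          omega = om))
      }
      # odd changes are steady-state crossings, reported by the caller
    }
  }
  events
}

# frequency of the near-imaginary root of one factor at a Hopf point:
# scan |Delta(i*omega)| for local minima and polish the best with Newton
hopf_frequency_at <- function(k1, k2, tau1, tau2, family) {
  om_max <- sqrt(max((abs(k1) + abs(k2))^2 - 1, 0)) + 0.5
  oms <- seq(1e-3, om_max, length.out = 2000)
  v <- abs(char_factor(1i * oms, k1, k2, tau1, tau2, family))
  cand <- oms[which(diff(sign(diff(v))) > 0) + 1L]
  if (!length(cand)) return(NA_real_)
  best <- NA_real_; bestres <- Inf
  for (om0 in cand) {
    lam <- 1i * om0
    for (i in 1:40) {
      fv <- char_factor(lam, k1, k2, tau1, tau2, family)
      if (abs(fv) < 1e-13) break
      lam <- lam - fv / char_factor_deriv(lam, k1, k2, tau1, tau2, family)
    }
    if (abs(Re(lam)) < 1e-3 && abs(fv) < bestres) {
      best <- abs(Im(lam)); bestres <- abs(fv)
    }
  }
  best
}

#' @export
print.eq_branch <- function(x, ...) {
  cat(sprintf("Equilibrium branch (%s), %d points, alpha2 in [%.4g, %.4g]\n",
              if (x$trivial) "trivial" else "nontrivial",
              nrow(x$points), min(x$points$alpha2), max(x$points$alpha2)))
  if (nrow(x$events)) {
    cat("Events:\n")
    print(x$events, digits = 5)
  } else cat("No events detected.\n")
  invisible(x)
}

#' Locate codimension-two points of equilibria
#'
#' Finds parameter pairs \eqn{(\alpha_1, \alpha_2)} at which two
#' bifurcation conditions hold simultaneously at an equilibrium:
#' \describe{
#' \item{`"hopf-hopf"`}{both characteristic factors of the trivial
#'   equilibrium carry an imaginary root pair: the intersection of the
#'   two Hopf curves in the gain plane, mapped through
#'   [gains_to_alphas()].}
#' \item{`"transcritical-hopf"`}{the trivial equilibrium has a zero root
#'   (on the steady-state line) and an imaginary pair: the ZH vertex of
#'   the region, mapped likewise.}
#' \item{`"fold-hopf"`}{a nontrivial equilibrium satisfies the fold
#'   condition \eqn{1 + k_1 - k_2 = 0} while the antisymmetric factor
#'   carries an imaginary pair.  Solved as a simultaneous root of the
#'   equilibrium residual, the fold condition and
#'   \eqn{\Delta_+(i\omega) = 0} in \eqn{(\alpha_1, \alpha_2, x^*,
#'   \omega)} by damped Newton, seeded from `seed`.}
#' }
#'
#' @param params a [pop_model()] template (slopes, delays, activation).
#' @param kind which codimension-two point.
#' @param seed for `"fold-hopf"`: starting values, a list or named vector
#'   with `alpha1`, `alpha2`, `x_star`, `omega`.
#' @param region optionally a precomputed [stability_region()].
#' @return A list with `kind`, `alpha1`, `alpha2`, `x_star`, `omega`
#'   (`omega2` as well for `"hopf-hopf"`) and the residual norm.
#' @export
locate_codim2 <- function(params,
                          kind = c("hopf-hopf", "transcritical-hopf",
                                   "fold-hopf"),
                          seed = NULL, region = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("hopf-hopf", "transcritical-hopf")) {
    if (is.null(region))
      region <- stability_region(params$tau1, params$tau2)
    i <- if (kind == "hopf-hopf") 2 else 1
    k <- c(region$codim2$k1[i], region$codim2$k2[i])
    al <- gains_to_alphas(k[1], k[2], params)
    return(list(kind = kind, alpha1 = unname(al[1]), alpha2 = unname(al[2]),
                x_star = 0, omega = region$codim2$omega1[i],
                omega2 = region$codim2$omega2[i], residual = 0))
  }
  if (is.null(seed)) stop("fold-hopf location requires a seed")
  seed <- unlist(seed)
  z <- c(seed[["alpha1"]], seed[["alpha2"]], seed[["x_star"]], seed[["omega"]])
  F <- function(z) {
    p <- params; p$alpha1 <- z[1]; p$alpha2 <- z[2]
    k <- equilibrium_gains(p, z[3])
    dv <- char_factor(1i * z[4], k[1], k[2], p$tau1, p$tau2, "plus")
    c(equilibrium_residual(z[3], p), 1 + k[1] - k[2], Re(dv), Im(dv))
  }
  for (it in 1:100) {
    f0 <- F(z)
    if (sqrt(sum(f0^2)) < 1e-11) break
    J <- matrix(0, 4, 4)
    for (j in 1:4) {
      h <- 1e-8 * max(1, abs(z[j]))
      zp <- z; zp[j] <- zp[j] + h
      J[, j] <- (F(zp) - f0) / h
    }
    step <- solve(J, f0)
    lam <- 1
    repeat {
      zn <- z - lam * step
      if (sqrt(sum(F(zn)^2)) < sqrt(sum(f0^2)) || lam < 1e-4) break
      lam <- lam / 2
    }
    z <- zn
  }
  rn <- sqrt(sum(F(z)^2))
  if (rn > 1e-10) stop("fold-hopf Newton did not converge (residual ", rn, ")")
  list(kind = kind, alpha1 = z[1], alpha2 = z[2], x_star = z[3],
       omega = z[4], residual = rn)
}
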