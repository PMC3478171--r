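# Pseudo-arclength continuation of periodic orbits in alpha2, with
# Floquet-based event detection (period doubling, fold of cycles,
# Neimark-Sacker).

# corrector with an additional scalar constraint; z = (vec(U), T, alpha2)
correct_cycle_constrained <- function(z, params, ws, uref, constraint,
                                      tol = 1e-9, max_iter = 20) {
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    sys <- cycle_system(z, params, ws, uref, free_alpha2 = TRUE)
    cres <- constraint(z)
    res <- c(sys$res, cres$value)
    rn <- sqrt(mean(res^2))
    if (!is.finite(rn)) break
    if (rn < tol) { ok <- TRUE; break }
    J <- rbind(sys$J, cres$grad)
    step <- tryCatch(solve(J, res), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      zn <- z - lam * step
      r2 <- c(cycle_residual_only(zn, params, ws, uref, TRUE),
              constraint(zn)$value)
      rn2 <- sqrt(mean(r2^2))
      if (is.finite(rn2) && (rn2 < rn || lam < 1 / 16)) break
      lam <- lam / 2
    }
    z <- zn
  }
  list(z = z, converged = ok)
}

# start the cycle branch at a Hopf point: amplitude is prescribed and
# alpha2 released, which avoids collapse onto the equilibrium
start_cycle_branch <- function(params, omega, family = "symmetric",
                               x_star = 0, amplitude = 0.05, L = 40, m = 4) {
  seed <- hopf_cycle_seed(params, omega, amplitude, family, x_star, L, m)
  ws <- seed$ws
  planar <- !seed$symmetric
  uref <- make_uref(seed$U, ws, planar)
  z <- c(as.vector(seed$U), seed$T, params$alpha2)
  n <- if (planar) 2 else 1
  constraint <- function(z) {
    U <- matrix(z[1:(ws$Np * n)], ws$Np, n)
    val <- orbit_amplitude(U, ws) - amplitude
    # analytic gradient through the quadrature form of the amplitude
    grad <- numeric(length(z))
    W0 <- interp_matrix(ws, ws$sc)
    u <- W0 %*% U[, 1, drop = FALSE]
    mu <- sum(ws$wq * u)
    amp <- sqrt(2 * sum(ws$wq * (u - mu)^2))
    gu <- 2 * ws$wq * (u - mu) / amp          # d amp / d u(c)
    grad[1:ws$Np] <- as.vector(t(W0) %*% gu)
    list(value = val, grad = grad)
  }
  out <- correct_cycle_constrained(z, params, ws, uref, constraint)
  if (!out$converged) stop("Hopf branch start failed to converge")
  z <- out$z
  orb <- seed
  orb$U <- matrix(z[1:(ws$Np * n)], ws$Np, n)
  orb$T <- z[ws$Np * n + 1]
  orb$params$alpha2 <- z[ws$Np * n + 2]
  orb$converged <- TRUE
  orb
}

# classified multiplier tests for event detection
multiplier_tests <- function(mu) {
  i_triv <- which.min(Mod(mu - 1))
  nt <- mu[-i_triv]
  fac <- attr(mu, "factor")[-i_triv]
  realish <- abs(Im(nt)) < 1e-4 * pmax(1, Mod(nt))
  tests <- list()
  for (f in unique(fac)) {
    sel <- realish & fac == f & Re(nt) < 0
    tests[[paste0("pd_", f)]] <-
      if (any(sel)) min(Re(nt[sel])) + 1 else 1
  }
  cplx <- !realish
  tests$ns <- if (any(cplx)) max(Mod(nt[cplx])) - 1 else -1
  tests$stable <- max(Mod(nt)) < 1 + 1e-4
  tests$trivial_err <- Mod(mu[i_triv] - 1)
  tests
}

#' Continue a branch of periodic orbits in the excitation parameter
#'
#' Pseudo-arclength continuation of a periodic-orbit branch in `alpha2`,
#' monitoring Floquet multipliers at every accepted step.  Detected
#' events:
#' \describe{
#' \item{PD}{a real multiplier crosses \eqn{-1} (period doubling); for
#'   symmetric orbits the factor (symmetric/antisymmetric variational
#'   mode) is recorded — antisymmetric period doublings spawn asymmetric
#'   orbits;}
#' \item{LPC}{a fold of cycles: the branch turns around in `alpha2`;}
#' \item{NS}{a complex multiplier pair crosses the unit circle
#'   (Neimark-Sacker).}
#' }
#' Events are refined by bisection in arclength to `alpha2` tolerance
#' `event_tol`.  The branch terminates when `alpha2` leaves `range`,
#' when the orbit amplitude collapses (the branch closes in a Hopf
#' point), or after `max_steps` steps.
#'
#' @param orbit a converged starting `"periodic_orbit"` (e.g. from the
#'   Hopf starter used by [cycle_branch_from_hopf()]).
#' @param range `alpha2` interval over which to continue.
#' @param direction initial direction of `alpha2` (+1 or -1).
#' @param step initial arclength step (in the scaled continuation
#'   metric).
#' @param max_step,min_step step-size bounds.
#' @param max_steps step cap.
#' @param event_tol bisection tolerance for events (alpha2 scale).
#' @param amp_floor amplitude below which the branch is deemed to have
#'   closed in a Hopf point.  A steadily shrinking orbit below amplitude
#'   0.1 is also treated as Hopf closure, and a return of the branch to
#'   a previously visited point (within tight tolerances on `alpha2`,
#'   period and amplitude) terminates the run as a closed loop.
#' @param max_pd stop after this many period-doubling events (the
#'   default continues to the end of the branch).
#' @return An object of class `"cycle_branch"`: list with `points` (data
#'   frame `alpha2`, `T`, `amplitude`, `max_mod_nontrivial`, `stable`),
#'   `events` (data frame `type`, `factor`, `alpha2`, `T`), `orbits`
#'   (list of orbits at events), `last` (final orbit).
#' @export
continue_cycles <- function(orbit, range, direction = -1, step = 0.02,
                            max_step = 0.06, min_step = 1e-4,
                            max_steps = 400, event_tol = 5e-5,
                            amp_floor = 5e-3, max_pd = Inf) {
  ws <- orbit$ws
  planar <- !orbit$symmetric
  n <- if (planar) 2 else 1
  nz <- ws$Np * n + 2
  pscale <- 5                      # weight of alpha2 in the arclength metric
  zfun <- function(orb) c(as.vector(orb$U), orb$T, orb$params$alpha2)
  as_orbit <- function(z, template) {
    o <- template
    o$U <- matrix(z[1:(ws$Np * n)], ws$Np, n)
    o$T <- z[ws$Np * n + 1]
    o$params$alpha2 <- z[nz]
    o$converged <- TRUE
    o
  }
  metric <- function(dz) sqrt(sum(dz[1:(nz - 2)]^2) / ws$Np +
                                dz[nz - 1]^2 / 25 + (pscale * dz[nz])^2)
  z <- zfun(orbit)
  mu <- floquet_multipliers(orbit)
  tests <- multiplier_tests(mu)
  pts <- list(); evs <- list(); orbs <- list()
  record <- function(z, tests) {
    U <- matrix(z[1:(ws$Np * n)], ws$Np, n)
    data.frame(alpha2 = z[nz], T = z[nz - 1],
               amplitude = (max(U[, 1]) - min(U[, 1])) / 2,
               max_mod_nontrivial = NA_real_,
               stable = tests$stable, trivial_err = tests$trivial_err)
  }
  pts[[1]] <- record(z, tests)
  # initial tangent: vary alpha2
  tan_prev <- numeric(nz); tan_prev[nz] <- direction
  correct_at <- function(zpred, tang) {
    uref <- make_uref(matrix(zpred[1:(ws$Np * n)], ws$Np, n), ws, planar)
    constraint <- function(zz) {
      list(value = sum(tang * (zz - zpred)), grad = tang)
    }
    correct_cycle_constrained(zpred, orbit$params, ws, uref, constraint)
  }
  prev_tests <- tests
  z_prev <- z
  h <- step
  steps <- 0
  status <- "max_steps"
  while (steps < max_steps) {
    steps <- steps + 1
    zpred <- z + h * tan_prev / metric(tan_prev)
    out <- correct_at(zpred, tan_prev)
    if (!out$converged) {
      h <- h / 2
      if (h < min_step) { status <- "step_underflow"; break }
      next
    }
    zn <- out$z
    orbn <- as_orbit(zn, orbit)
    mun <- floquet_multipliers(orbn)
    tn <- multiplier_tests(mun)
    # events between z and zn
    for (nm in grep("^pd_", names(tn), value = TRUE)) {
      if (!is.null(prev_tests[[nm]]) &&
          sign(prev_tests[[nm]]) != sign(tn[[nm]])) {
        ev <- refine_event(z, zn, orbit, ws, planar, nm, correct_at,
                           event_tol)
        evs[[length(evs) + 1]] <- data.frame(
          type = "PD", factor = sub("pd_", "", nm),
          alpha2 = ev$alpha2, T = ev$T)
        orbs[[length(orbs) + 1]] <- ev$orbit
      }
    }
    if (sign(prev_tests$ns) != sign(tn$ns)) {
      ev <- refine_event(z, zn, orbit, ws, planar, "ns", correct_at,
                         event_tol)
      evs[[length(evs) + 1]] <- data.frame(
        type = "NS", factor = "", alpha2 = ev$alpha2, T = ev$T)
      orbs[[length(orbs) + 1]] <- ev$orbit
    }
    # LPC: fold in alpha2 (tangent reversal)
    tan_new <- zn - z
    if (steps > 1 && (z[nz] - z_prev[nz]) * (zn[nz] - z[nz]) < 0 &&
        abs(zn[nz] - z[nz]) < 0.05) {
      evs[[length(evs) + 1]] <- data.frame(
        type = "LPC", factor = "",
        alpha2 = z[nz], T = z[nz - 1])
      orbs[[length(orbs) + 1]] <- as_orbit(z, orbit)
    }
    z_prev <- z
    z <- zn
    tan_prev <- tan_new
    prev_tests <- tn
    pts[[length(pts) + 1]] <- record(zn, tn)
    # step control
    h <- min(max_step, h * 1.3)
    amp <- (max(zn[1:ws$Np]) - min(zn[1:ws$Np])) / 2
    if (amp < amp_floor) { status <- "hopf_closure"; break }
    np <- length(pts)
    if (amp < 0.1 && np > 8) {
      amps <- vapply(pts[(np - 8):np], function(d) d$amplitude, 0)
      if (all(diff(amps) < 0)) { status <- "hopf_closure"; break }
    }
    if (np > 20) {
      prior <- do.call(rbind, pts[1:(np - 15)])
      if (any(abs(prior$alpha2 - zn[nz]) < 2e-4 &
              abs(prior$T - zn[nz - 1]) < 2e-3 &
              abs(prior$amplitude - amp) < 2e-3)) {
        status <- "closed_loop"; break
      }
    }
    if (sum(vapply(evs, function(e) e$type == "PD", TRUE)) >= max_pd) {
      status <- "max_pd"; break
    }
    if (zn[nz] < range[1] || zn[nz] > range[2]) { status <- "range"; break }
  }
  structure(list(points = do.call(rbind, pts),
                 events = if (length(evs)) do.call(rbind, evs)
                          else data.frame(type = character(0),
                                          factor = character(0),
                                          alpha2 = numeric(0),
                                          T = numeric(0)),
                 orbits = orbs, last = as_orbit(z, orbit),
                 status = status),
            class = "cycle_branch")
}

# bisection refinement of a multiplier event bracketed by z0, z1
refine_event <- function(z0, z1, template, ws, planar, test_name,
                         correct_at, event_tol) {
  n <- if (planar) 2 else 1
  nz <- ws$Np * n + 2
  as_orbit <- function(z) {
    o <- template
    o$U <- matrix(z[1:(ws$Np * n)], ws$Np, n)
    o$T <- z[nz - 1]
    o$params$alpha2 <- z[nz]
    o$converged <- TRUE
    o
  }
  tval <- function(z) {
    tt <- multiplier_tests(floquet_multipliers(as_orbit(z)))
    if (test_name == "ns") tt$ns else tt[[test_name]]
  }
  f0 <- tval(z0)
  za <- z0; zb <- z1
  for (i in 1:30) {
    if (max(abs(zb[nz] - za[nz]), abs(zb[nz] - za[nz])) < event_tol &&
        i > 6) break
    zm_pred <- (za + zb) / 2
    tang <- zb - za
    out <- correct_at(zm_pred, tang)
    if (!out$converged) break
    zm <- out$z
    fm <- tval(zm)
    if (sign(fm) == sign(f0)) { za <- zm; f0 <- fm } else zb <- zm
  }
  zm <- (za + zb) / 2
  out <- correct_at(zm, zb - za)
  zr <- if (out$converged) out$z else zb
  o <- as_orbit(zr)
  list(alpha2 = zr[nz], T = zr[nz - 1], orbit = o)
}

#' Start and continue the cycle branch born at a Hopf bifurcation
#'
#' Convenience wrapper: corrects a small-amplitude orbit at the Hopf
#' point with the amplitude prescribed and the excitation released, then
#' hands over to [continue_cycles()].
#'
#' @param params a [pop_model()] at the Hopf point (its `alpha2` set to
#'   the Hopf value).
#' @param omega Hopf frequency.
#' @param family `"symmetric"` or `"asymmetric"`.
#' @param x_star bifurcating equilibrium level.
#' @param range,direction,... passed to [continue_cycles()].
#' @param amplitude starting amplitude.
#' @param L,m mesh resolution.
#' @return A `"cycle_branch"`.
#' @export
cycle_branch_from_hopf <- function(params, omega, family = "symmetric",
                                   x_star = 0, range, direction = -1,
                                   amplitude = 0.05, L = 40, m = 4, ...) {
  orb <- start_cycle_branch(params, omega, family, x_star, amplitude, L, m)
  continue_cycles(orb, range = range, direction = direction, ...)
}

#' @export
print.cycle_branch <- function(x, ...) {
  p <- x$points
  cat(sprintf("Cycle branch: %d steps, alpha2 in [%.4g, %.4g] (status: %s)\n",
              nrow(p), min(p$alpha2), max(p$alpha2), x$status))
  if (nrow(x$events)) {
    cat("Events:\n"); print(x$events, digits = 5)
  } else cat("No events detected.\n")
  invisible(x)
}

#' @export
plot.cycle_branch <- function(x, ...) {
  p <- x$points
  graphics::plot(p$alpha2, p$amplitude, type = "l", xlab = "alpha2",
                 ylab = "orbit amplitude", ...)
  st <- p$stable
  graphics::points(p$alpha2[st], p$amplitude[st], pch = 16, cex = 0.4)
  if (nrow(x$events))
    graphics::abline(v = x$events$alpha2, lty = 3, col = "gray")
  invisible(x)
}
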