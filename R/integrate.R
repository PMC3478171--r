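#' History function presets
#'
#' Four initial history functions on \eqn{[-\tau_2, 0]} that select the
#' four coexisting attractors of the multistable regime
#' (`alpha1 = 0.069`, `alpha2 = 0.55`, paper-default slopes and delays):
#' \describe{
#' \item{A}{constant `(0, 0.1)` — decays to the trivial steady state;}
#' \item{B}{constant `(1.5, 1.7)` — settles on the nontrivial steady
#'   state;}
#' \item{C}{`(1 + 1.2 sin(2*pi*t/15), 0.8 + 1.3 sin(2*pi*t/15))` —
#'   converges to the symmetric (in-phase) periodic solution;}
#' \item{D}{`(0.7 + 0.7 sin(pi*t/30), 0.6 - 0.9 sin(pi*t/30))` —
#'   converges to the asymmetric (anti-phase) periodic solution.}
#' }
#'
#' @param name one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return A function of time `t` (vectorized over a scalar `t`)
#'   returning the state pair, valid on `[-20.3, 0]`.
#' @export
history_preset <- function(name = c("A", "B", "C", "D")) {
  name <- match.arg(name)
  switch(name,
         A = function(t) c(0, 0.1),
         B = function(t) c(1.5, 1.7),
         C = function(t) c(1 + 1.2 * sin(2 * pi * t / 15),
                           0.8 + 1.3 * sin(2 * pi * t / 15)),
         D = function(t) c(0.7 + 0.7 * sin(pi * t / 30),
                           0.6 - 0.9 * sin(pi * t / 30)))
}

#' Integrate the model from a history function
#'
#' Simulates the full nonlinear two-population model forward from an
#' arbitrary continuous history on \eqn{[-\tau_2, 0]}.  Integration uses
#' the method of steps as implemented in [deSolve::dede()]: delayed
#' states are evaluated from the solver's interpolated past solution for
#' positive times and from the supplied history function for
#' nonpositive times.
#'
#' @param params a [pop_model()] object.
#' @param history a history function of time (as from
#'   [history_preset()]), or a length-2 numeric for a constant history.
#' @param t_end end time (> 0).
#' @param dt output grid spacing.
#' @param rtol,atol relative/absolute local error tolerances.
#' @return An object of class `"dde_trajectory"`: list with `times`,
#'   `x` (two-column matrix), `params`, `history`, and interpolants
#'   `xfun` (a function of `t` returning the state pair, valid on
#'   `[-tau2, t_end]`).
#' @export
integrate_dde <- function(params, history, t_end = 5000, dt = 0.25,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(t_end > 0, rtol > 0, atol > 0)
  if (is.numeric(history)) {
    h0 <- history
    history <- function(t) h0
  }
  p <- params
  deriv <- function(t, y, parms) {
    l1 <- if (t - p$tau1 <= 0) history(t - p$tau1) else deSolve::lagvalue(t - p$tau1)
    l2 <- if (t - p$tau2 <= 0) history(t - p$tau2) else deSolve::lagvalue(t - p$tau2)
    # freeze once the state has decayed far below any tolerance, to keep
    # exponential decay to the origin from underflowing the error weights
    if (max(abs(y), abs(l1), abs(l2)) < 1e-30) return(list(c(0, 0)))
    list(model_rhs(p, y, l1, l2))
  }
  times <- seq(0, t_end, by = dt)
  sol <- suppressWarnings(
    deSolve::dede(y = history(0), times = times, func = deriv,
                  parms = NULL, rtol = rtol, atol = atol))
  x <- unname(sol[, 2:3, drop = FALSE])
  tg <- sol[, 1]
  okrow <- is.finite(x[, 1]) & is.finite(x[, 2])
  x <- x[okrow, , drop = FALSE]; tg <- tg[okrow]
  if (length(tg) < length(times)) {
    # the solver stops early when the state decays so far below the
    # error weights that the step norms underflow; from there on the
    # solution is numerically indistinguishable from the equilibrium
    last <- x[nrow(x), ]
    if (max(abs(last)) < 1e-6) {
      extra <- times[times > max(tg)]
      x <- rbind(x, matrix(last, length(extra), 2, byrow = TRUE))
      tg <- c(tg, extra)
    } else {
      stop("integration stopped early at t = ", max(tg))
    }
  }
  f1 <- stats::splinefun(tg, x[, 1], method = "fmm")
  f2 <- stats::splinefun(tg, x[, 2], method = "fmm")
  xfun <- function(t) {
    if (length(t) == 1 && t <= 0) return(history(t))
    cbind(f1(t), f2(t))
  }
  structure(list(times = tg, x = x, params = params, history = history,
                 xfun = xfun, rtol = rtol, atol = atol),
            class = "dde_trajectory")
}

#' @export
print.dde_trajectory <- function(x, ...) {
  cat(sprintf("DDE trajectory: t in [0, %g], %d output points\n",
              max(x$times), length(x$times)))
  cat(sprintf("  final state: (%.6g, %.6g)\n",
              x$x[nrow(x$x), 1], x$x[nrow(x$x), 2]))
  invisible(x)
}

#' @export
plot.dde_trajectory <- function(x, from = 0, ...) {
  i <- x$times >= from
  graphics::matplot(x$times[i], x$x[i, ], type = "l", lty = c(1, 2),
                    col = c("black", "red"), xlab = "t",
                    ylab = "activity", ...)
  graphics::legend("topright", c("x1", "x2"), lty = c(1, 2),
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Classify the limiting attractor of a trajectory
#'
#' Inspects the post-transient part of a trajectory and assigns one of
#' five classes: `trivial_equilibrium`, `nontrivial_equilibrium`,
#' `symmetric_cycle` (in-phase, \eqn{x_1 \equiv x_2}),
#' `asymmetric_cycle` (anti-phase, \eqn{x_1(t) = x_2(t + T/2)}), or
#' `unclassified`.  A trajectory is steady when its post-transient
#' amplitude falls below `steady_tol`, trivial when additionally its mean
#' magnitude does.  For oscillations the period is estimated from the
#' autocorrelation of \eqn{x_1} with parabolic refinement of the peak,
#' and the symmetry class from the in-phase and anti-phase residuals
#' relative to the orbit amplitude.
#'
#' @param traj a [integrate_dde()] trajectory.
#' @param transient time to discard.
#' @param steady_tol amplitude threshold for steadiness.
#' @param sym_tol symmetry residual threshold (relative to amplitude).
#' @return A list with `class`, `period`, `amplitude`, `residuals`
#'   (named: `inphase`, `antiphase`, relative).
#' @export
classify_attractor <- function(traj, transient = 4000, steady_tol = 1e-5,
                               sym_tol = 1e-3) {
  i <- traj$times >= transient
  if (sum(i) < 100) stop("observation window too short after transient")
  t <- traj$times[i]
  x1 <- traj$x[i, 1]; x2 <- traj$x[i, 2]
  amp <- max(max(x1) - min(x1), max(x2) - min(x2)) / 2
  if (amp < steady_tol) {
    cls <- if (max(abs(c(x1, x2))) < steady_tol) "trivial_equilibrium"
           else "nontrivial_equilibrium"
    return(list(class = cls, period = NA_real_, amplitude = amp,
                residuals = c(inphase = NA_real_, antiphase = NA_real_)))
  }
  per <- estimate_period(t, x1)
  if (is.na(per))
    return(list(class = "unclassified", period = NA_real_, amplitude = amp,
                residuals = c(inphase = NA_real_, antiphase = NA_real_)))
  dt <- t[2] - t[1]
  r_in <- max(abs(x1 - x2)) / (2 * amp)
  # anti-phase residual: compare x1(t) with x2(t + T/2) via shift
  half <- round(per / 2 / dt)
  n <- length(x1)
  idx <- seq_len(n - half)
  r_anti <- max(abs(x1[idx] - x2[idx + half])) / (2 * amp)
  cls <- if (r_in < sym_tol) "symmetric_cycle"
         else if (r_anti < max(sym_tol, 0.02)) "asymmetric_cycle"
         else "unclassified"
  list(class = cls, period = per, amplitude = amp,
       residuals = c(inphase = r_in, antiphase = r_anti))
}

# period from the autocorrelation of the mean-removed signal, first
# non-initial maximum refined by parabolic interpolation
estimate_period <- function(t, x) {
  dt <- t[2] - t[1]
  x <- x - mean(x)
  n <- length(x)
  maxlag <- floor(n / 3)
  ac <- stats::acf(x, lag.max = maxlag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  # first local max after the initial decay
  dec <- which(diff(ac) > 0)
  if (!length(dec)) return(NA_real_)
  start <- dec[1]
  seg <- ac[start:length(ac)]
  pk <- which.max(seg) + start - 1L
  if (pk <= 2 || pk >= length(ac)) return(NA_real_)
  a <- ac[pk - 1]; b <- ac[pk]; c <- ac[pk + 1]
  denom <- a - 2 * b + c
  shift <- if (abs(denom) > 1e-14) 0.5 * (a - c) / denom else 0
  (pk - 1 + shift) * dt
}
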