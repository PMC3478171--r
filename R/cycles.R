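#' Small-amplitude periodic-orbit seed at a Hopf point
#'
#' Builds the harmonic initial guess
#' \eqn{x(s) = x^* + \epsilon\,\mathrm{Re}(e^{2\pi i s} p)} with period
#' \eqn{T = 2\pi/\omega}, where the eigenvector is \eqn{p = (1,1)} for
#' the symmetric (in-phase) family and \eqn{p = (1,-1)} for the
#' asymmetric (anti-phase) family.
#'
#' @param params a [pop_model()] object at the Hopf parameter values.
#' @param omega Hopf frequency.
#' @param amplitude seed amplitude \eqn{\epsilon}.
#' @param family `"symmetric"` or `"asymmetric"`.
#' @param x_star equilibrium activity the orbit bifurcates from.
#' @param L,m mesh intervals and collocation degree.
#' @return An (uncorrected) object of class `"periodic_orbit"`.
#' @export
hopf_cycle_seed <- function(params, omega, amplitude = 1e-2,
                            family = c("symmetric", "asymmetric"),
                            x_star = 0, L = 40, m = 4) {
  family <- match.arg(family)
  ws <- colloc_setup(L, m)
  s <- seq(0, 1, length.out = ws$Np)
  base <- x_star + amplitude * cos(2 * pi * s)
  U <- if (family == "symmetric") matrix(base, ncol = 1)
       else cbind(base, x_star - amplitude * cos(2 * pi * s))
  structure(list(U = U, T = 2 * pi / omega, params = params, ws = ws,
                 symmetric = family == "symmetric", converged = FALSE,
                 residual = NA_real_),
            class = "periodic_orbit")
}

#' Newton correction of a periodic orbit
#'
#' Solves the periodic collocation boundary-value problem by a damped
#' Newton iteration: profile and period are unknowns, an integral phase
#' condition against the previous profile's derivative removes the
#' translation degeneracy, and delayed phases are wrapped by whole
#' periods as needed.  Symmetric (in-phase) orbits are corrected inside
#' the invariant diagonal subspace, where the dynamics reduce to a
#' scalar equation; asymmetric orbits use the full planar problem.
#'
#' @param orbit a `"periodic_orbit"` (seed or converged).
#' @param params optionally, parameter values overriding those stored in
#'   the orbit (used when stepping in a parameter).
#' @param tol residual norm tolerance.
#' @param max_iter Newton iteration cap.
#' @param quiet suppress the non-convergence error, returning the
#'   unconverged orbit with `converged = FALSE`.
#' @return The corrected `"periodic_orbit"` with fields `U` (profile
#'   values on the representation grid), `T` (period), `multipliers`
#'   (empty until [floquet_multipliers()] is called), `residual`.
#' @export
correct_cycle <- function(orbit, params = NULL, tol = 1e-9, max_iter = 25,
                          quiet = FALSE) {
  p <- if (is.null(params)) orbit$params else params
  ws <- orbit$ws
  planar <- !orbit$symmetric
  Uref <- make_uref(orbit$U, ws, planar)
  z <- c(as.vector(orbit$U), orbit$T)
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    sys <- cycle_system(z, p, ws, Uref)
    rn <- sqrt(mean(sys$res^2))
    if (!is.finite(rn)) break
    if (rn < tol) { ok <- TRUE; break }
    step <- tryCatch(solve(sys$J, sys$res), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      zn <- z - lam * step
      rn2 <- sqrt(mean(cycle_residual_only(zn, p, ws, Uref)^2))
      if (is.finite(rn2) && (rn2 < rn || lam < 1 / 16)) break
      lam <- lam / 2
    }
    z <- zn
    if (zn[length(zn)] < 10 / (ws$L * ws$m)) break    # period collapse
  }
  n <- if (planar) 2 else 1
  out <- orbit
  out$U <- matrix(z[1:(ws$Np * n)], ws$Np, n)
  out$T <- z[ws$Np * n + 1]
  out$params <- p
  out$converged <- ok
  out$residual <- sqrt(mean(cycle_residual_only(z, p, ws,
                                                make_uref(out$U, ws, planar))^2))
  if (!ok && !quiet) stop("cycle correction did not converge (residual ",
                          format(out$residual), ")")
  out
}

#' @export
print.periodic_orbit <- function(x, ...) {
  amp <- apply(x$U, 2, function(u) (max(u) - min(u)) / 2)
  cat(sprintf("Periodic orbit (%s family)%s\n",
              if (x$symmetric) "symmetric" else "asymmetric",
              if (x$converged) "" else "  [NOT converged]"))
  cat(sprintf("  alpha2 = %.6g, period T = %.6g, amplitude = %s\n",
              x$params$alpha2, x$T,
              paste(sprintf("%.4g", amp), collapse = ", ")))
  if (!is.null(x$multipliers))
    cat("  leading multipliers:",
        paste(sprintf("%.5g%+.5gi", Re(x$multipliers), Im(x$multipliers)),
              collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a periodic orbit profile
#'
#' @param orbit a converged `"periodic_orbit"`.
#' @param s phases in \[0, 1) (wrapped).
#' @return Matrix of state values (two columns; symmetric orbits are
#'   expanded to the plane).
#' @export
cycle_profile <- function(orbit, s) {
  M <- interp_matrix(orbit$ws, s)
  U <- M %*% orbit$U
  if (orbit$symmetric) cbind(U, U) else U
}

# non-wrapping interpolation rows on the [0,1] representation grid
interp_rows_clamped <- function(ws, s) {
  s <- pmin(pmax(s, 0), 1)
  M <- matrix(0, length(s), ws$Np)
  iv <- pmin(floor(s * ws$L), ws$L - 1)
  u <- s * ws$L - iv
  lv <- lagrange_vals(u, ws$m)
  for (r in seq_along(s)) M[r, iv[r] * ws$m + 1:(ws$m + 1)] <- lv$V[r, ]
  M
}

# monodromy matrix of the linearization about a cycle for one scalar
# variational factor (symmetric orbits; sign = +1 symmetric modes,
# -1 antisymmetric modes), or the full planar variational system.
monodromy_matrix <- function(orbit, sign_lag2 = 1, planar = FALSE) {
  ws <- orbit$ws; p <- orbit$params
  T <- orbit$T
  nu1 <- p$tau1 / T; nu2 <- p$tau2 / T
  nuh <- nu2                     # longest delay fixes the segment length
  Lh <- max(4, ceiling(nuh * ws$L))
  mh <- ws$m
  wsh <- colloc_setup(Lh, mh)    # history mesh mapped onto [-nuh, 0]
  Mh <- wsh$Np
  # coefficients on the known cycle (periodic interpolation)
  xl1 <- as.vector(interp_matrix(ws, ws$sc - nu1) %*% orbit$U[, 1])
  xl2 <- as.vector(interp_matrix(ws, ws$sc - nu2) %*% orbit$U[, 1])
  a1c <- -p$alpha1 * p$beta1 * sigmoid_act_deriv(p$beta1 * xl1, p$a)
  a2c <- p$alpha2 * p$beta2 * sigmoid_act_deriv(p$beta2 * xl2, p$a)
  hist_rows <- function(q) {      # q in [-nuh, 0]
    interp_rows_clamped(wsh, (q + nuh) / nuh)
  }
  nc <- ws$ncol
  eval_rows <- function(s) {
    # rows over c(V grid (Np), H grid (Mh)) for phases s in [-nuh, 1]
    MV <- matrix(0, length(s), ws$Np)
    MH <- matrix(0, length(s), Mh)
    pos <- s >= 0
    if (any(pos)) MV[pos, ] <- interp_rows_clamped(ws, s[pos])
    if (any(!pos)) MH[!pos, ] <- hist_rows(s[!pos])
    cbind(MV, MH)
  }
  D0 <- interp_matrix(ws, ws$sc, deriv = TRUE)
  V0 <- interp_rows_clamped(ws, ws$sc)
  E1 <- eval_rows(ws$sc - nu1)
  E2 <- eval_rows(ws$sc - nu2)
  if (!planar) {
    s2 <- sign_lag2
    Mfull <- cbind(D0, matrix(0, nc, Mh)) +
      T * cbind(V0, matrix(0, nc, Mh)) -
      T * a1c * E1 - T * s2 * a2c * E2
    A <- Mfull[, 2:ws$Np]
    B <- -Mfull[, c(ws$Np + 1:Mh)]
    B[, Mh] <- B[, Mh] - Mfull[, 1]     # v(0) = last history value
    Vsol_map <- solve(A, B)             # V2 = map %*% H
    # output segment sampled at the history mesh's representation points
    qh <- -nuh + nuh * rep_points(wsh)
    Rfull <- eval_rows(1 + qh)
    RV <- Rfull[, 1:ws$Np]; RH <- Rfull[, ws$Np + 1:Mh]
    Mono <- RV[, 2:ws$Np] %*% Vsol_map + RH
    Mono[, Mh] <- Mono[, Mh] + RV[, 1]
    return(Mono)
  }
  # planar variational system: components couple through the long delay
  xl1b <- as.vector(interp_matrix(ws, ws$sc - nu1) %*% orbit$U[, 2])
  xl2b <- as.vector(interp_matrix(ws, ws$sc - nu2) %*% orbit$U[, 2])
  a1c2 <- -p$alpha1 * p$beta1 * sigmoid_act_deriv(p$beta1 * xl1b, p$a)
  a2c2 <- p$alpha2 * p$beta2 * sigmoid_act_deriv(p$beta2 * xl2b, p$a)
  Z <- function(M) matrix(0, nrow(M), ncol(M))
  # component 1's long-delay term reads component 2 (coefficient from the
  # second component's lagged profile) and vice versa
  row1 <- cbind(cbind(D0, matrix(0, nc, Mh)) + T * cbind(V0, matrix(0, nc, Mh)) -
                  T * a1c * E1, -T * a2c2 * E2)
  row2 <- cbind(-T * a2c * E2,
                cbind(D0, matrix(0, nc, Mh)) + T * cbind(V0, matrix(0, nc, Mh)) -
                  T * a1c2 * E1)
  nV <- ws$Np; cols_V <- function(comp) (comp - 1) * (nV + Mh) + 1:nV
  cols_H <- function(comp) (comp - 1) * (nV + Mh) + nV + 1:Mh
  Mfull <- rbind(row1, row2)
  vc <- c(cols_V(1), cols_V(2)); hc <- c(cols_H(1), cols_H(2))
  first <- c(cols_V(1)[1], cols_V(2)[1])
  keepV <- setdiff(vc, first)
  A <- Mfull[, keepV]
  B <- -Mfull[, hc]
  B[, Mh] <- B[, Mh] - Mfull[, first[1]]
  B[, 2 * Mh] <- B[, 2 * Mh] - Mfull[, first[2]]
  Vsol_map <- solve(A, B)
  qh <- -nuh + nuh * rep_points(wsh)
  Rf <- eval_rows(1 + qh)
  RV <- Rf[, 1:nV]; RH <- Rf[, nV + 1:Mh]
  zr <- matrix(0, nrow(RV), ncol(RV)); zh <- matrix(0, nrow(RH), ncol(RH))
  RVb <- rbind(cbind(RV[, 2:nV], zr[, 2:nV]), cbind(zr[, 2:nV], RV[, 2:nV]))
  RHb <- rbind(cbind(RH, zh), cbind(zh, RH))
  Mono <- RVb %*% Vsol_map + RHb
  Mono[, Mh] <- Mono[, Mh] + c(RV[, 1], zr[, 1])
  Mono[, 2 * Mh] <- Mono[, 2 * Mh] + c(zr[, 1], RV[, 1])
  Mono
}

# representation points of a collocation workspace on [0, 1]
rep_points <- function(ws) {
  as.vector(c(outer((0:(ws$m - 1)) / ws$m / ws$L, (0:(ws$L - 1)) / ws$L, `+`), 1))
}

#' Floquet multipliers of a periodic orbit
#'
#' Computes the leading eigenvalues of the linearized return map over one
#' period.  The variational equation about the orbit is discretized with
#' the same collocation structure as the orbit itself; the resulting
#' linear map takes the solution segment over one delay interval to the
#' segment one period later, and its spectrum approximates the Floquet
#' multipliers.  For symmetric orbits the variational problem decouples
#' into a symmetric and an antisymmetric scalar factor (multipliers are
#' returned with a `factor` attribute); for asymmetric orbits the full
#' planar problem is solved.  The trivial multiplier 1 is always present
#' and its numerical deviation from 1 is a resolution diagnostic.
#'
#' @param orbit a converged `"periodic_orbit"`.
#' @param count number of leading multipliers to return.
#' @return Complex vector of multipliers sorted by decreasing modulus,
#'   with attribute `factor` (`"symmetric"`/`"antisymmetric"`/`"planar"`
#'   per multiplier).
#' @export
floquet_multipliers <- function(orbit, count = 12) {
  stopifnot(orbit$converged)
  if (orbit$symmetric) {
    ms <- eigen(monodromy_matrix(orbit, 1), only.values = TRUE)$values
    ma <- eigen(monodromy_matrix(orbit, -1), only.values = TRUE)$values
    mu <- c(ms, ma)
    fac <- c(rep("symmetric", length(ms)), rep("antisymmetric", length(ma)))
  } else {
    mu <- eigen(monodromy_matrix(orbit, planar = TRUE),
                only.values = TRUE)$values
    fac <- rep("planar", length(mu))
  }
  o <- order(-Mod(mu))[seq_len(min(count, length(mu)))]
  structure(mu[o], factor = fac[o])
}

# orbit L2 amplitude (used by the Hopf branch starter)
orbit_amplitude <- function(U, ws) {
  W0 <- interp_matrix(ws, ws$sc)
  u <- W0 %*% U[, 1, drop = FALSE]
  mu <- sum(ws$wq * u)
  sqrt(2 * sum(ws$wq * (u - mu)^2))
}
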