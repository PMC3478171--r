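# Piecewise-polynomial collocation infrastructure for periodic solutions
# of the two-delay model.  Periodic orbits are represented on the unit
# phase circle: L uniform mesh intervals, degree-m Lagrange polynomials
# on uniform representation points within each interval, collocation at
# the m Gauss-Legendre nodes of each interval.  The period T is an
# unknown; delayed phases s - tau/T are wrapped by as many whole periods
# as needed (the long delay may exceed one period).

# Gauss-Legendre nodes/weights on [0, 1]
gauss01 <- function(m) {
  # Golub-Welsch on the Jacobi matrix
  if (m == 1) return(list(x = 0.5, w = 1))
  b <- (1:(m - 1)) / sqrt(4 * (1:(m - 1))^2 - 1)
  J <- diag(0, m)
  J[cbind(1:(m - 1), 2:m)] <- b
  J[cbind(2:m, 1:(m - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = (e$values + 1) / 2, w = 2 * (e$vectors[1, ])^2 / 2)
}

# Lagrange basis values and derivatives at points u in [0,1] for nodes
# j/m, j = 0..m
lagrange_vals <- function(u, m) {
  nodes <- (0:m) / m
  V <- matrix(0, length(u), m + 1)
  Dv <- matrix(0, length(u), m + 1)
  for (j in 0:m) {
    others <- nodes[-(j + 1)]
    denom <- prod(nodes[j + 1] - others)
    for (ii in seq_along(u)) {
      diffs <- u[ii] - others
      V[ii, j + 1] <- prod(diffs) / denom
      s <- 0
      for (k in seq_along(others)) s <- s + prod(diffs[-k])
      Dv[ii, j + 1] <- s / denom
    }
  }
  list(V = V, D = Dv)
}

# collocation workspace for a mesh (L intervals, degree m)
colloc_setup <- function(L = 40, m = 4) {
  g <- gauss01(m)
  Np <- L * m + 1
  # collocation phases
  sc <- as.vector(outer(g$x / L, (0:(L - 1)) / L, `+`))
  list(L = L, m = m, Np = Np, ncol = L * m, sc = sc,
       wq = rep(g$w / L, L), gx = g$x)
}

# interpolation matrix: rows give u(s) at phases s (wrapped onto [0,1))
# as linear combinations of the Np profile values
interp_matrix <- function(ws, s, deriv = FALSE) {
  L <- ws$L; m <- ws$m; Np <- ws$Np
  s <- s - floor(s)
  s[s > 1 - 1e-13] <- 0
  iv <- pmin(floor(s * L), L - 1)
  u <- s * L - iv
  M <- matrix(0, length(s), Np)
  lv <- lagrange_vals(u, m)
  B <- if (deriv) lv$D * L else lv$V
  for (r in seq_along(s)) {
    cols <- iv[r] * m + 1:(m + 1)
    M[r, cols] <- B[r, ]
  }
  M
}

# rhs and partial derivatives of the model in symmetric-subspace (scalar)
# or full planar form.  sign_lag2 = -1 gives the antisymmetric
# variational coefficient for symmetric orbits.
cycle_rhs <- function(params, now, l1, l2, planar) {
  a <- params$a
  if (!planar)
    return(-now - params$alpha1 * sigmoid_act(params$beta1 * l1, a) +
             params$alpha2 * sigmoid_act(params$beta2 * l2, a))
  cbind(-now[, 1] - params$alpha1 * sigmoid_act(params$beta1 * l1[, 1], a) +
          params$alpha2 * sigmoid_act(params$beta2 * l2[, 2], a),
        -now[, 2] - params$alpha1 * sigmoid_act(params$beta1 * l1[, 2], a) +
          params$alpha2 * sigmoid_act(params$beta2 * l2[, 1], a))
}

# residual and Jacobian of the periodic collocation system.
# z = c(vec(U), T [, alpha2]); returns list(res, J)
cycle_system <- function(z, params, ws, uref, free_alpha2 = FALSE,
                         extra = NULL) {
  planar <- attr(uref, "planar")
  n <- if (planar) 2 else 1
  Np <- ws$Np; nc <- ws$ncol
  U <- matrix(z[1:(Np * n)], Np, n)
  T <- z[Np * n + 1]
  p <- params
  if (free_alpha2) p$alpha2 <- z[Np * n + 2]
  nu1 <- p$tau1 / T; nu2 <- p$tau2 / T
  W0 <- interp_matrix(ws, ws$sc)
  D  <- interp_matrix(ws, ws$sc, deriv = TRUE)
  W1 <- interp_matrix(ws, ws$sc - nu1)
  W2 <- interp_matrix(ws, ws$sc - nu2)
  u0 <- W0 %*% U; u1 <- W1 %*% U; u2 <- W2 %*% U
  f <- cycle_rhs(p, u0, u1, u2, planar)
  res_c <- D %*% U - T * f
  # periodicity and phase condition
  res_per <- U[Np, ] - U[1, ]
  dref <- attr(uref, "dref")      # derivative of reference at colloc pts
  res_phase <- sum(ws$wq * rowSums((W0 %*% U) * dref))
  res <- c(as.vector(res_c), res_per, res_phase)

  # analytic Jacobian wrt U; numeric wrt T (and alpha2)
  a <- p$a
  dS1 <- -p$alpha1 * p$beta1 * sigmoid_act_deriv(p$beta1 * u1, a)
  dS2 <- p$alpha2 * p$beta2 * sigmoid_act_deriv(p$beta2 * u2, a)
  nun <- Np * n
  J <- matrix(0, length(res), nun + 1 + free_alpha2)
  for (ci in 1:n) {
    rows <- (ci - 1) * nc + 1:nc
    colsci <- (ci - 1) * Np + 1:Np
    blk <- D + T * W0 - T * dS1[, ci] * W1
    J[rows, colsci] <- J[rows, colsci] + blk
    cj <- if (planar) 3 - ci else ci      # excitation couples across
    colscj <- (cj - 1) * Np + 1:Np
    J[rows, colscj] <- J[rows, colscj] - T * dS2[, cj] * W2
  }
  for (ci in 1:n) {
    r <- n * nc + ci
    J[r, (ci - 1) * Np + 1] <- -1
    J[r, ci * Np] <- 1
  }
  for (ci in 1:n)
    J[n * nc + n + 1, (ci - 1) * Np + 1:Np] <-
      (ws$wq * dref[, ci]) %*% W0
  # numeric columns for T (interpolation stencils move with T); central
  # differences keep the column error below the Newton tolerance
  fd_col <- function(j) {
    h <- 1e-6 * max(1, abs(z[j]))
    zp <- z; zp[j] <- zp[j] + h
    zm <- z; zm[j] <- zm[j] - h
    (cycle_residual_only(zp, params, ws, uref, free_alpha2) -
       cycle_residual_only(zm, params, ws, uref, free_alpha2)) / (2 * h)
  }
  J[, nun + 1] <- fd_col(nun + 1)
  if (free_alpha2) J[, nun + 2] <- fd_col(nun + 2)
  list(res = res, J = J)
}

cycle_residual_only <- function(z, params, ws, uref, free_alpha2 = FALSE) {
  planar <- attr(uref, "planar")
  n <- if (planar) 2 else 1
  Np <- ws$Np
  U <- matrix(z[1:(Np * n)], Np, n)
  T <- z[Np * n + 1]
  p <- params
  if (free_alpha2) p$alpha2 <- z[Np * n + 2]
  nu1 <- p$tau1 / T; nu2 <- p$tau2 / T
  W0 <- interp_matrix(ws, ws$sc)
  D  <- interp_matrix(ws, ws$sc, deriv = TRUE)
  W1 <- interp_matrix(ws, ws$sc - nu1)
  W2 <- interp_matrix(ws, ws$sc - nu2)
  f <- cycle_rhs(p, W0 %*% U, W1 %*% U, W2 %*% U, planar)
  res_c <- D %*% U - T * f
  res_per <- U[Np, ] - U[1, ]
  dref <- attr(uref, "dref")
  res_phase <- sum(ws$wq * rowSums((W0 %*% U) * dref))
  c(as.vector(res_c), res_per, res_phase)
}

# reference profile (for the integral phase condition) from a profile
# matrix U: stores its collocation-point derivative
make_uref <- function(U, ws, planar) {
  D <- interp_matrix(ws, ws$sc, deriv = TRUE)
  dref <- D %*% U
  structure(U, dref = dref, planar = planar)
}
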