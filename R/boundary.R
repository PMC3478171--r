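#' Hopf bifurcation curves in the gain plane
#'
#' Purely imaginary characteristic roots \eqn{\pm i\omega} of a factor
#' occur on a curve in the \eqn{(k_1,k_2)} gain plane obtained by solving
#' the 2x2 linear system formed by the real and imaginary parts of
#' \eqn{\Delta_\pm(i\omega) = 0}:
#' \deqn{k_1 = -\frac{\sin(\omega\tau_2) + \omega\cos(\omega\tau_2)}
#'                  {\sin(\omega(\tau_2-\tau_1))}, \qquad
#'       k_2 = \mp\frac{\sin(\omega\tau_1) + \omega\cos(\omega\tau_1)}
#'                  {\sin(\omega(\tau_2-\tau_1))},}
#' the upper sign for the minus (symmetric) family, the lower for the plus
#' (antisymmetric) family.  The curves consist of branches separated by
#' the asymptotes \eqn{\omega = n\pi/(\tau_2-\tau_1)}, where the linear
#' system degenerates.
#'
#' @param omega Hopf frequency (> 0, vectorized).
#' @param tau1,tau2 the two delays.
#' @param family `"minus"` (symmetric modes) or `"plus"` (antisymmetric).
#' @param tol asymptote guard: error if
#'   `|sin(omega*(tau2-tau1))| < tol`.
#' @return A data frame with columns `omega`, `k1`, `k2`, `family` and the
#'   branch index `branch` (count of asymptotes below `omega`).
#' @export
hopf_curve <- function(omega, tau1, tau2, family = c("minus", "plus"),
                       tol = 1e-10) {
  family <- match.arg(family)
  dt <- tau2 - tau1
  s <- sin(omega * dt)
  if (any(abs(s) < tol))
    stop("omega too close to an asymptote n*pi/(tau2 - tau1)")
  k1 <- -(sin(omega * tau2) + omega * cos(omega * tau2)) / s
  k2g <- (sin(omega * tau1) + omega * cos(omega * tau1)) / s
  k2 <- if (family == "plus") k2g else -k2g
  data.frame(omega = omega, k1 = k1, k2 = k2, family = family,
             branch = floor(omega * dt / pi))
}

#' Degenerate Hopf lines
#'
#' At frequencies where \eqn{\omega = -\tan(\omega\tau_1)
#' = -\tan(\omega\tau_2)} simultaneously, the 2x2 system defining the Hopf
#' curves degenerates and a whole line
#' \eqn{k_1 + \sigma k_2 = -1/\cos(\omega\tau_1)} of gain pairs carries
#' roots \eqn{\pm i\omega}.  For generic delay pairs no such frequency
#' exists; this scan reports exact solutions in the window together with
#' near-misses and their residuals.
#'
#' @param tau1,tau2 the two delays.
#' @param omega_max upper end of the scanned frequency window.
#' @param tol residual tolerance for an exact simultaneous solution.
#' @return A list with `lines` (data frame: `omega`, `sigma`, `intercept`,
#'   one row per exact solution; zero rows for generic delays) and
#'   `near_misses` (data frame of local minima of the combined residual
#'   with columns `omega`, `residual`).
#' @export
degenerate_hopf_lines <- function(tau1, tau2, omega_max = 5, tol = 1e-10) {
  res <- function(om) abs(om + tan(om * tau1)) + abs(om + tan(om * tau2))
  om <- seq(1e-4, omega_max, length.out = 20000)
  r <- res(om)
  loc <- which(diff(sign(diff(r))) > 0) + 1L
  miss <- data.frame(omega = numeric(0), residual = numeric(0))
  lines <- data.frame(omega = numeric(0), sigma = numeric(0),
                      intercept = numeric(0))
  for (i in loc) {
    o <- stats::optimize(res, c(om[max(1, i - 1)], om[min(length(om), i + 1)]))
    if (o$objective < tol) {
      sg <- sign(cos(o$minimum * tau1) * cos(o$minimum * tau2))
      lines <- rbind(lines, data.frame(
        omega = o$minimum, sigma = sg,
        intercept = -1 / cos(o$minimum * tau1)))
    } else {
      miss <- rbind(miss, data.frame(omega = o$minimum, residual = o$objective))
    }
  }
  list(lines = lines, near_misses = miss)
}

#' Steady-state bifurcation lines
#'
#' Zero characteristic roots occur exactly on the lines
#' \eqn{1 + k_1 + k_2 = 0} (plus factor) and \eqn{1 + k_1 - k_2 = 0}
#' (minus factor).  Gains are positive at any equilibrium, so the plus
#' line never meets the physical quadrant: symmetry-breaking steady-state
#' bifurcations cannot occur.  On the minus line \eqn{k_2 = 1 + k_1}, a
#' trivial-equilibrium crossing is transcritical, a nontrivial one a fold.
#'
#' @param family `"minus"` or `"plus"`.
#' @return A list with `intercept` and `slope` of `k2` as a function of
#'   `k1`, and `reachable` (whether the line meets `k1, k2 > 0`).
#' @export
steady_state_line <- function(family = c("minus", "plus")) {
  family <- match.arg(family)
  if (family == "minus")
    list(family = family, intercept = 1, slope = 1, reachable = TRUE)
  else
    list(family = family, intercept = -1, slope = -1, reachable = FALSE)
}

#' Assemble the stability region in the gain plane
#'
#' Traces the boundary of the region of asymptotic stability around the
#' origin of the first quadrant of the \eqn{(k_1, k_2)} plane.  For the
#' delays of interest the boundary consists of (i) a segment of the
#' steady-state line \eqn{k_2 = 1 + k_1} from the \eqn{k_2} axis to a
#' fold-Hopf point ZH where the antisymmetric Hopf curve crosses the
#' line, (ii) a short arc of the antisymmetric curve \eqn{h_+} up to a
#' Hopf-Hopf point HH where it intersects the symmetric curve
#' \eqn{h_-}, and (iii) an arc of \eqn{h_-} descending to the
#' \eqn{k_1} axis.  The frequency windows \eqn{\Omega_S(h_\pm)} over
#' which each Hopf family forms part of the boundary are returned along
#' with the codimension-two vertices.  The segment structure is
#' discovered by scanning, not assumed: candidate intersections are
#' located on a frequency grid below `omega_max` and refined by Newton
#' iteration, and the assembled boundary is verified spectrally
#' (interior samples stable, boundary points neutral within tolerance).
#'
#' The frequency cap is justified by [frequency_bound()]: for the gain
#' extent of the region, imaginary roots above `omega_max` are impossible.
#'
#' @param tau1,tau2 the two delays.
#' @param omega_max frequency scan cap.
#' @param n_arc points per boundary arc in the returned polyline.
#' @param verify spectrally verify the assembled boundary (adds a few
#'   seconds).
#' @return An object of class `"stability_region"`: list with `boundary`
#'   (data frame `k1`, `k2`, `label`), `omega_ranges` (list `plus`,
#'   `minus`), `codim2` (data frame of ZH and HH vertices), `tau1`,
#'   `tau2`.
#' @export
stability_region <- function(tau1, tau2, omega_max = 1, n_arc = 60,
                             verify = FALSE) {
  dt <- tau2 - tau1
  hp <- function(om) unlist(hopf_curve(om, tau1, tau2, "plus")[1, c("k1", "k2")])
  hm <- function(om) unlist(hopf_curve(om, tau1, tau2, "minus")[1, c("k1", "k2")])
  grid <- seq(1e-3, min(omega_max, pi / dt - 1e-3), length.out = 3000)

  # ZH: h+ meets the steady-state line k2 = 1 + k1
  fzh <- function(om) { k <- hp(om); k[2] - 1 - k[1] }
  vz <- vapply(grid, fzh, 0)
  iz <- which(diff(sign(vz)) != 0)
  if (!length(iz)) stop("no fold-Hopf intersection found below omega_max")
  om_zh <- stats::uniroot(fzh, grid[c(iz[1], iz[1] + 1)], tol = 1e-13)$root
  k_zh <- hp(om_zh)

  # HH: h+ meets h- (2-D Newton seeded from the closest grid pair)
  vp <- t(vapply(grid, hp, c(0, 0)))
  vm <- t(vapply(grid, hm, c(0, 0)))
  ok_p <- which(vp[, 1] > -0.2 & vp[, 2] > 0 & abs(vp[, 2]) < 3)
  ok_m <- which(vm[, 1] > -0.2 & vm[, 2] > 0 & abs(vm[, 2]) < 3)
  dmat <- outer(ok_p, ok_m, function(i, j)
    (vp[i, 1] - vm[j, 1])^2 + (vp[i, 2] - vm[j, 2])^2)
  hit <- arrayInd(which.min(dmat), dim(dmat))
  p <- c(grid[ok_p[hit[1]]], grid[ok_m[hit[2]]])
  for (i in 1:60) {
    f0 <- hp(p[1]) - hm(p[2])
    if (max(abs(f0)) < 1e-13) break
    J <- matrix(0, 2, 2); h <- 1e-7
    J[, 1] <- (hp(p[1] + h) - hp(p[1])) / h
    J[, 2] <- -(hm(p[2] + h) - hm(p[2])) / h
    p <- p - solve(J, f0)
  }
  om_hh <- p
  k_hh <- hm(om_hh[2])

  # exit of h- from the first quadrant: k2 = 0
  fk2 <- function(om) hm(om)[2]
  vk <- vapply(grid, fk2, 0)
  ik <- which(diff(sign(vk)) != 0)
  ik <- ik[grid[ik] < om_hh[2]]
  if (!length(ik)) stop("h- arc does not reach the k1 axis below omega_max")
  om_ax <- stats::uniroot(fk2, grid[c(max(ik), max(ik) + 1)], tol = 1e-13)$root

  seg_line <- data.frame(k1 = seq(0, k_zh[1], length.out = n_arc))
  seg_line$k2 <- 1 + seg_line$k1
  seg_line$label <- "fold"
  arc <- function(o1, o2, fn, lab) {
    om <- seq(o1, o2, length.out = n_arc)
    k <- t(vapply(om, fn, c(0, 0)))
    data.frame(k1 = k[, 1], k2 = k[, 2], label = lab)
  }
  boundary <- rbind(seg_line,
                    arc(om_zh, om_hh[1], hp, "h+"),
                    arc(om_hh[2], om_ax, hm, "h-"))

  region <- structure(list(
    boundary = boundary,
    omega_ranges = list(plus = c(om_zh, om_hh[1]), minus = c(om_ax, om_hh[2])),
    codim2 = data.frame(
      kind = c("ZH", "HH"),
      k1 = c(k_zh[1], k_hh[1]), k2 = c(k_zh[2], k_hh[2]),
      omega1 = c(om_zh, om_hh[1]), omega2 = c(NA, om_hh[2])),
    tau1 = tau1, tau2 = tau2), class = "stability_region")

  if (verify) {
    bad <- verify_region(region)
    if (bad > 0)
      warning(sprintf("%d boundary/interior sample(s) failed spectral check", bad))
  }
  region
}

# spectral sanity check of an assembled region; returns number of failures
verify_region <- function(region, n = 40, margin_tol = 1e-5) {
  b <- region$boundary
  idx <- unique(round(seq(1, nrow(b), length.out = n)))
  fails <- 0L
  for (i in idx) {
    r <- rightmost_roots(b$k1[i], b$k2[i], region$tau1, region$tau2, count = 1)
    if (abs(r$rho[1]) > margin_tol) fails <- fails + 1L
    # matching interior point must be strictly stable
    ki <- c(b$k1[i], b$k2[i]) * 0.97
    ri <- rightmost_roots(ki[1], ki[2], region$tau1, region$tau2, count = 1)
    if (ri$rho[1] > -1e-9) fails <- fails + 1L
  }
  fails
}

#' @export
print.stability_region <- function(x, ...) {
  cat("Stability region of a symmetric equilibrium in the (k1, k2) plane\n")
  cat(sprintf("  delays: tau1 = %g, tau2 = %g\n", x$tau1, x$tau2))
  cat(sprintf("  Omega_S(h+) = (%.3f, %.3f)\n",
              x$omega_ranges$plus[1], x$omega_ranges$plus[2]))
  cat(sprintf("  Omega_S(h-) = (%.3f, %.3f)\n",
              x$omega_ranges$minus[1], x$omega_ranges$minus[2]))
  cat(sprintf("  ZH vertex at k = (%.3f, %.3f), omega = %.3f\n",
              x$codim2$k1[1], x$codim2$k2[1], x$codim2$omega1[1]))
  cat(sprintf("  HH vertex at k = (%.3f, %.3f), omegas = (%.3f, %.3f)\n",
              x$codim2$k1[2], x$codim2$k2[2], x$codim2$omega1[2],
              x$codim2$omega2[2]))
  invisible(x)
}

#' @export
plot.stability_region <- function(x, ...) {
  b <- x$boundary
  graphics::plot(b$k1, b$k2, type = "n", xlab = "k1", ylab = "k2",
                 main = "Stability region boundary", ...)
  cols <- c(fold = "blue", `h+` = "red", `h-` = "magenta")
  for (lab in unique(b$label)) {
    s <- b[b$label == lab, ]
    graphics::lines(s$k1, s$k2, col = cols[[lab]], lwd = 2)
  }
  graphics::points(x$codim2$k1, x$codim2$k2, pch = 19)
  graphics::text(x$codim2$k1, x$codim2$k2, x$codim2$kind, pos = 4)
  invisible(x)
}

#' Map gains at the origin to coupling parameters
#'
#' At the trivial equilibrium the activation slope is exactly 1, so the
#' linearization gains are \eqn{k_1 = \alpha_1\beta_1},
#' \eqn{k_2 = \alpha_2\beta_2} and any point of the gain-plane bifurcation
#' diagram maps linearly to the \eqn{(\alpha_1, \alpha_2)} plane.
#'
#' @param k1,k2 gains.
#' @param params a [pop_model()] object supplying the slopes.
#' @return Named vector `c(alpha1, alpha2)`.
#' @export
gains_to_alphas <- function(k1, k2, params) {
  c(alpha1 = k1 / params$beta1, alpha2 = k2 / params$beta2)
}

#' Count Hopf crossings of an equilibrium branch
#'
#' Follows the image of an equilibrium branch in the gain plane and
#' counts its transversal crossings with the full set of Hopf-curve
#' branches of both factors, between (and including) the two crossings
#' of the stability-region boundary at which the branch loses and regains
#' stability.  Each crossing is an imaginary-axis passage of a conjugate
#' root pair, so crossings are detected as changes of the
#' argument-principle unstable-root count of each factor along the
#' branch; steady-state passages (single real root through zero, e.g.
#' a branch point or fold) are recorded separately, not counted as Hopf
#' crossings.  The sampling is refined until the count stabilizes.
#'
#' @param branch an `eq_branch` object from [equilibrium_branch()], or a
#'   data frame with columns `k1`, `k2` ordered along the branch.
#' @param params the [pop_model()] object (for the delays).
#' @param refine number of successive grid doublings used to confirm the
#'   count.
#' @return A list with `hopf` (integer count), `steady` (count of real
#'   zero crossings) and `events` (data frame: index, factor, change).
#' @export
count_hopf_crossings <- function(branch, params, refine = 1) {
  b <- if (inherits(branch, "eq_branch")) branch$points else branch
  stopifnot(all(c("k1", "k2") %in% names(b)))
  tau1 <- params$tau1; tau2 <- params$tau2
  nu <- function(k1, k2)
    c(winding_count(k1, k2, tau1, tau2, -1), winding_count(k1, k2, tau1, tau2, 1))
  counts <- mapply(function(a, c2) nu(a, c2), b$k1, b$k2)
  tally <- function(counts) {
    d <- counts[, -1, drop = FALSE] - counts[, -ncol(counts), drop = FALSE]
    hopf <- sum(abs(d[abs(d) %% 2 == 0])) / 2
    steady <- sum(abs(d) %% 2 == 1)
    list(hopf = hopf, steady = steady, d = d)
  }
  t0 <- tally(counts)
  # refine: bisect every step, including steps with no detected change,
  # until the totals stop moving
  k1 <- b$k1; k2 <- b$k2
  for (r in seq_len(refine)) {
    n <- length(k1)
    mk1 <- (k1[-n] + k1[-1]) / 2; mk2 <- (k2[-n] + k2[-1]) / 2
    k1 <- as.vector(rbind(k1[-n], mk1)); k1 <- c(k1, b$k1[length(b$k1)])
    k2 <- as.vector(rbind(k2[-n], mk2)); k2 <- c(k2, b$k2[length(b$k2)])
    counts <- mapply(nu, k1, k2)
    t1 <- tally(counts)
    if (t1$hopf == t0$hopf && t1$steady == t0$steady) break
    t0 <- t1
  }
  ev <- which(colSums(abs(t0$d)) > 0)
  events <- do.call(rbind, lapply(ev, function(i) {
    ch <- t0$d[, i]
    data.frame(index = i,
               factor = c("minus", "plus")[ch != 0],
               change = ch[ch != 0])
  }))
  list(hopf = as.integer(t0$hopf), steady = as.integer(t0$steady),
       events = events)
}
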