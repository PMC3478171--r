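# High-level analyses: assembled bifurcation tables in the excitation
# parameter, equilibrium codimension-two points, and the task runner
# behind the command-line interface.

#' One-parameter bifurcation events of the equilibria
#'
#' Assembles the equilibrium-borne rows of the one-parameter bifurcation
#' table in `alpha2` at fixed `alpha1`: the Hopf bifurcations and branch
#' point of the trivial equilibrium (H1 is the stability loss of the
#' origin, B1 the transcritical point) and the fold and Hopf
#' bifurcations of the nontrivial branch (F1 the fold, H2/H3 the
#' Hopf points near it, H4 the restabilizing Hopf on the opposite side).
#' Labels follow the field's convention: H for Hopf, B for branch
#' point, F for fold, numbered in the narrative order of the study
#' (origin first, then the nontrivial branch from the branch point).
#'
#' @param params a [pop_model()]; `alpha2` is the scanned parameter.
#' @param alpha2_range trivial-branch scan window.
#' @param x_range nontrivial-branch activity window.
#' @param n sampling density per branch.
#' @return A data frame with columns `label`, `alpha2`, `x_star`,
#'   `factor`, `omega`.
#' @export
equilibrium_table <- function(params, alpha2_range = c(0.4, 1.1),
                              x_range = c(-0.6, 2.2), n = 900) {
  tb <- equilibrium_branch(params, range = alpha2_range, trivial = TRUE,
                           n = n)
  nb <- equilibrium_branch(params, range = x_range, trivial = FALSE, n = n)
  te <- tb$events
  # trivial branch: Hopf crossings in increasing alpha2; H1 is the first
  th <- te[te$type == "hopf", , drop = FALSE]
  th <- th[order(th$alpha2), , drop = FALSE]
  rows <- list()
  if (nrow(th))
    for (i in seq_len(nrow(th)))
      rows[[length(rows) + 1]] <- data.frame(
        label = if (i == 1) "H1" else paste0("H", i + 4),
        alpha2 = th$alpha2[i], x_star = 0, factor = th$factor[i],
        omega = th$omega[i])
  bp <- te[te$type == "branch-point", , drop = FALSE]
  if (nrow(bp))
    rows[[length(rows) + 1]] <- data.frame(
      label = "B1", alpha2 = bp$alpha2[1], x_star = 0, factor = "minus",
      omega = 0)
  ne <- nb$events
  folds <- ne[ne$type == "fold", , drop = FALSE]
  if (nrow(folds))
    rows[[length(rows) + 1]] <- data.frame(
      label = "F1", alpha2 = folds$alpha2[1], x_star = folds$x_star[1],
      factor = "minus", omega = 0)
  # nontrivial Hopf events: H2, H3 close to the fold (x > 0 beyond it),
  # H4 on the other side of the branch point (x < 0)
  nh <- ne[ne$type == "hopf", , drop = FALSE]
  if (nrow(folds) && nrow(nh)) {
    xf <- folds$x_star[1]
    beyond <- nh[nh$x_star > xf, , drop = FALSE]
    beyond <- beyond[order(beyond$x_star), , drop = FALSE]
    if (nrow(beyond) >= 1)
      rows[[length(rows) + 1]] <- data.frame(
        label = "H2", alpha2 = beyond$alpha2[1], x_star = beyond$x_star[1],
        factor = beyond$factor[1], omega = beyond$omega[1])
    if (nrow(beyond) >= 2)
      rows[[length(rows) + 1]] <- data.frame(
        label = "H3", alpha2 = beyond$alpha2[2], x_star = beyond$x_star[2],
        factor = beyond$factor[2], omega = beyond$omega[2])
  }
  neg <- nh[nh$x_star < 0, , drop = FALSE]
  if (nrow(neg)) {
    i <- which.min(neg$x_star)     # last crossing: most negative x
    rows[[length(rows) + 1]] <- data.frame(
      label = "H4", alpha2 = neg$alpha2[i], x_star = neg$x_star[i],
      factor = neg$factor[i], omega = neg$omega[i])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cycle-branch bifurcation events from the origin's Hopf
#'
#' Continues the symmetric periodic-orbit branch born at the origin's
#' stability-loss Hopf downward in `alpha2` and labels the detected
#' events in order of occurrence along the branch (PD1, LPC1, PD2, PD3,
#' LPC2, PD4, plus an unlabeled NS near the start).  The stable window
#' of symmetric orbits is bounded by the second and third period
#' doublings.
#'
#' @param params a [pop_model()].
#' @param h1 optionally, a list with the Hopf point (`alpha2`, `omega`);
#'   computed from the trivial branch if missing.
#' @param range `alpha2` continuation window.
#' @param L,m collocation mesh resolution.
#' @param ... passed to [continue_cycles()].
#' @return A list with `events` (data frame `label`, `type`, `factor`,
#'   `alpha2`, `T`), `branch` (the `"cycle_branch"`), and
#'   `stable_window` (the `alpha2` interval of stable symmetric orbits).
#' @export
cycle_table <- function(params, h1 = NULL, range = c(0.45, 0.8),
                        L = 40, m = 4, ...) {
  if (is.null(h1)) h1 <- origin_hopf(params)
  p <- params; p$alpha2 <- h1$alpha2
  br <- cycle_branch_from_hopf(p, h1$omega, family = "symmetric",
                               range = range, direction = -1,
                               L = L, m = m, ...)
  ev <- br$events
  lab <- character(nrow(ev))
  lab[ev$type == "PD"] <- paste0("PD", seq_len(sum(ev$type == "PD")))
  lab[ev$type == "LPC"] <- paste0("LPC", seq_len(sum(ev$type == "LPC")))
  lab[ev$type == "NS"] <- paste0("NS", seq_len(sum(ev$type == "NS")))
  ev$label <- lab
  ev <- ev[, c("label", "type", "factor", "alpha2", "T")]
  sw <- stable_window(br)
  list(events = ev, branch = br, stable_window = sw)
}

# largest contiguous run of stable points along a cycle branch
stable_window <- function(branch) {
  p <- branch$points
  r <- rle(p$stable)
  if (!any(r$values)) return(c(NA_real_, NA_real_))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  i <- which(r$values)[which.max(r$lengths[r$values])]
  range(p$alpha2[starts[i]:ends[i]])
}

#' Stability-loss Hopf of the origin
#'
#' The smallest `alpha2` at which the trivial equilibrium loses
#' stability: the crossing of the vertical line \eqn{k_1 =
#' \alpha_1\beta_1} with the symmetric-family arc of the stability
#' region boundary, converted back through \eqn{\alpha_2 = k_2/\beta_2}.
#'
#' @param params a [pop_model()].
#' @param region optionally a precomputed [stability_region()].
#' @return A list with `alpha2`, `omega`, `k1`, `k2`.
#' @export
origin_hopf <- function(params, region = NULL) {
  if (is.null(region)) region <- stability_region(params$tau1, params$tau2)
  k1 <- params$alpha1 * params$beta1
  rng <- region$omega_ranges$minus
  f <- function(om) hopf_curve(om, params$tau1, params$tau2, "minus")$k1 - k1
  om <- stats::uniroot(f, rng, tol = 1e-12)$root
  k2 <- hopf_curve(om, params$tau1, params$tau2, "minus")$k2
  list(alpha2 = k2 / params$beta2, omega = om, k1 = k1, k2 = k2)
}

#' Equilibrium codimension-two points in the coupling plane
#'
#' The four codimension-two points carried by equilibria: the Hopf-Hopf
#' (HH1) and transcritical-Hopf (ZH1) points of the origin (the region
#' vertices mapped through the gain relations), the generalized Hopf
#' (GH1) on the symmetric Hopf curve, and the fold-Hopf (ZH2) of the
#' nontrivial equilibrium, located by a scan over `alpha1` of the fold
#' point's antisymmetric spectrum followed by a four-dimensional Newton
#' solve.
#'
#' @param params a [pop_model()] template.
#' @param alpha1_scan scan interval for the ZH2 search.
#' @return A data frame with columns `label`, `alpha2`, `alpha1`,
#'   `x_star`, `omega`.
#' @export
codim2_table <- function(params, alpha1_scan = c(0.002, 0.05)) {
  region <- stability_region(params$tau1, params$tau2)
  hh <- locate_codim2(params, "hopf-hopf", region = region)
  zh <- locate_codim2(params, "transcritical-hopf", region = region)
  gh <- find_generalized_hopf(params,
                              omega_range = region$omega_ranges$minus)
  zh2 <- locate_zh2(params, alpha1_scan)
  out <- data.frame(
    label = c("HH1", "ZH1", "GH1", "ZH2"),
    alpha2 = c(hh$alpha2, zh$alpha2, gh$alpha2, zh2$alpha2),
    alpha1 = c(hh$alpha1, zh$alpha1, gh$alpha1, zh2$alpha1),
    x_star = c(0, 0, 0, zh2$x_star),
    omega = c(hh$omega, zh$omega, gh$omega, zh2$omega))
  out
}

# fold point (x, alpha2) of the nontrivial branch at given alpha1
nontrivial_fold <- function(params) {
  f <- function(x) branch_alpha2_of_x(x, params)
  o <- stats::optimize(f, c(1e-3, 4))
  list(x_star = o$minimum, alpha2 = o$objective)
}

# ZH2: scan alpha1 for an imaginary antisymmetric pair at the fold,
# bisect the spectral abscissa of the plus factor, then Newton-polish
locate_zh2 <- function(params, alpha1_scan = c(0.002, 0.05), nscan = 30) {
  test <- function(a1) {
    p <- params; p$alpha1 <- a1
    fp <- nontrivial_fold(p)
    p$alpha2 <- fp$alpha2
    k <- equilibrium_gains(p, fp$x_star)
    r <- axis_nearest_root(unname(k[1]), unname(k[2]), p$tau1, p$tau2, "plus")
    if (is.na(r)) return(list(v = -1, fp = fp, om = NA_real_))
    list(v = unname(Re(r)), fp = fp, om = unname(Im(r)))
  }
  a1s <- seq(alpha1_scan[1], alpha1_scan[2], length.out = nscan)
  vs <- vapply(a1s, function(a) test(a)$v, 0)
  ix <- which(diff(sign(vs)) != 0)
  if (!length(ix)) stop("no fold-Hopf sign change found on the alpha1 scan")
  lo <- a1s[ix[1]]; hi <- a1s[ix[1] + 1]
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (sign(test(mid)$v) == sign(test(lo)$v)) lo <- mid else hi <- mid
  }
  t0 <- test((lo + hi) / 2)
  seed <- list(alpha1 = (lo + hi) / 2, alpha2 = t0$fp$alpha2,
               x_star = t0$fp$x_star, omega = t0$om)
  locate_codim2(params, "fold-hopf", seed = seed)
}

#' Write a bifurcation table
#'
#' Serializes labeled bifurcation events to CSV (and back), rows ordered
#' stably by parameter value.
#'
#' @param events a data frame with an `alpha2` column (and usually
#'   `label`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bifurcation_table <- function(events, path) {
  key <- if (is.null(events$label)) seq_len(nrow(events)) else events$label
  ev <- events[order(events$alpha2, key), , drop = FALSE]
  utils::write.csv(format(ev, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bifurcation_table
#' @export
read_bifurcation_table <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in setdiff(names(tb), c("label", "type", "factor")))
    tb[[nm]] <- as.numeric(tb[[nm]])
  tb
}

#' Run a named analysis task
#'
#' The programmatic core of the command-line interface.  Executes one of
#' the package's standard analyses and writes machine-readable output
#' (JSON and/or CSV) into `out_dir`.
#'
#' Tasks: `"region"` (stability-region geometry), `"spectrum"`
#' (rightmost roots at given gains), `"equilibrium-branch"`,
#' `"lyapunov"` (Lyapunov coefficient along the symmetric arc),
#' `"simulate"` (trajectory + attractor class for a history preset),
#' `"cycles"` (symmetric cycle branch from the origin's Hopf),
#' `"table1"` (equilibrium + cycle events), `"table2-equilibrium"`
#' (codimension-two points).
#'
#' @param config a list with entries `task`, `params` (a [pop_model()],
#'   default the paper-default preset), `out_dir` (default `"."`), and
#'   task-specific options (`preset`, `t_end`, `omega_range`, `range`,
#'   `n_steps`, ...).
#' @return A list with the task's results (also written to disk),
#'   invisibly.
#' @export
run_task <- function(config) {
  task <- config$task
  params <- config$params %||% pop_model_preset()
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  towrite <- function(x, nm) {
    jsonlite::write_json(x, file.path(out_dir, nm), auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
  }
  res <- switch(
    task,
    "region" = {
      reg <- stability_region(params$tau1, params$tau2)
      out <- list(
        boundary = reg$boundary,
        omega_ranges = lapply(reg$omega_ranges, round, 6),
        codim2 = reg$codim2)
      towrite(out, "region.json")
      reg
    },
    "spectrum" = {
      r <- rightmost_roots(config$k1, config$k2, params$tau1, params$tau2,
                           count = config$count %||% 8)
      towrite(r, "spectrum.json")
      r
    },
    "equilibrium-branch" = {
      br <- equilibrium_branch(params,
                               range = config$range %||% c(0.4, 1.1),
                               trivial = config$trivial %||% FALSE,
                               n = config$n %||% 600)
      utils::write.csv(br$points, file.path(out_dir, "branch.csv"),
                       row.names = FALSE)
      write_bifurcation_table(br$events, file.path(out_dir, "branch_events.csv"))
      br
    },
    "lyapunov" = {
      rng <- config$omega_range %||% c(0.251, 0.293)
      oms <- seq(rng[1], rng[2], length.out = config$n_steps %||% 100)
      ell <- vapply(oms, ell1_on_hminus, 0, params = params)
      k <- hopf_curve(oms, params$tau1, params$tau2, "minus")
      df <- data.frame(omega = oms, k1 = k$k1, k2 = k$k2, ell1 = ell,
                       criticality = ifelse(ell < 0, "supercritical",
                                            "subcritical"))
      utils::write.csv(df, file.path(out_dir, "lyapunov.csv"),
                       row.names = FALSE)
      gh <- find_generalized_hopf(params)
      towrite(gh, "generalized_hopf.json")
      list(scan = df, gh = gh)
    },
    "simulate" = {
      hist <- history_preset(config$preset %||% "C")
      traj <- integrate_dde(params, hist,
                            t_end = config$t_end %||% 5000)
      cls <- classify_attractor(traj,
                                transient = config$transient %||% 4000)
      utils::write.csv(data.frame(t = traj$times, x1 = traj$x[, 1],
                                  x2 = traj$x[, 2]),
                       file.path(out_dir, "trajectory.csv"),
                       row.names = FALSE)
      towrite(cls, "classification.json")
      list(trajectory = traj, classification = cls)
    },
    "cycles" = {
      ct <- cycle_table(params, range = config$range %||% c(0.45, 0.8))
      utils::write.csv(ct$branch$points, file.path(out_dir, "cycle_branch.csv"),
                       row.names = FALSE)
      write_bifurcation_table(ct$events, file.path(out_dir, "cycle_events.csv"))
      ct
    },
    "table1" = {
      eq <- equilibrium_table(params)
      ct <- cycle_table(params)
      ev <- rbind(eq[, c("label", "alpha2")],
                  ct$events[ct$events$type != "NS", c("label", "alpha2")])
      write_bifurcation_table(ev, file.path(out_dir, "table1.csv"))
      list(equilibria = eq, cycles = ct, table = ev)
    },
    "table2-equilibrium" = {
      tb <- codim2_table(params)
      write_bifurcation_table(tb, file.path(out_dir, "table2_equilibrium.csv"))
      towrite(tb, "table2_equilibrium.json")
      tb
    },
    stop("unknown task: ", task))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
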