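#' Two-population neural mass model with two delays
#'
#' Constructs the parameter set of the non-dimensionalized two-population
#' model
#' \deqn{\dot x_1(t) = -x_1(t) - \alpha_1 S(\beta_1 x_1(t-\tau_1))
#'                     + \alpha_2 S(\beta_2 x_2(t-\tau_2)),}
#' \deqn{\dot x_2(t) = -x_2(t) - \alpha_1 S(\beta_1 x_2(t-\tau_1))
#'                     + \alpha_2 S(\beta_2 x_1(t-\tau_2)),}
#' where \eqn{x_1, x_2} are the activities of two mutually excitatory
#' neuronal populations, \eqn{\alpha_1} is the strength of delayed
#' self-inhibition (delay \eqn{\tau_1}), \eqn{\alpha_2} the strength of
#' delayed cross-excitation (delay \eqn{\tau_2}), \eqn{\beta_1,\beta_2}
#' the corresponding activation slopes, and \eqn{S(\cdot; a)} the shifted
#' tanh activation of [sigmoid_act()] with inflection parameter `a`.
#' Identical parameters for the two populations make the model equivariant
#' under the swap \eqn{(x_1,x_2) \mapsto (x_2,x_1)}.
#'
#' All parameters must be strictly positive, and the excitatory delay must
#' exceed the inhibitory one (`tau2 > tau1`), the regime assumed throughout
#' the stability analysis.
#'
#' @param alpha1 inhibitory coupling gain (> 0).
#' @param alpha2 excitatory coupling gain (> 0).
#' @param beta1 inhibitory activation slope (> 0).
#' @param beta2 excitatory activation slope (> 0).
#' @param tau1 feedback-inhibition delay, dimensionless time (> 0).
#' @param tau2 feedforward-excitation delay (> `tau1`).
#' @param a activation inflection parameter (> 0).
#' @return An object of class `"pop_model"`: a named list of the seven
#'   parameters.
#' @seealso [pop_model_preset()], [model_rhs()], [read_model_config()]
#' @examples
#' p <- pop_model(alpha1 = 0.069, alpha2 = 0.55)
#' p
#' @export
pop_model <- function(alpha1, alpha2, beta1 = 2, beta2 = 1.2,
                      tau1 = 11.6, tau2 = 20.3, a = 1) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
            tau1 = tau1, tau2 = tau2, a = a)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all model parameters must be finite and strictly positive")
  if (tau2 <= tau1)
    stop("the excitatory delay tau2 must exceed the inhibitory delay tau1")
  class(p) <- "pop_model"
  p
}

#' Named parameter presets
#'
#' `"paper-default"` is the reference configuration used throughout the
#' bifurcation study: slopes `beta1 = 2`, `beta2 = 1.2`, delays
#' `tau1 = 11.6`, `tau2 = 20.3`, activation shape `a = 1`, inhibition
#' `alpha1 = 0.069`.  The excitation `alpha2` is the principal bifurcation
#' parameter; the preset places it at 0.55, inside the four-attractor
#' multistable window.
#'
#' @param name preset name; currently `"paper-default"`.
#' @param ... named overrides of individual parameters.
#' @return A [pop_model()] object.
#' @export
pop_model_preset <- function(name = "paper-default", ...) {
  name <- match.arg(name)
  base <- list(alpha1 = 0.069, alpha2 = 0.55, beta1 = 2, beta2 = 1.2,
               tau1 = 11.6, tau2 = 20.3, a = 1)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(base))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    base[names(ov)] <- ov
  }
  do.call(pop_model, base)
}

#' @export
print.pop_model <- function(x, ...) {
  cat("Two-population neural mass model (two delays)\n")
  cat(sprintf("  coupling:   alpha1 = %g (inhibition), alpha2 = %g (excitation)\n",
              x$alpha1, x$alpha2))
  cat(sprintf("  slopes:     beta1  = %g, beta2  = %g\n", x$beta1, x$beta2))
  cat(sprintf("  delays:     tau1   = %g, tau2   = %g\n", x$tau1, x$tau2))
  cat(sprintf("  activation: shifted tanh, a = %g\n", x$a))
  invisible(x)
}

#' Shifted tanh activation function
#'
#' The synaptic activation
#' \deqn{S(x; a) = (\tanh(x - a) + \tanh(a)) \cosh^2(a),}
#' a bounded, strictly increasing sigmoid normalized so that
#' \eqn{S(0) = 0} and \eqn{S'(0) = 1}.  Unlike an odd sigmoid it is not
#' symmetric about the origin: activation saturates more strongly than
#' deactivation, reflecting the physiological asymmetry of synaptic
#' activation.
#'
#' @param x input activity (vectorized).
#' @param a inflection parameter (> 0); the inflection point sits at
#'   `x = a`.
#' @return `S(x; a)`, same shape as `x`.
#' @examples
#' sigmoid_act(0, 1)   # 0 by construction
#' sigmoid_act(1, 1)   # tanh(1) * cosh(1)^2
#' @export
sigmoid_act <- function(x, a = 1) {
  (tanh(x - a) + tanh(a)) * cosh(a)^2
}

#' Derivatives of the shifted tanh activation
#'
#' Closed-form derivatives of [sigmoid_act()] up to third order.  The
#' first derivative enters the linearization gains, the second and third
#' the cubic Hopf normal-form coefficient; they are evaluated analytically
#' so normal-form computations carry no differentiation noise.
#'
#' @inheritParams sigmoid_act
#' @param order derivative order, 1, 2 or 3.
#' @return The derivative of `S` of the requested order at `x`.
#' @export
sigmoid_act_deriv <- function(x, a = 1, order = 1) {
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  u <- x - a
  sech2 <- 1 / cosh(u)^2
  switch(order,
         cosh(a)^2 * sech2,
         -2 * cosh(a)^2 * sech2 * tanh(u),
         cosh(a)^2 * sech2 * (4 * tanh(u)^2 - 2 * sech2))
}

#' Model right-hand side
#'
#' Evaluates the derivative of the two-population model given the current
#' state and the two lagged states.  Component \eqn{i} is
#' \eqn{-x_i(t) - \alpha_1 S(\beta_1 x_i(t-\tau_1))
#'      + \alpha_2 S(\beta_2 x_j(t-\tau_2))} with \eqn{j \ne i}:
#' inhibition acts within a population, excitation across populations.
#' The map commutes with [swap_state()].
#'
#' @param params a [pop_model()] object.
#' @param now state pair \eqn{(x_1, x_2)} at time t.
#' @param lag1 state pair at \eqn{t - \tau_1}.
#' @param lag2 state pair at \eqn{t - \tau_2}.
#' @return The derivative pair.
#' @export
model_rhs <- function(params, now, lag1, lag2) {
  -now - params$alpha1 * sigmoid_act(params$beta1 * lag1, params$a) +
    params$alpha2 * sigmoid_act(params$beta2 * rev(lag2), params$a)
}

#' Population swap
#'
#' The generator of the model's Z2 symmetry: exchanges the two population
#' activities.  An involution; its fixed space is the diagonal
#' \eqn{x_1 = x_2}, on which the symmetric equilibria and in-phase
#' oscillations live.
#'
#' @param x state pair.
#' @return The pair with components exchanged.
#' @export
swap_state <- function(x) rev(x)

#' Read and write plain-text model configurations
#'
#' A configuration file holds one `key = value` line per parameter
#' (`alpha1`, `alpha2`, `beta1`, `beta2`, `tau1`, `tau2`, `a`).  Lines
#' starting with `#` and blank lines are ignored.  A line `preset = NAME`
#' loads the named preset first; later keys override it.
#'
#' @param path file path.
#' @return `read_model_config()` returns a [pop_model()] object;
#'   `write_model_config()` writes `params` and returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed config line (expected key = value)")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  args <- list()
  if ("preset" %in% keys) {
    args <- unclass(pop_model_preset(vals[keys == "preset"][1L]))
    keep <- keys != "preset"
    keys <- keys[keep]; vals <- vals[keep]
  }
  num <- as.numeric(vals)
  if (any(is.na(num))) stop("non-numeric value for key(s): ",
                            paste(keys[is.na(num)], collapse = ", "))
  args[keys] <- num
  do.call(pop_model, args)
}

#' @rdname read_model_config
#' @param params a [pop_model()] object to serialize.
#' @export
write_model_config <- function(params, path) {
  stopifnot(inherits(params, "pop_model"))
  writeLines(sprintf("%s = %.17g", names(unclass(params)), unlist(params)), path)
  invisible(path)
}
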