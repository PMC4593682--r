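# Deterministic mean-field limit on the complete graph:
#
#   x'(t) = -lambda x y,   y'(t) = lambda x y - alpha y z,   z'(t) = alpha y z
#
# and the time-changed density-dependent system
#
#   x'(t) = -lambda x,     y'(t) = (lambda + alpha) x + alpha y - alpha
#
# whose solution is closed form: x(t) = x0 exp(-lambda t), y(t) = f(x(t))
# with f(x) = 1 - z0 (x0/x)^rho - x.

#' Mean-field rumour dynamics on the complete graph
#'
#' Numerically integrates the deterministic limit of the scotching process
#' under homogeneous mixing.
#'
#' @param params A [make_params()] object.
#' @param init A [make_init()] object.
#' @param t_end Final time (> 0).
#' @param n_points Number of equally spaced output times (>= 2).
#' @param control A [rumour_control()] object.
#'
#' @return A trajectory data frame with columns `t`, `x`, `y`, `z`.
#' @export
#' @examples
#' tr <- solve_mean_field(make_params(0.5, 0.5), make_init(0.98, 0.01, 0.01),
#'                        t_end = 40)
#' max(tr$y)  # spreader peak
solve_mean_field <- function(params, init, t_end, n_points = 201,
                             control = rumour_control()) {
  stopifnot(inherits(params, "rumour_params"), inherits(init, "rumour_init"))
  if (!is.numeric(t_end) || t_end <= 0) stop("`t_end` must be > 0", call. = FALSE)
  if (n_points < 2) stop("`n_points` must be >= 2", call. = FALSE)
  times <- seq(0, t_end, length.out = n_points)
  rhs <- function(t, state, p) {
    x <- state[1]; y <- state[2]; z <- state[3]
    inf <- p$lambda * x * y
    sc <- p$alpha * y * z
    list(c(-inf, inf - sc, sc))
  }
  sol <- deSolve::ode(y = c(x = init$x0, y = init$y0, z = init$z0),
                      times = times, func = rhs, parms = params,
                      rtol = control$ode_rtol, atol = control$ode_atol)
  if (nrow(sol) < n_points) {
    stop(sprintf("ODE integration failed after t = %.6g", sol[nrow(sol), 1]),
         call. = FALSE)
  }
  new_trajectory(sol[, 1], sol[, 2], sol[, 3], sol[, 4],
                 mass_tol = control$mass_tol)
}

#' The final-size function f
#'
#' Builds the function f(x) = 1 - z0 (x0/x)^rho - x on the domain (0, x0],
#' whose root in (0, x0] is the limiting ignorant fraction.  The identity
#' f(x0) = y0 holds by construction.
#'
#' @inheritParams solve_mean_field
#' @return A list of class `f_curve`.
#' @export
f_curve <- function(params, init) {
  stopifnot(inherits(params, "rumour_params"), inherits(init, "rumour_init"))
  structure(list(params = params, init = init), class = "f_curve")
}

#' Evaluate the final-size function
#'
#' The power term is evaluated in log space, (x0/x)^rho =
#' exp(rho (log x0 - log x)), so that tiny x with large rho cannot
#' overflow.
#'
#' @param curve An [f_curve()] object.
#' @param x Evaluation points in (0, x0]; vectorised.
#'
#' @return f(x), same length as `x`.
#' @export
#' @examples
#' cv <- f_curve(make_params(0.5, 0.5), make_init(0.98, 0.01, 0.01))
#' f_eval(cv, 0.5)  # 1 - 0.0196 - 0.5 = 0.4804
f_eval <- function(curve, x) {
  stopifnot(inherits(curve, "f_curve"))
  x0 <- curve$init$x0
  if (any(!is.finite(x)) || any(x <= 0) || any(x > x0 + 1e-15)) {
    stop(sprintf("`x` must lie in (0, x0] = (0, %g]", x0), call. = FALSE)
  }
  rho <- curve$params$rho
  z0 <- curve$init$z0
  1 - z0 * exp(rho * (log(x0) - log(x))) - x
}

#' Time-changed density-dependent system
#'
#' Integrates the transformed linear system x' = -lambda x,
#' y' = (lambda + alpha) x + alpha y - alpha.  Past the first zero of y the
#' curve y(t) is negative; that part is mathematically meaningful for the
#' case analysis of the final size and is returned unless
#' `stop_at_zero = TRUE`, in which case integration halts at the first
#' zero crossing of y (the transformed absorption time).
#'
#' @inheritParams solve_mean_field
#' @param stop_at_zero Halt at the first zero of y?
#'
#' @return A trajectory data frame (`z` reported as 1 - x - y; only x and y
#'   are dynamical here).
#' @export
solve_transformed <- function(params, init, t_end, n_points = 201,
                              stop_at_zero = FALSE,
                              control = rumour_control()) {
  stopifnot(inherits(params, "rumour_params"), inherits(init, "rumour_init"))
  if (!is.numeric(t_end) || t_end <= 0) stop("`t_end` must be > 0", call. = FALSE)
  if (n_points < 2) stop("`n_points` must be >= 2", call. = FALSE)
  times <- seq(0, t_end, length.out = n_points)
  rhs <- function(t, state, p) {
    x <- state[1]; y <- state[2]
    list(c(-p$lambda * x, (p$lambda + p$alpha) * x + p$alpha * y - p$alpha))
  }
  if (stop_at_zero && init$y0 > 0) {
    sol <- deSolve::lsodar(y = c(x = init$x0, y = init$y0), times = times,
                           func = rhs, parms = params,
                           rootfunc = function(t, state, p) state[2],
                           rtol = control$ode_rtol, atol = control$ode_atol)
  } else {
    sol <- deSolve::ode(y = c(x = init$x0, y = init$y0), times = times,
                        func = rhs, parms = params,
                        rtol = control$ode_rtol, atol = control$ode_atol)
  }
  tt <- sol[, 1]; x <- sol[, 2]; y <- sol[, 3]
  keep <- !duplicated(tt)
  new_trajectory(tt[keep], x[keep], y[keep], 1 - x[keep] - y[keep],
                 mass_tol = Inf)
}

#' Closed-form solution of the time-changed system
#'
#' Returns (x(t), y(t)) = (x0 exp(-lambda t), f(x(t))).
#'
#' @inheritParams solve_mean_field
#' @param t Non-negative times; vectorised.
#'
#' @return A two-column matrix with columns `x` and `y`.
#' @export
#' @examples
#' closed_form_xy(make_params(0.5, 0.5), make_init(0.98, 0.01, 0.01), 0)
closed_form_xy <- function(params, init, t) {
  stopifnot(inherits(params, "rumour_params"), inherits(init, "rumour_init"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  x <- init$x0 * exp(-params$lambda * t)
  y <- f_eval(f_curve(params, init), x)
  cbind(x = x, y = y)
}

# Event-stopped integration of the untransformed mean-field system up to
# the point where the spreader fraction has effectively died out
# (y < y_floor).  Returns the final state.  Used by the phase-diagram ODE
# engine.
mean_field_final_state <- function(params, init, y_floor = 1e-8,
                                   control = rumour_control()) {
  if (init$y0 <= y_floor) {
    return(c(x = init$x0, y = init$y0, z = init$z0))
  }
  rhs <- function(t, state, p) {
    x <- state[1]; y <- state[2]; z <- state[3]
    inf <- p$lambda * x * y
    sc <- p$alpha * y * z
    list(c(-inf, inf - sc, sc))
  }
  t_cap <- 1e6 / params$lambda
  sol <- deSolve::lsodar(y = c(x = init$x0, y = init$y0, z = init$z0),
                         times = c(0, t_cap), func = rhs, parms = params,
                         rootfunc = function(t, state, p) state[2] - y_floor,
                         rtol = control$ode_rtol, atol = control$ode_atol)
  st <- pmin(pmax(sol[nrow(sol), -1], 0), 1)  # clip integrator round-off
  names(st) <- c("x", "y", "z")
  st
}
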