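# Shared parameter, state and trajectory types used by every other module.

#' Numerical control settings
#'
#' Central record of the tolerances used throughout the package.
#'
#' @param ode_rtol Relative tolerance of the ODE integrators.
#' @param ode_atol Absolute tolerance of the ODE integrators.
#' @param mass_tol Tolerance for the mass-conservation check x + y + z = 1.
#' @param root_xtol Tolerance of the bracketed root searches.
#'
#' @return A list of class `rumour_control`.
#' @export
#' @examples
#' rumour_control(ode_rtol = 1e-6)
rumour_control <- function(ode_rtol = 1e-8, ode_atol = 1e-10,
                           mass_tol = 1e-8, root_xtol = 1e-12) {
  stopifnot(ode_rtol > 0, ode_atol > 0, mass_tol > 0, root_xtol > 0)
  structure(list(ode_rtol = ode_rtol, ode_atol = ode_atol,
                 mass_tol = mass_tol, root_xtol = root_xtol),
            class = "rumour_control")
}

#' Rumour model rates
#'
#' Validated pair of rates: `lambda`, the rate at which a spreader informs an
#' ignorant contact, and `alpha`, the rate at which a stifler scotches
#' (silences) a spreader.  The derived ratio `rho = alpha / lambda` is the
#' model's single shape parameter once the initial condition is fixed.
#'
#' @param lambda Positive, finite spreading rate.
#' @param alpha Non-negative, finite scotching rate.
#'
#' @return A list of class `rumour_params` with fields `lambda`, `alpha`,
#'   `rho`.
#' @export
#' @examples
#' make_params(0.5, 0.5)$rho  # 1
make_params <- function(lambda, alpha) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) {
    stop("`lambda` must be a single finite positive number", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0) {
    stop("`alpha` must be a single finite non-negative number", call. = FALSE)
  }
  structure(list(lambda = as.numeric(lambda), alpha = as.numeric(alpha),
                 rho = as.numeric(alpha) / as.numeric(lambda)),
            class = "rumour_params")
}

#' @export
print.rumour_params <- function(x, ...) {
  cat(sprintf("rumour rates: lambda = %g, alpha = %g (rho = %g)\n",
              x$lambda, x$alpha, x$rho))
  invisible(x)
}

#' Initial compartment fractions
#'
#' Limiting initial fractions (x0, y0, z0) of ignorants, spreaders and
#' stiflers.  The standing assumptions of the asymptotic theory are
#' x0 > 0 and z0 > 0 (a rumour can only be scotched if some stiflers are
#' present from the start); y0 may be zero.
#'
#' @param x0 Initial ignorant fraction, in (0, 1).
#' @param y0 Initial spreader fraction, in \[0, 1).
#' @param z0 Initial stifler fraction, in (0, 1).
#'
#' @return A list of class `rumour_init`.
#' @export
#' @examples
#' make_init(0.98, 0.01, 0.01)
make_init <- function(x0, y0, z0) {
  for (nm in c("x0", "y0", "z0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  if (x0 <= 0) stop("`x0` must be > 0", call. = FALSE)
  if (z0 <= 0) stop("`z0` must be > 0", call. = FALSE)
  if (y0 < 0) stop("`y0` must be >= 0", call. = FALSE)
  if (abs(x0 + y0 + z0 - 1) > 1e-12) {
    stop("initial fractions must sum to 1 (within 1e-12)", call. = FALSE)
  }
  structure(list(x0 = as.numeric(x0), y0 = as.numeric(y0),
                 z0 = as.numeric(z0)),
            class = "rumour_init")
}

#' @export
print.rumour_init <- function(x, ...) {
  cat(sprintf("initial fractions: x0 = %g, y0 = %g, z0 = %g\n",
              x$x0, x$y0, x$z0))
  invisible(x)
}

#' Integer compartment counts for a finite population
#'
#' Discretises limiting fractions into integer counts (X, Y, Z) with
#' X + Y + Z = n.  X and Z are rounded; the spreader count Y takes the
#' remainder, so the compartment whose positivity drives the dynamics is an
#' exact integer complement.
#'
#' @param n Population size (>= 3).
#' @param init A [make_init()] object.
#'
#' @return A list of class `rumour_counts` with fields `X`, `Y`, `Z`, `n`.
#' @export
#' @examples
#' counts_from_fractions(1e4, make_init(0.98, 0.01, 0.01))
counts_from_fractions <- function(n, init) {
  stopifnot(inherits(init, "rumour_init"))
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 3 ||
      n != round(n)) {
    stop("`n` must be a single integer >= 3", call. = FALSE)
  }
  n <- as.integer(n)
  X <- as.integer(round(init$x0 * n))
  Z <- as.integer(round(init$z0 * n))
  Y <- n - X - Z
  if (X < 0 || Y < 0 || Z < 0) {
    stop("rounding produced a negative compartment count; use a larger `n`",
         call. = FALSE)
  }
  structure(list(X = X, Y = Y, Z = Z, n = n), class = "rumour_counts")
}

#' @export
print.rumour_counts <- function(x, ...) {
  cat(sprintf("counts (n = %d): X = %d, Y = %d, Z = %d\n",
              x$n, x$X, x$Y, x$Z))
  invisible(x)
}

# Assemble a trajectory data frame and check its invariants.
new_trajectory <- function(times, x, y, z, mass_tol = 1e-8) {
  stopifnot(length(times) == length(x), length(x) == length(y),
            length(y) == length(z))
  if (any(diff(times) <= 0)) {
    stop("trajectory times must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(t = times, x = x, y = y, z = z),
            class = c("rumour_trajectory", "data.frame"),
            mass_tol = mass_tol)
}

#' Check trajectory invariants
#'
#' Verifies that a trajectory conserves mass (x + y + z = 1 within `tol`)
#' and that all stored values are fractions (within `tol` of \[0, 1\]).
#'
#' @param traj A trajectory data frame with columns `t`, `x`, `y`, `z`.
#' @param tol Absolute tolerance.
#'
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_trajectory <- function(traj, tol = 1e-8) {
  stopifnot(all(c("t", "x", "y", "z") %in% names(traj)))
  mass <- traj$x + traj$y + traj$z
  if (any(abs(mass - 1) > tol)) {
    stop(sprintf("mass conservation violated (max |x+y+z-1| = %.3g)",
                 max(abs(mass - 1))), call. = FALSE)
  }
  vals <- c(traj$x, traj$y, traj$z)
  if (any(vals < -100 * tol) || any(vals > 1 + 100 * tol)) {
    stop("trajectory values outside [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a run configuration file
#'
#' Reads a YAML or JSON configuration with the standard keys `lambda`,
#' `alpha`, `x0`, `y0`, `z0`, `n`, `seed`, `reps`.  Commands may allow
#' additional keys via `extra_keys`; any other key is an error (fail loud).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param extra_keys Character vector of additional permitted keys.
#'
#' @return A named list of configuration values.
#' @export
read_rumour_config <- function(path, extra_keys = character()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML 1.1 reads a bare `n:` key as the boolean FALSE; restore it
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  allowed <- c("lambda", "alpha", "x0", "y0", "z0", "n", "seed", "reps",
               extra_keys)
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg
}
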