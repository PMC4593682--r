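# Final-size limit theorems for the complete-graph process:
# the limiting ignorant fraction x_inf (law of large numbers), the
# deterministic absorption time tau_inf = -(1/lambda) log(x_inf / x0),
# the CLT variance sigma^2 of sqrt(n) (X(tau)/n - x_inf), and the Gaussian
# covariance machinery from which sigma^2 can be re-derived.
#
# All root searches work in the log variable u = log(x0 / x) >= 0, where
#   g(u) = f(x0 exp(-u)) = 1 - z0 exp(rho u) - x0 exp(-u).
# This keeps the bracketed search well conditioned even when the root of f
# is many orders of magnitude below x0 (small rho), and makes the upper
# bracket end a simple geometric expansion.

# g(u) and a bracketed root search on [u_lo, expanding upper end].
.g_of_u <- function(u, params, init) {
  1 - init$z0 * exp(params$rho * u) - init$x0 * exp(-u)
}

.find_root_u <- function(params, init, u_lo, control) {
  g <- function(u) .g_of_u(u, params, init)
  u_hi <- max(1, 2 * u_lo)
  while (g(u_hi) > 0) {
    u_hi <- u_hi * 2
    if (u_hi > 1e6) {
      stop(sprintf(paste0("no sign change of f on the search bracket: ",
                          "f(lower) = %.6g, f(upper) = %.6g (rho = %g; the ",
                          "final-size equation needs alpha > 0 and z0 > 0)"),
                   g(u_lo), g(u_hi), params$rho), call. = FALSE)
    }
  }
  stats::uniroot(g, c(u_lo, u_hi), tol = control$root_xtol)$root
}

#' Limiting final fraction of ignorants
#'
#' The law of large numbers: X(tau)/n converges to x_inf, the root of
#' f(x) = 1 - z0 (x0/x)^rho - x in (0, x0].  Three cases arise:
#' if y0 > 0 the root is interior; if y0 = 0 and x0 > rho z0 the rumour
#' still takes off (the boundary root f(x0) = 0 is spurious) and the
#' interior root below x0 is returned; if y0 = 0 and x0 <= rho z0 the
#' process dies immediately and x_inf = x0.
#'
#' @inheritParams solve_mean_field
#'
#' @return A list with `x_inf` and `case` (`"interior_root"` or
#'   `"immediate_death"`).
#' @export
#' @examples
#' final_ignorant_fraction(make_params(0.5, 0.5), make_init(0.98, 0.01, 0.01))
final_ignorant_fraction <- function(params, init,
                                    control = rumour_control()) {
  stopifnot(inherits(params, "rumour_params"), inherits(init, "rumour_init"))
  if (init$y0 > 0) {
    u <- .find_root_u(params, init, u_lo = 0, control = control)
    return(list(x_inf = init$x0 * exp(-u), case = "interior_root"))
  }
  # y0 == 0: x0 is always a root of f; dispatch on the sign of f'(x0).
  if (init$x0 > params$rho * init$z0) {
    # g(0) = 0 and g'(0) = x0 - rho z0 > 0: step inward until g > 0, then
    # bracket the interior root above.
    u_lo <- 1e-8
    while (.g_of_u(u_lo, params, init) <= 0) {
      u_lo <- u_lo / 8
      if (u_lo < 1e-300) {
        stop("failed to separate the interior root from the boundary root",
             call. = FALSE)
      }
    }
    u <- .find_root_u(params, init, u_lo = u_lo, control = control)
    return(list(x_inf = init$x0 * exp(-u), case = "interior_root"))
  }
  list(x_inf = init$x0, case = "immediate_death")
}

#' Deterministic absorption time
#'
#' tau_inf = -(1/lambda) log(x_inf / x0); exactly 0 in the immediate-death
#' case.
#'
#' @inheritParams solve_mean_field
#' @return A single non-negative number.
#' @export
extinction_time <- function(params, init, control = rumour_control()) {
  fr <- final_ignorant_fraction(params, init, control)
  if (fr$case == "immediate_death") return(0)
  -log(fr$x_inf / init$x0) / params$lambda
}

# Shared hypothesis check for the CLT: y0 > 0, or y0 = 0 and rho < x0/z0.
.check_clt_hypotheses <- function(params, init) {
  if (init$y0 > 0) return(invisible(TRUE))
  if (params$rho < init$x0 / init$z0) return(invisible(TRUE))
  stop(paste0("CLT hypotheses violated: need y0 > 0, or y0 = 0 with ",
              "rho < x0/z0"), call. = FALSE)
}

#' Asymptotic variance of the final ignorant fraction
#'
#' The CLT states sqrt(n) (X(tau)/n - x_inf) => N(0, sigma^2) with
#'
#' sigma^2 = x_inf z_inf \[x0 x_inf (1 - z0 - x_inf) +
#'           z0 rho^2 z_inf (x0 - x_inf)\] /
#'           (x0 z0 \[rho - x_inf (rho + 1)\]^2),
#'
#' where z_inf = 1 - x_inf.  Valid when y0 > 0, or y0 = 0 and
#' rho < x0/z0.
#'
#' @inheritParams solve_mean_field
#' @return sigma^2, a single non-negative number.
#' @export
#' @examples
#' clt_variance(make_params(0.5, 0.5), make_init(0.98, 0.01, 0.01))
clt_variance <- function(params, init, control = rumour_control()) {
  stopifnot(inherits(params, "rumour_params"), inherits(init, "rumour_init"))
  .check_clt_hypotheses(params, init)
  x_inf <- final_ignorant_fraction(params, init, control)$x_inf
  z_inf <- 1 - x_inf
  rho <- params$rho
  denom_core <- rho - x_inf * (rho + 1)
  if (abs(denom_core) < 1e-10) {
    stop("degenerate CLT: rho - x_inf (rho + 1) is numerically zero",
         call. = FALSE)
  }
  x0 <- init$x0; z0 <- init$z0
  num <- x_inf * z_inf *
    (x0 * x_inf * (1 - z0 - x_inf) + z0 * rho^2 * z_inf * (x0 - x_inf))
  num / (x0 * z0 * denom_core^2)
}

#' Gaussian covariance matrix of the density-dependent fluctuations
#'
#' Evaluates Cov(V(tau_inf), V(tau_inf)) =
#' int_0^tau Phi(tau, s) G(x(s), y(s)) Phi(tau, s)^T ds by adaptive
#' quadrature along the closed-form deterministic path, where
#' G(x, y) = \[\[lambda x, -lambda x\], \[-lambda x,
#' (lambda - alpha) x - alpha y + alpha\]\] is the diffusion matrix of the
#' two jump directions and Phi(t, s) = exp(A (t - s)) for the constant
#' drift Jacobian A = \[\[-lambda, 0\], \[lambda + alpha, alpha\]\], with
#' entries Phi11 = e^(-lambda (t-s)), Phi21 = e^(alpha (t-s)) -
#' e^(-lambda (t-s)), Phi22 = e^(alpha (t-s)) used in closed form.
#'
#' @inheritParams solve_mean_field
#' @param abs_tol Absolute quadrature tolerance per matrix entry.
#'
#' @return A symmetric 2x2 matrix.
#' @export
covariance_matrix <- function(params, init, abs_tol = 1e-10,
                              control = rumour_control()) {
  stopifnot(inherits(params, "rumour_params"), inherits(init, "rumour_init"))
  .check_clt_hypotheses(params, init)
  tau <- extinction_time(params, init, control)
  if (tau == 0) return(matrix(0, 2, 2))
  lam <- params$lambda; alp <- params$alpha
  curve <- f_curve(params, init)
  integrand <- function(s, i, j) {
    xs <- init$x0 * exp(-lam * s)
    ys <- f_eval(curve, xs)
    g11 <- lam * xs
    g12 <- -lam * xs
    g22 <- (lam - alp) * xs - alp * ys + alp
    p11 <- exp(-lam * (tau - s))
    p22 <- exp(alp * (tau - s))
    p21 <- p22 - p11
    # (Phi G Phi^T)[i, j] with Phi = [[p11, 0], [p21, p22]]
    if (i == 1 && j == 1) {
      p11 * g11 * p11
    } else if (i == 2 && j == 2) {
      p21 * p21 * g11 + 2 * p21 * p22 * g12 + p22 * p22 * g22
    } else {
      p11 * (g11 * p21 + g12 * p22)
    }
  }
  quad <- function(i, j) {
    stats::integrate(function(s) vapply(s, integrand, numeric(1), i = i,
                                        j = j),
                     lower = 0, upper = tau,
                     abs.tol = abs_tol, rel.tol = abs_tol,
                     subdivisions = 500L)$value
  }
  c11 <- quad(1, 1); c12 <- quad(1, 2); c22 <- quad(2, 2)
  matrix(c(c11, c12, c12, c22), 2, 2)
}

#' CLT variance re-derived from the covariance matrix
#'
#' Independent route to sigma^2: the limiting fluctuation of the final
#' ignorant fraction is Vx(tau) + c Vy(tau) with
#' c = x_inf / ((1 + rho) x_inf - rho) (delta method at the hitting time of
#' y = 0, c = -x'(tau)/y'(tau)), so sigma^2 = C11 + 2 c C12 + c^2 C22.
#' Agrees with [clt_variance()] and serves as a numerical cross-check of
#' the closed formula.
#'
#' @inheritParams covariance_matrix
#' @return sigma^2 computed via quadrature.
#' @export
clt_variance_from_covariance <- function(params, init, abs_tol = 1e-10,
                                         control = rumour_control()) {
  x_inf <- final_ignorant_fraction(params, init, control)$x_inf
  cc <- x_inf / ((1 + params$rho) * x_inf - params$rho)
  C <- covariance_matrix(params, init, abs_tol, control)
  C[1, 1] + 2 * cc * C[1, 2] + cc^2 * C[2, 2]
}

#' Full asymptotic summary
#'
#' Collects the limit-theorem quantities: x_inf, z_inf = 1 - x_inf,
#' tau_inf, sigma^2 (NA when the CLT hypotheses fail) and the case label.
#'
#' @inheritParams solve_mean_field
#' @param n Optional population size; if supplied, the finite-n standard
#'   deviation sqrt(sigma^2 / n) of the final fraction is included.
#'
#' @return A list of class `asymptotic_summary`.
#' @export
#' @examples
#' asymptotic_summary(make_params(0.5, 0.5), make_init(0.98, 0.01, 0.01),
#'                    n = 1e4)
asymptotic_summary <- function(params, init, n = NULL,
                               control = rumour_control()) {
  fr <- final_ignorant_fraction(params, init, control)
  tau <- if (fr$case == "immediate_death") 0 else
    -log(fr$x_inf / init$x0) / params$lambda
  sigma2 <- tryCatch(clt_variance(params, init, control),
                     error = function(e) NA_real_)
  out <- list(x_inf = fr$x_inf, z_inf = 1 - fr$x_inf, tau_inf = tau,
              sigma2 = sigma2, case = fr$case)
  if (!is.null(n)) out$sd_final_fraction_at_n <- sqrt(sigma2 / n)
  structure(out, class = "asymptotic_summary")
}

#' @export
print.asymptotic_summary <- function(x, ...) {
  cat(sprintf("final-size asymptotics (%s):\n", x$case))
  cat(sprintf("  x_inf  = %.8g\n  z_inf  = %.8g\n  tau_inf = %.6g\n",
              x$x_inf, x$z_inf, x$tau_inf))
  cat(sprintf("  sigma2 = %.6g\n", x$sigma2))
  if (!is.null(x$sd_final_fraction_at_n)) {
    cat(sprintf("  sd of final fraction at n: %.6g\n",
                x$sd_final_fraction_at_n))
  }
  invisible(x)
}
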