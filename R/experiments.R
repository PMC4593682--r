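# Reproducible experiment drivers: CLT goodness of fit, (lambda, alpha)
# phase diagrams, Monte-Carlo-versus-QMF comparison, and ER/BA final-size
# distributions against the homogeneous theory.

#' Goodness of fit of the final-size CLT
#'
#' One-sample Kolmogorov-Smirnov test of simulated final ignorant
#' fractions against the theoretical Normal(x_inf, sigma^2 / n).
#'
#' @param final_fractions Numeric vector of final ignorant fractions
#'   (>= 100 samples).
#' @param params,init Model parameters and initial fractions.
#' @param n Population size the samples were generated at.
#'
#' @return A list: `ks_statistic`, `p_value`, `x_inf`, `sigma2`.
#' @export
clt_check <- function(final_fractions, params, init, n) {
  if (length(final_fractions) < 100) {
    stop("need at least 100 samples for the goodness-of-fit check",
         call. = FALSE)
  }
  x_inf <- final_ignorant_fraction(params, init)$x_inf
  sigma2 <- clt_variance(params, init)
  ks <- suppressWarnings(
    ks.test(final_fractions, "pnorm", mean = x_inf, sd = sqrt(sigma2 / n)))
  list(ks_statistic = unname(ks$statistic), p_value = ks$p.value,
       x_inf = x_inf, sigma2 = sigma2)
}

#' Final-size phase diagram over (lambda, alpha)
#'
#' Mean final ignorant fraction on a grid of rates, by default 0.05 to
#' 1.00 in steps of 0.05 (a 20 x 20 grid).  Engines: `"ode"` integrates
#' the mean-field system to spreader extinction (deterministic, one run
#' per cell); `"gillespie"` averages exact complete-graph replicates;
#' `"network"` averages discrete Monte Carlo replicates on a fixed graph.
#'
#' @param engine `"ode"`, `"gillespie"` or `"network"`.
#' @param init A [make_init()] object.
#' @param n Population size (gillespie engine).
#' @param network A `rumour_network` (network engine).
#' @param grid_start,grid_step,grid_end Rate grid specification, applied
#'   to both lambda and alpha.
#' @param reps Replicates per cell for the stochastic engines.
#' @param base_seed Base seed; each cell uses an offset stream.
#' @param max_steps Step cap for the network engine.
#'
#' @return A list of class `phase_diagram`: `lambda_grid`, `alpha_grid`,
#'   `mean_final_ignorant` (lambda rows x alpha columns), `non_absorbed`
#'   counts, `reps`, `engine`.
#' @export
phase_diagram <- function(engine = c("ode", "gillespie", "network"),
                          init = make_init(0.98, 0.01, 0.01),
                          n = NULL, network = NULL,
                          grid_start = 0.05, grid_step = 0.05,
                          grid_end = 1.0, reps = 50, base_seed = 1,
                          max_steps = 100000L) {
  engine <- match.arg(engine)
  lam_grid <- seq(grid_start, grid_end, by = grid_step)
  alp_grid <- lam_grid
  if (engine == "gillespie" && is.null(n)) {
    stop("the gillespie engine needs `n`", call. = FALSE)
  }
  if (engine == "network" && is.null(network)) {
    stop("the network engine needs `network`", call. = FALSE)
  }
  m <- matrix(NA_real_, length(lam_grid), length(alp_grid),
              dimnames = list(lambda = sprintf("%.2f", lam_grid),
                              alpha = sprintf("%.2f", alp_grid)))
  bad <- matrix(0L, length(lam_grid), length(alp_grid))
  cell_seed <- base_seed
  for (i in seq_along(lam_grid)) {
    for (j in seq_along(alp_grid)) {
      p <- make_params(lam_grid[i], alp_grid[j])
      if (engine == "ode") {
        m[i, j] <- mean_field_final_state(p, init)[["x"]]
      } else if (engine == "gillespie") {
        b <- batch_gillespie(n, p, init, reps, cell_seed)
        m[i, j] <- mean(b$final_ignorant_fraction)
        bad[i, j] <- sum(!b$absorbed)
      } else {
        b <- batch_network_mc(network, p, init, reps, cell_seed,
                              max_steps = max_steps)
        m[i, j] <- mean(b$final_ignorant_fraction)
        bad[i, j] <- sum(!b$absorbed)
      }
      cell_seed <- cell_seed + reps + 1L
    }
  }
  structure(list(lambda_grid = lam_grid, alpha_grid = alp_grid,
                 mean_final_ignorant = m, non_absorbed = bad,
                 reps = if (engine == "ode") 1L else as.integer(reps),
                 engine = engine),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("phase diagram (%s engine): %d x %d grid, %d rep(s)/cell\n",
              x$engine, length(x$lambda_grid), length(x$alpha_grid),
              x$reps))
  invisible(x)
}

#' Monte Carlo versus node-level ODE comparison
#'
#' Runs `reps` discrete Monte Carlo replicates on a network (uniform
#' seeding), averages the aggregate fractions on the common step grid
#' (replicates that absorb early are carried forward at their final
#' state), and pairs them with the scotching QMF aggregate evaluated at
#' the same step times.  One Monte Carlo step corresponds to one unit of
#' model time (each active node makes one contact trial per step).
#'
#' @param network A `rumour_network`.
#' @param params,init Model parameters and initial fractions.
#' @param reps Number of Monte Carlo replicates.
#' @param base_seed Base seed.
#' @param max_steps Step cap per replicate.
#'
#' @return A data frame `t`, `compartment`, `mc_mean`, `mc_sd`, `qmf`,
#'   `z_score` (QMF deviation in MC standard deviations).
#' @export
compare_sim_vs_qmf <- function(network, params, init, reps = 50,
                               base_seed = 1, max_steps = 100000L) {
  stopifnot(inherits(network, "rumour_network"))
  trajs <- vector("list", reps)
  for (r in seq_len(reps)) {
    states <- seed_states(network, init, "uniform", seed = base_seed + r)
    smp <- run_network_mc(network, states, params,
                          seed = base_seed + 500000L + r,
                          max_steps = max_steps, record_trajectory = TRUE)
    trajs[[r]] <- smp$trajectory
  }
  n_steps <- max(vapply(trajs, nrow, integer(1)))
  pad <- function(v) c(v, rep(v[length(v)], n_steps - length(v)))
  arr <- lapply(c("x", "y", "z"), function(cmp) {
    vapply(trajs, function(tr) pad(tr[[cmp]]), numeric(n_steps))
  })
  names(arr) <- c("x", "y", "z")
  steps <- 0:(n_steps - 1)
  qmf <- solve_scotching_qmf(network, params, init,
                             t_end = max(steps, 1),
                             n_points = max(n_steps, 2))
  agg <- aggregate_probs(qmf)[seq_len(n_steps), ]
  out <- do.call(rbind, lapply(c("x", "y", "z"), function(cmp) {
    mm <- rowMeans(arr[[cmp]])
    ss <- apply(arr[[cmp]], 1, sd)
    data.frame(t = steps, compartment = cmp, mc_mean = mm, mc_sd = ss,
               qmf = agg[[cmp]])
  }))
  out$z_score <- ifelse(out$mc_sd > 0,
                        (out$qmf - out$mc_mean) / out$mc_sd, 0)
  out
}

#' ER versus BA final-size distributions
#'
#' Runs the discrete Monte Carlo on matched Erdos-Renyi and
#' Barabasi-Albert graphs (same `n` and target mean degree) and returns
#' both final-sample sets together with the homogeneous-theory Gaussian
#' overlay (x_inf, sigma^2 / n).
#'
#' @param n Number of nodes.
#' @param mean_degree Target mean degree (ER uses p = mean_degree/(n-1),
#'   BA uses m = mean_degree/2).
#' @param params,init Model parameters and initial fractions.
#' @param reps Replicates per network.
#' @param base_seed Base seed.
#' @param max_steps Step cap per replicate.
#'
#' @return A list: `er`, `ba` (batch data frames), `x_inf`, `sigma2`,
#'   `sd_theory` (sqrt(sigma2/n)).
#' @export
er_ba_final_distribution <- function(n, mean_degree, params, init,
                                     reps = 200, base_seed = 1,
                                     max_steps = 100000L) {
  er <- gen_er(n, mean_degree / (n - 1), seed = base_seed)
  ba <- gen_ba(n, max(1, round(mean_degree / 2)), seed = base_seed + 1)
  b_er <- batch_network_mc(er, params, init, reps, base_seed + 10,
                           max_steps = max_steps)
  b_ba <- batch_network_mc(ba, params, init, reps,
                           base_seed + 10 + reps + 1,
                           max_steps = max_steps)
  x_inf <- final_ignorant_fraction(params, init)$x_inf
  sigma2 <- clt_variance(params, init)
  list(er = b_er, ba = b_ba, x_inf = x_inf, sigma2 = sigma2,
       sd_theory = sqrt(sigma2 / n))
}
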