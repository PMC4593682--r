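# Quenched mean-field (QMF) node-level ODEs on a fixed graph.
#
# Scotching model:
#   x_i' = -lambda x_i sum_j P[j,i] y_j
#   y_i' =  lambda x_i sum_j P[j,i] y_j - alpha y_i sum_j P[j,i] z_j
#   z_i' =  alpha  y_i sum_j P[j,i] z_j
#
# Maki-Thompson comparison model: the stifling sum uses the outgoing
# contact weights P[i,j] applied to (x_j + z_j), exactly as printed in the
# source dynamics; for undirected graphs A is symmetric but unequal
# degrees make P[i,j] != P[j,i], so the index order matters and a switch
# is provided to flip it for sensitivity analysis.
#
# The incidence structure is kept sparse, so each derivative evaluation
# costs O(|E|).

.qmf_integrate <- function(P, params, init_mat, times, model, control,
                           mt_index_order = "as_printed") {
  n <- nrow(init_mat)
  lam <- params$lambda
  alp <- params$alpha
  Pt <- Matrix::t(P)  # Pt %*% v = incoming sums: (Pt v)_i = sum_j P[j,i] v_j
  rhs <- function(t, state, parms) {
    x <- state[1:n]; y <- state[(n + 1):(2 * n)]; z <- state[(2 * n + 1):(3 * n)]
    spread <- as.numeric(Pt %*% y)
    stifle <- switch(model,
      scotch = as.numeric(Pt %*% z),
      mt = if (mt_index_order == "as_printed") as.numeric(P %*% (x + z))
           else as.numeric(Pt %*% (x + z)))
    dx <- -lam * x * spread
    dz <- alp * y * stifle
    list(c(dx, -dx - dz, dz))
  }
  state0 <- c(init_mat[, 1], init_mat[, 2], init_mat[, 3])
  sol <- deSolve::ode(y = state0, times = times, func = rhs, parms = NULL,
                      method = "adams",
                      rtol = control$ode_rtol, atol = control$ode_atol)
  if (nrow(sol) < length(times)) {
    stop(sprintf("QMF integration failed after t = %.6g", sol[nrow(sol), 1]),
         call. = FALSE)
  }
  structure(list(times = sol[, 1],
                 x = sol[, 2:(n + 1), drop = FALSE],
                 y = sol[, (n + 2):(2 * n + 1), drop = FALSE],
                 z = sol[, (2 * n + 2):(3 * n + 1), drop = FALSE],
                 model = model),
            class = "node_probabilities")
}

# Normalise the per-node initial probabilities argument.
.qmf_init_mat <- function(network, init, init_probs) {
  n <- network$n
  if (is.null(init_probs)) {
    init_probs <- matrix(c(init$x0, init$y0, init$z0), nrow = n, ncol = 3,
                         byrow = TRUE)
  }
  init_probs <- as.matrix(init_probs)
  if (nrow(init_probs) != n || ncol(init_probs) != 3) {
    stop("`init_probs` must be an n x 3 matrix of (x, y, z) triples",
         call. = FALSE)
  }
  if (any(abs(rowSums(init_probs) - 1) > 1e-10) || any(init_probs < 0)) {
    stop("each row of `init_probs` must be a probability triple summing to 1",
         call. = FALSE)
  }
  init_probs
}

#' Node-level ODEs for the scotching model
#'
#' Integrates the 3n-dimensional quenched mean-field system for the
#' probabilities that each node is ignorant, spreader or stifler.
#'
#' @param network A `rumour_network` with at least one edge.
#' @param params A [make_params()] object.
#' @param init A [make_init()] object; every node starts from the uniform
#'   triple (x0, y0, z0) unless `init_probs` is given.
#' @param t_end Final time.
#' @param n_points Number of output times.
#' @param init_probs Optional n x 3 matrix of per-node initial triples
#'   (for seeding experiments).
#' @param control A [rumour_control()] object.
#'
#' @return A `node_probabilities` object: `times` plus n-column matrices
#'   `x`, `y`, `z` (rows = times).
#' @export
#' @examples
#' net <- gen_er(100, 0.1, seed = 1)
#' pr <- solve_scotching_qmf(net, make_params(0.2, 0.1),
#'                           make_init(0.98, 0.01, 0.01), t_end = 30)
solve_scotching_qmf <- function(network, params, init, t_end,
                                n_points = 101, init_probs = NULL,
                                control = rumour_control()) {
  stopifnot(inherits(network, "rumour_network"),
            inherits(params, "rumour_params"))
  if (nrow(network$edges) < 1) stop("network has no edges", call. = FALSE)
  im <- .qmf_init_mat(network, init, init_probs)
  times <- seq(0, t_end, length.out = n_points)
  .qmf_integrate(contact_weights(network), params, im, times, "scotch",
                 control)
}

#' Node-level ODEs for the Maki-Thompson model
#'
#' Same spreading term as the scotching model, but a spreader is stifled
#' through its own contacts with already-informed nodes:
#' the stifling sum is alpha y_i sum_j P\[i, j\] (x_j + z_j).
#'
#' @inheritParams solve_scotching_qmf
#' @param mt_index_order `"as_printed"` uses the outgoing weights P\[i, j\]
#'   in the stifling sum; `"flipped"` uses incoming weights P\[j, i\]
#'   (sensitivity analysis).
#'
#' @return A `node_probabilities` object.
#' @export
solve_mt_qmf <- function(network, params, init, t_end, n_points = 101,
                         init_probs = NULL,
                         mt_index_order = c("as_printed", "flipped"),
                         control = rumour_control()) {
  stopifnot(inherits(network, "rumour_network"),
            inherits(params, "rumour_params"))
  mt_index_order <- match.arg(mt_index_order)
  if (nrow(network$edges) < 1) stop("network has no edges", call. = FALSE)
  im <- .qmf_init_mat(network, init, init_probs)
  times <- seq(0, t_end, length.out = n_points)
  .qmf_integrate(contact_weights(network), params, im, times, "mt",
                 control, mt_index_order)
}

#' Aggregate node probabilities to population fractions
#'
#' @param probs A `node_probabilities` object.
#' @return A trajectory data frame with per-time means across nodes.
#' @export
aggregate_probs <- function(probs) {
  stopifnot(inherits(probs, "node_probabilities"))
  new_trajectory(probs$times, rowMeans(probs$x), rowMeans(probs$y),
                 rowMeans(probs$z), mass_tol = 1e-8)
}

#' Final ignorant fraction from the node-level ODEs
#'
#' Integrates the scotching QMF system in chunks until the aggregate
#' spreader fraction drops below `y_floor` (hard cap t = 1e6 / lambda),
#' then returns the aggregate ignorant fraction.  If the cap is reached
#' first, the result carries a warning.
#'
#' @inheritParams solve_scotching_qmf
#' @param y_floor Aggregate spreader threshold treated as extinction.
#'
#' @return The final aggregate ignorant fraction.
#' @export
final_ignorants_qmf <- function(network, params, init, init_probs = NULL,
                                y_floor = 1e-7,
                                control = rumour_control()) {
  stopifnot(inherits(network, "rumour_network"))
  im <- .qmf_init_mat(network, init, init_probs)
  if (mean(im[, 2]) <= y_floor) return(mean(im[, 1]))
  t_cap <- 1e6 / params$lambda
  chunk <- 50 / params$lambda
  t0 <- 0
  repeat {
    t1 <- min(t0 + chunk, t_cap)
    pr <- .qmf_integrate(contact_weights(network), params, im,
                         times = seq(t0, t1, length.out = 21),
                         "scotch", control)
    last <- length(pr$times)
    im <- cbind(pr$x[last, ], pr$y[last, ], pr$z[last, ])
    im[im < 0] <- 0
    if (mean(im[, 2]) < y_floor) break
    t0 <- t1
    if (t0 >= t_cap) {
      warning("time cap reached before spreader extinction")
      break
    }
  }
  mean(im[, 1])
}
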