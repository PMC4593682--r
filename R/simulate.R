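# Stochastic simulation front ends.
#
# Two engines with deliberately distinct parameter contracts: the exact
# Gillespie chain treats lambda and alpha as continuous rates (any
# positive value), while the discrete asynchronous network scheme treats
# them as per-trial success probabilities and therefore requires values in
# [0, 1].  Each replicate owns its seed, so batches are reproducible
# regardless of execution order.

#' Exact Gillespie simulation on the complete graph
#'
#' Event-driven simulation of the counts chain: with total rate
#' R = lambda X Y + alpha Y Z, waiting times are exponential(R) and the
#' next event is a spreading step (X-1, Y+1) with probability
#' lambda X Y / R, else a scotching step (Y-1, Z+1).  Terminates when the
#' total rate vanishes.
#'
#' @param n Population size (>= 3).
#' @param params A [make_params()] object (rates; any positive values).
#' @param init_counts A [counts_from_fractions()] object with matching `n`.
#' @param seed RNG seed for this replicate (`NULL` = current stream).
#' @param record_trajectory Also return the full event trajectory?
#'
#' @return A list of class `final_sample`: `final_ignorant_fraction`,
#'   `absorption_time`, `absorbed`, `final_counts`, `seed`, and optionally
#'   `trajectory` (fractions at event times).
#' @export
#' @examples
#' cc <- counts_from_fractions(1000, make_init(0.98, 0.01, 0.01))
#' gillespie_complete(1000, make_params(0.5, 0.5), cc, seed = 1)
gillespie_complete <- function(n, params, init_counts, seed = NULL,
                               record_trajectory = FALSE) {
  stopifnot(inherits(params, "rumour_params"),
            inherits(init_counts, "rumour_counts"))
  if (init_counts$n != n) stop("`n` does not match `init_counts$n`",
                               call. = FALSE)
  if (n < 3) stop("`n` must be >= 3", call. = FALSE)
  res <- with_seed(seed, gillespie_complete_cpp(
    params$lambda, params$alpha,
    init_counts$X, init_counts$Y, init_counts$Z, record_trajectory))
  out <- list(final_ignorant_fraction = res$X / n,
              absorption_time = res$time,
              absorbed = res$absorbed,
              final_counts = c(X = res$X, Y = res$Y, Z = res$Z),
              seed = if (is.null(seed)) NA_integer_ else seed)
  if (record_trajectory) {
    tt <- res$traj_t
    keep <- !duplicated(tt)
    out$trajectory <- new_trajectory(tt[keep], res$traj_X[keep] / n,
                                     res$traj_Y[keep] / n,
                                     res$traj_Z[keep] / n)
  }
  structure(out, class = "final_sample")
}

#' Discrete asynchronous Monte Carlo on a network
#'
#' Implements the sequential asynchronous contact scheme: at each step the
#' nodes that are spreaders or stiflers at step start are visited in a
#' fresh uniform shuffle; each visited node (using its current state)
#' contacts one uniformly chosen neighbour, a spreader converting an
#' ignorant with probability `lambda` and a stifler converting a spreader
#' with probability `alpha`.  Updates apply immediately.
#'
#' @param network A `rumour_network`, or `NULL` when `complete_n` is given.
#' @param states Integer vector of initial node states (0 ignorant,
#'   1 spreader, 2 stifler), e.g. from [seed_states()].
#' @param params A [make_params()] object with `lambda`, `alpha` in
#'   \[0, 1\] (per-trial probabilities).
#' @param seed RNG seed for this replicate.
#' @param max_steps Step cap; reaching it with live spreaders flags the
#'   result as non-absorbed.
#' @param record_trajectory Also return the per-step aggregate trajectory?
#' @param complete_n If non-`NULL`, run on the complete graph of this many
#'   nodes without materialising its edges.
#'
#' @return A `final_sample` list (absorption time reported in steps), with
#'   `final_states` and optionally `trajectory`.
#' @export
run_network_mc <- function(network, states, params, seed = NULL,
                           max_steps = 100000L, record_trajectory = FALSE,
                           complete_n = NULL) {
  stopifnot(inherits(params, "rumour_params"))
  if (params$lambda > 1 || params$alpha > 1) {
    stop(paste0("the discrete scheme interprets lambda and alpha as ",
                "per-trial probabilities; both must be in [0, 1]"),
         call. = FALSE)
  }
  if (is.null(complete_n)) {
    stopifnot(inherits(network, "rumour_network"))
    n <- network$n
    adj <- csr_adjacency(network)
    complete <- FALSE
  } else {
    n <- as.integer(complete_n)
    adj <- list(ptr = integer(n + 1), idx = integer(0))
    complete <- TRUE
  }
  states <- as.integer(states)
  if (length(states) != n || any(!states %in% 0:2)) {
    stop("`states` must be a length-n vector with values in {0, 1, 2}",
         call. = FALSE)
  }
  res <- with_seed(seed, run_network_mc_cpp(
    adj$ptr, adj$idx, states, params$lambda, params$alpha,
    as.integer(max_steps), record_trajectory, complete))
  out <- list(final_ignorant_fraction = res$X / n,
              absorption_time = res$steps,
              absorbed = res$absorbed,
              final_counts = c(X = res$X, Y = res$Y, Z = res$Z),
              final_states = res$final_states,
              seed = if (is.null(seed)) NA_integer_ else seed)
  if (record_trajectory) {
    steps <- seq_along(res$traj_X) - 1
    out$trajectory <- new_trajectory(steps, res$traj_X / n, res$traj_Y / n,
                                     res$traj_Z / n)
  }
  structure(out, class = "final_sample")
}

#' Initial node states under a seeding strategy
#'
#' Converts fractions to counts with [counts_from_fractions()] and places
#' them: `uniform` assigns states by a random permutation;
#' `hub_spreaders` makes the Y0 highest-degree nodes spreaders (ties by
#' node id) and scatters stiflers uniformly over the rest;
#' `hub_stiflers` is the symmetric case.
#'
#' @param network A `rumour_network`.
#' @param init A [make_init()] object.
#' @param strategy One of `"uniform"`, `"hub_spreaders"`, `"hub_stiflers"`.
#' @param seed RNG seed.
#'
#' @return Integer vector of node states (0/1/2).
#' @export
seed_states <- function(network, init,
                        strategy = c("uniform", "hub_spreaders",
                                     "hub_stiflers"),
                        seed = NULL) {
  stopifnot(inherits(network, "rumour_network"))
  strategy <- match.arg(strategy)
  cc <- counts_from_fractions(network$n, init)
  n <- network$n
  if (strategy != "uniform" && (cc$Y == 0 || cc$Z == 0)) {
    stop("hub strategies need at least one spreader and one stifler",
         call. = FALSE)
  }
  with_seed(seed, {
    states <- integer(n)
    if (strategy == "uniform") {
      perm <- sample.int(n)
      states[perm[seq_len(cc$Y)]] <- 1L
      states[perm[cc$Y + seq_len(cc$Z)]] <- 2L
    } else {
      # highest-degree nodes first, ties broken by node id (0-based)
      hubs <- order(-network$degrees, seq_len(n) - 1)
      if (strategy == "hub_spreaders") {
        states[hubs[seq_len(cc$Y)]] <- 1L
        rest <- setdiff(seq_len(n), hubs[seq_len(cc$Y)])
        states[sample(rest, cc$Z)] <- 2L
      } else {
        states[hubs[seq_len(cc$Z)]] <- 2L
        rest <- setdiff(seq_len(n), hubs[seq_len(cc$Z)])
        states[sample(rest, cc$Y)] <- 1L
      }
    }
    states
  })
}

#' Batch replication
#'
#' Runs `run_fn(seed)` for seeds `base_seed + 1, ..., base_seed + reps`,
#' one independent seeded RNG stream per replicate, and collects the final
#' samples.
#'
#' @param reps Number of replicates (>= 1).
#' @param base_seed Base seed; replicate r uses `base_seed + r`.
#' @param run_fn Function of one argument (the seed) returning a
#'   `final_sample`.
#'
#' @return A data frame `replicate`, `seed`, `final_ignorant_fraction`,
#'   `absorption_time`, `absorbed`, with a `summary` attribute (mean,
#'   variance, count).
#' @export
run_batch <- function(reps, base_seed, run_fn) {
  stopifnot(reps >= 1)
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    s <- base_seed + r
    smp <- tryCatch(run_fn(s), error = function(e) {
      stop(sprintf("replicate %d (seed %d) failed: %s", r, s,
                   conditionMessage(e)), call. = FALSE)
    })
    rows[[r]] <- data.frame(replicate = r, seed = s,
                            final_ignorant_fraction =
                              smp$final_ignorant_fraction,
                            absorption_time = smp$absorption_time,
                            absorbed = smp$absorbed)
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(
    mean = mean(out$final_ignorant_fraction),
    variance = var(out$final_ignorant_fraction),
    count = reps)
  out
}

#' @rdname run_batch
#' @inheritParams gillespie_complete
#' @param init A [make_init()] object.
#' @export
batch_gillespie <- function(n, params, init, reps, base_seed) {
  cc <- counts_from_fractions(n, init)
  run_batch(reps, base_seed, function(s) {
    gillespie_complete(n, params, cc, seed = s)
  })
}

#' @rdname run_batch
#' @inheritParams run_network_mc
#' @param strategy Seeding strategy passed to [seed_states()].
#' @export
batch_network_mc <- function(network, params, init, reps, base_seed,
                             strategy = "uniform", max_steps = 100000L) {
  run_batch(reps, base_seed, function(s) {
    states <- seed_states(network, init, strategy, seed = s)
    run_network_mc(network, states, params, seed = s + 500000L,
                   max_steps = max_steps)
  })
}
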