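# Shared fixtures and independent oracles used across the test files.

canonical_params <- function() make_params(0.5, 0.5)
canonical_init <- function() make_init(0.98, 0.01, 0.01)

# For rho = 1 the final-size equation f(x) = 1 - z0 x0 / x - x = 0 is a
# quadratic, x^2 - x + z0 x0 = 0; the limiting ignorant fraction is the
# smaller root.
quadratic_x_inf <- function(x0, z0) (1 - sqrt(1 - 4 * z0 * x0)) / 2

# Random valid initial fractions with x0 >= x0_min and y0, z0 > 0.
random_init <- function(x0_min = 0.5) {
  x0 <- runif(1, x0_min, 0.985)
  y0 <- runif(1, 0.005, (1 - x0) / 2)
  make_init(x0, y0, 1 - x0 - y0)
}

# Independent node-level exact CTMC on the complete graph, written naively
# over labelled nodes: competing exponentials via the embedded jump chain.
# Deliberately separate from the package's count-based Gillespie engine.
node_level_ctmc_final <- function(n, lambda, alpha, states) {
  repeat {
    X <- sum(states == 0L); Y <- sum(states == 1L); Z <- sum(states == 2L)
    r_spread <- lambda * X * Y
    r_scotch <- alpha * Y * Z
    if (r_spread + r_scotch <= 0) break
    if (runif(1) * (r_spread + r_scotch) < r_spread) {
      ig <- which(states == 0L)
      states[ig[sample.int(length(ig), 1)]] <- 1L
    } else {
      sp <- which(states == 1L)
      states[sp[sample.int(length(sp), 1)]] <- 2L
    }
  }
  sum(states == 0L) / n
}
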