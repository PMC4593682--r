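test_that("Gillespie edge cases terminate exactly as the chain dictates", {
  i <- make_init(0.9, 0, 0.1)
  cc <- counts_from_fractions(100, i)
  # no spreaders: absorbing from the start
  s <- gillespie_complete(100, make_params(0.5, 0.5), cc, seed = 1)
  expect_equal(s$final_ignorant_fraction, 0.9)
  expect_equal(s$absorption_time, 0)
  expect_true(s$absorbed)
  # alpha = 0 with live spreaders: every ignorant is eventually informed
  cc <- counts_from_fractions(100, make_init(0.98, 0.01, 0.01))
  s <- gillespie_complete(100, make_params(0.5, 0), cc, seed = 1)
  expect_equal(s$final_counts[["X"]], 0)
  expect_false(s$absorbed)  # spreaders stand when the total rate hits zero
})

test_that("Gillespie runs are reproducible and conserve population", {
  p <- canonical_params()
  i <- canonical_init()
  cc <- counts_from_fractions(500, i)
  a <- gillespie_complete(500, p, cc, seed = 77, record_trajectory = TRUE)
  b <- gillespie_complete(500, p, cc, seed = 77, record_trajectory = TRUE)
  expect_identical(a$final_counts, b$final_counts)
  expect_identical(a$trajectory, b$trajectory)
  check_trajectory(a$trajectory)
  expect_equal(sum(a$final_counts), 500)
  expect_equal(a$final_counts[["Y"]], 0)
  # trajectory monotonicity: X never increases, Z never decreases
  expect_true(all(diff(a$trajectory$x) <= 0))
  expect_true(all(diff(a$trajectory$z) >= 0))
})

test_that("network Monte Carlo respects one-way state flow", {
  net <- gen_er(300, 0.05, seed = 10)
  p <- make_params(0.5, 0.5)
  i <- canonical_init()
  st0 <- seed_states(net, i, "uniform", seed = 11)
  s <- run_network_mc(net, st0, p, seed = 12, record_trajectory = TRUE)
  # 0 -> 1 -> 2 only: no final state below the initial one
  expect_true(all(s$final_states >= st0))
  expect_true(all(diff(s$trajectory$x) <= 0))
  expect_true(all(diff(s$trajectory$z) >= 0))
  expect_true(s$absorbed)
  expect_equal(s$final_counts[["Y"]], 0)
  # lambda = 0: ignorants can never be informed
  s0 <- run_network_mc(net, st0, make_params(1e-12, 0.5), seed = 12)
  expect_equal(s0$final_counts[["X"]], sum(st0 == 0))
  # probabilities above 1 are rejected (rates belong to the exact engine)
  expect_error(run_network_mc(net, st0, make_params(1.5, 0.5), seed = 1),
               "per-trial probabilities")
})

test_that("seeding strategies place the right counts in the right places", {
  i <- canonical_init()
  net <- gen_ba(1000, 4, seed = 13)
  st <- seed_states(net, i, "uniform", seed = 14)
  expect_equal(unname(table(factor(st, levels = 0:2))), c(980L, 10L, 10L),
               ignore_attr = TRUE)
  # hub spreaders: the Y0 highest-degree nodes are the spreaders
  st <- seed_states(net, i, "hub_spreaders", seed = 14)
  hubs <- order(-net$degrees)[1:10]
  expect_true(all(st[hubs] == 1L))
  expect_equal(sum(st == 2L), 10L)
  # star graph: the centre is the single spreader
  star_path <- withr::local_tempfile()
  writeLines(c("# n = 10", paste(0, 1:9)), star_path)
  star <- read_edgelist(star_path)
  st <- seed_states(star, make_init(0.8, 0.1, 0.1), "hub_spreaders",
                    seed = 15)
  expect_equal(st[1], 1L)
  # no spreaders or stiflers to pin: hub strategies refuse
  expect_error(seed_states(net, make_init(0.99, 0, 0.01), "hub_spreaders"),
               "at least one")
})

test_that("batches are deterministic and embarrassingly reproducible", {
  p <- canonical_params()
  i <- canonical_init()
  b1 <- batch_gillespie(200, p, i, reps = 5, base_seed = 30)
  b2 <- batch_gillespie(200, p, i, reps = 5, base_seed = 30)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 5)
  expect_equal(b1$seed, 31:35)
  # reps = 1 reproduces a single seeded run exactly
  single <- gillespie_complete(200, p, counts_from_fractions(200, i),
                               seed = 31)
  expect_equal(b1$final_ignorant_fraction[1],
               single$final_ignorant_fraction)
  s <- attr(b1, "summary")
  expect_equal(s$mean, mean(b1$final_ignorant_fraction))
})

test_that("count-based and node-level exact simulations agree in law", {
  # dual route: the package's aggregate Gillespie engine versus a naive
  # node-level CTMC written independently in the test helpers
  p <- canonical_params()
  i <- canonical_init()
  n <- 200
  cc <- counts_from_fractions(n, i)
  pkg <- batch_gillespie(n, p, i, reps = 500, base_seed = 42)
  set.seed(4242)
  st0 <- c(rep(0L, cc$X), rep(1L, cc$Y), rep(2L, cc$Z))
  oracle <- replicate(500, node_level_ctmc_final(n, p$lambda, p$alpha, st0))
  ks <- suppressWarnings(
    ks.test(pkg$final_ignorant_fraction, oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("degree-rescaled dynamics approach the homogeneous prediction", {
  # on random regular graphs, per-trial probabilities lambda/k, alpha/k
  # reproduce the rate-(lambda, alpha) homogeneous final size as the graph
  # gets denser; at low degree a small sparse-graph deficit remains
  p <- canonical_params()
  i <- canonical_init()
  x_inf <- final_ignorant_fraction(p, i)$x_inf
  dev_for_k <- function(k, reps) {
    net <- gen_regular(2000, k, seed = 42)
    pt <- make_params(p$lambda / k, p$alpha / k)
    b <- batch_network_mc(net, pt, i, reps = reps, base_seed = 42)
    c(dev = mean(b$final_ignorant_fraction) - x_inf,
      se = sd(b$final_ignorant_fraction) / sqrt(reps))
  }
  sparse <- dev_for_k(20, 40)
  dense <- dev_for_k(100, 40)
  expect_lt(abs(sparse[["dev"]]), 0.002)            # close in absolute terms
  expect_lt(abs(dense[["dev"]]), 3 * dense[["se"]]) # indistinguishable when dense
  expect_lt(abs(dense[["dev"]]), abs(sparse[["dev"]]))
})
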