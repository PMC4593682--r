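test_that("node-level ODEs conserve mass per node and are monotone", {
  net <- gen_er(200, 10 / 199, seed = 8)
  p <- make_params(0.2, 0.1)
  i <- canonical_init()
  pr <- solve_scotching_qmf(net, p, i, t_end = 40, n_points = 41)
  mass <- pr$x + pr$y + pr$z
  expect_lt(max(abs(mass - 1)), 1e-8)
  expect_true(all(apply(pr$x, 2, function(v) all(diff(v) <= 1e-10))))
  expect_true(all(apply(pr$z, 2, function(v) all(diff(v) >= -1e-10))))
  agg <- aggregate_probs(pr)
  check_trajectory(agg)
})

test_that("no initial spreaders freezes the node-level system", {
  net <- gen_er(50, 0.2, seed = 8)
  pr <- solve_scotching_qmf(net, make_params(0.5, 0.5),
                            make_init(0.9, 0, 0.1), t_end = 10,
                            n_points = 11)
  expect_equal(max(abs(sweep(pr$x, 2, pr$x[1, ]))), 0, tolerance = 1e-10)
  expect_equal(final_ignorants_qmf(net, make_params(0.5, 0.5),
                                   make_init(0.9, 0, 0.1)), 0.9)
})

test_that("complete-graph node equations reduce to the homogeneous system", {
  n <- 200
  p <- canonical_params()
  i <- canonical_init()
  pr <- solve_scotching_qmf(gen_complete(n), p, i, t_end = 30,
                            n_points = 61)
  # identical nodes stay identical
  expect_lt(max(apply(pr$x, 1, function(v) diff(range(v)))), 1e-10)
  agg <- aggregate_probs(pr)
  mf <- solve_mean_field(p, i, t_end = 30, n_points = 61)
  dev <- max(abs(agg$x - mf$x), abs(agg$y - mf$y), abs(agg$z - mf$z))
  expect_lt(dev, 2 / n)
})

test_that("node probabilities are more heterogeneous on BA than on ER", {
  p <- make_params(0.2, 0.1)
  i <- canonical_init()
  er <- gen_er(500, 10 / 499, seed = 42)
  ba <- gen_ba(500, 5, seed = 42)
  qe <- solve_scotching_qmf(er, p, i, t_end = 40, n_points = 41)
  qb <- solve_scotching_qmf(ba, p, i, t_end = 40, n_points = 41)
  tmid <- 21  # t = 20, mid-dynamics
  expect_gt(var(qb$z[tmid, ]), var(qe$z[tmid, ]))
  expect_gt(var(qb$y[tmid, ]), var(qe$y[tmid, ]))
})

test_that("hubs become stiflers earlier on BA networks", {
  p <- make_params(0.2, 0.1)
  ba <- gen_ba(1000, 50, seed = 42)
  pr <- solve_scotching_qmf(ba, p, canonical_init(), t_end = 60,
                            n_points = 121)
  crossing <- apply(pr$z, 2, function(zz) pr$times[which(zz >= 0.5)[1]])
  ok <- !is.na(crossing)
  expect_gt(sum(ok), 30)
  rho_s <- suppressWarnings(
    cor(ba$degrees[ok], crossing[ok], method = "spearman"))
  expect_lt(rho_s, 0)
})

test_that("Maki-Thompson variant coincides with scotching when alpha = 0", {
  net <- gen_er(100, 0.1, seed = 5)
  p <- make_params(0.3, 0)
  i <- canonical_init()
  a <- solve_scotching_qmf(net, p, i, t_end = 20, n_points = 21)
  b <- solve_mt_qmf(net, p, i, t_end = 20, n_points = 21)
  expect_lt(max(abs(a$x - b$x), abs(a$y - b$y), abs(a$z - b$z)), 1e-8)
})

test_that("the spreader peak is lower under Maki-Thompson stifling", {
  net <- gen_er(300, 10 / 299, seed = 42)
  p <- make_params(0.2, 0.1)
  i <- canonical_init()
  sc <- aggregate_probs(solve_scotching_qmf(net, p, i, t_end = 60,
                                            n_points = 121))
  mt <- aggregate_probs(solve_mt_qmf(net, p, i, t_end = 60,
                                     n_points = 121))
  expect_lt(max(mt$y), max(sc$y))
  # the index-order switch changes the MT solution on irregular graphs
  mt2 <- aggregate_probs(solve_mt_qmf(net, p, i, t_end = 60,
                                      n_points = 121,
                                      mt_index_order = "flipped"))
  expect_gt(max(abs(mt$y - mt2$y)), 1e-6)
})

test_that("per-node initial probabilities are validated", {
  net <- gen_er(50, 0.2, seed = 5)
  p <- canonical_params()
  i <- canonical_init()
  bad <- matrix(0.5, nrow = 50, ncol = 3)
  expect_error(solve_scotching_qmf(net, p, i, 10, init_probs = bad),
               "summing to 1")
  expect_error(solve_scotching_qmf(net, p, i, 10,
                                   init_probs = matrix(1, 10, 3)),
               "n x 3")
})
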