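test_that("final ignorant fraction matches the quadratic closed form at rho = 1", {
  # rho = 1 makes f(x) = 0 a quadratic with closed-form roots: use it as
  # an independent oracle across random initial conditions
  set.seed(7)
  for (rep in 1:100) {
    i <- random_init(0.3)
    p <- make_params(runif(1, 0.05, 1), 0)
    p <- make_params(p$lambda, p$lambda)  # alpha = lambda, rho = 1
    fr <- final_ignorant_fraction(p, i)
    expect_equal(fr$case, "interior_root")
    expect_equal(fr$x_inf, quadratic_x_inf(i$x0, i$z0), tolerance = 1e-10)
  }
  fr <- final_ignorant_fraction(canonical_params(), canonical_init())
  expect_equal(fr$x_inf, 0.0098980, tolerance = 1e-5)
})

test_that("the y0 = 0 case analysis is honoured", {
  p <- make_params(0.5, 0.5)  # rho = 1
  # x0 <= rho z0: immediate death, x_inf = x0 and tau_inf = 0 exactly
  i <- make_init(0.4, 0, 0.6)
  fr <- final_ignorant_fraction(p, i)
  expect_identical(fr$case, "immediate_death")
  expect_identical(fr$x_inf, 0.4)
  expect_identical(extinction_time(p, i), 0)
  # x0 > rho z0: the boundary root x0 is spurious; the interior root is
  # found below it (quadratic oracle: roots 0.9 and 0.1)
  i <- make_init(0.9, 0, 0.1)
  fr <- final_ignorant_fraction(p, i)
  expect_identical(fr$case, "interior_root")
  expect_equal(fr$x_inf, 0.1, tolerance = 1e-9)
})

test_that("rho = 0 with live spreaders has no final-size root and says so", {
  expect_error(
    final_ignorant_fraction(make_params(0.5, 0), canonical_init()),
    "no sign change")
})

test_that("x_inf is strictly increasing in rho", {
  i <- canonical_init()
  xs <- vapply(seq(0.1, 3, by = 0.1), function(r) {
    final_ignorant_fraction(make_params(1, r), i)$x_inf
  }, numeric(1))
  expect_true(all(diff(xs) > 0))
})

test_that("extinction time matches both its formula and the ODE crossing", {
  p <- canonical_params()
  i <- canonical_init()
  tau <- extinction_time(p, i)
  expect_equal(tau, -2 * log(0.0098980 / 0.98), tolerance = 1e-4)
  # event-located zero of y in the transformed system as oracle
  tr <- solve_transformed(p, i, t_end = 3 * tau, n_points = 300,
                          stop_at_zero = TRUE)
  expect_equal(tr$t[nrow(tr)], tau, tolerance = 1e-6)
})

test_that("the CLT variance formula is internally consistent", {
  p <- canonical_params()
  i <- canonical_init()
  s2 <- clt_variance(p, i)
  expect_equal(s2, 0.0199, tolerance = 0.005)
  # quadrature route through the covariance matrix agrees to 1e-6
  expect_equal(clt_variance_from_covariance(p, i), s2, tolerance = 1e-6)
  # ... and for other parameter values
  set.seed(3)
  for (rep in 1:5) {
    pp <- make_params(runif(1, 0.1, 1), runif(1, 0.1, 1))
    ii <- random_init(0.6)
    expect_equal(clt_variance_from_covariance(pp, ii),
                 clt_variance(pp, ii), tolerance = 1e-6)
  }
})

test_that("CLT preconditions are enforced", {
  # y0 = 0 with rho >= x0/z0 is outside the theorem's hypotheses
  expect_error(clt_variance(make_params(0.5, 0.5), make_init(0.4, 0, 0.6)),
               "hypotheses")
  expect_error(covariance_matrix(make_params(0.5, 0.5),
                                 make_init(0.4, 0, 0.6)),
               "hypotheses")
})

test_that("the covariance matrix is symmetric with the known (1,1) entry", {
  p <- canonical_params()
  i <- canonical_init()
  C <- covariance_matrix(p, i)
  expect_equal(C[1, 2], C[2, 1], tolerance = 1e-10)
  x_inf <- final_ignorant_fraction(p, i)$x_inf
  expect_equal(C[1, 1], x_inf - x_inf^2 / i$x0, tolerance = 1e-8)
  # positive semidefinite
  expect_true(all(eigen(C, symmetric = TRUE)$values > -1e-8))
})

test_that("the asymptotic summary collects consistent quantities", {
  s <- asymptotic_summary(canonical_params(), canonical_init(), n = 1e4)
  expect_equal(s$z_inf, 1 - s$x_inf, tolerance = 1e-14)
  expect_equal(s$sd_final_fraction_at_n, sqrt(s$sigma2 / 1e4),
               tolerance = 1e-12)
  expect_identical(s$case, "interior_root")
  f0 <- f_eval(f_curve(canonical_params(), canonical_init()), s$x_inf)
  expect_lt(abs(f0), 1e-10)
})
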