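test_that("the transfer function is monotone in drive and threshold", {
  mus <- seq(2, 9, by = 0.5)
  r_mu <- lif_transfer_rate(mus, sigma = 2)
  expect_true(all(diff(r_mu) > 0))
  ths <- seq(6, 14, by = 0.5)
  r_th <- lif_transfer_rate(5.7, 2.4, theta = ths)
  expect_true(all(diff(r_th) < 0))
  # theta approaching mu from above: the rate grows by an order of magnitude
  expect_gt(lif_transfer_rate(5.7, 2.4, theta = 5.75) /
              lif_transfer_rate(5.7, 2.4, theta = 10), 10)
  expect_error(lif_transfer_rate(5.7, 2.4, theta = -1), "exceed")
  expect_error(lif_transfer_rate(5.7, 0), "positive")
})

test_that("self-consistency solves in one evaluation when J = 0 and is damping-invariant", {
  set.seed(1)
  mu_ext <- pmax(rnorm(200, 5.7, 0.4), 0.05)
  sol0 <- solve_self_consistent(mu_ext, J = 0)
  expect_equal(sol0$nu, mean(lif_transfer_rate(mu_ext, sqrt(mu_ext))),
               tolerance = 1e-12)

  solA <- solve_self_consistent(mu_ext, J = 0.05, C = 100, damping = 0.1)
  solB <- solve_self_consistent(mu_ext, J = 0.05, C = 100, damping = 0.5)
  expect_lt(abs(solA$nu - solB$nu), 2e-4)
  expect_lt(solA$residual, 1e-4)
})

test_that("local homeostasis (alpha = 0) collapses rates onto the target", {
  set.seed(2)
  mu_ext <- pmax(rnorm(250, 5.7, 0.4), 0.05)
  fit <- mf_homeostasis(mu_ext, alpha = 0, phi0 = 2, n_steps = 400)
  expect_lt(max(abs(fit$rates - 2)) / 2, 1e-3)
  # a global signal (alpha = 1) fixes the mean but keeps heterogeneity
  fit1 <- mf_homeostasis(mu_ext, alpha = 1, phi0 = 2, n_steps = 400)
  expect_equal(fit1$phibar, 2, tolerance = 1e-3)
  expect_gt(sd(fit1$rates), 0.3)
})

test_that("steady-state rate variance is non-decreasing in alpha", {
  set.seed(3)
  mu_ext <- pmax(rnorm(250, 5.7, 0.4), 0.05)
  vars <- sapply(c(0, 0.4, 0.8, 1), function(a)
    var(mf_homeostasis(mu_ext, a, phi0 = 2, n_steps = 400)$rates))
  expect_true(all(diff(vars) >= -1e-10))
})

test_that("covariance populations hit the requested correlation and ordering", {
  hi <- build_covariance_population(0.99, 1e4, seed = 4)
  lo <- build_covariance_population(0.6, 1e4, seed = 4)
  un <- build_covariance_population(0, 1e4, seed = 4)
  expect_lt(abs(hi$rho_empirical - 0.99), 0.02)
  expect_lt(abs(lo$rho_empirical - 0.6), 0.02)
  # stronger input-threshold matching narrows the rate distribution
  expect_lt(var(hi$rates), var(lo$rates))
  expect_lt(var(lo$rates), var(un$rates))
  # and the decorrelated population is more heavy-tailed
  expect_gt(rate_summary(lo$rates)$skewness, rate_summary(hi$rates)$skewness)
  expect_error(build_covariance_population(1.2, 10), "rho")
})

test_that("input-width and mixing shape response linearity as expected", {
  sw <- mf_response_linearity(alpha_grid = c(0, 0.95),
                              delta_grid = c(0.1, 1.0), n = 300,
                              trials = 2, n_steps = 250, seed = 5)
  m <- aggregate(r2 ~ alpha + delta, sw, mean)
  r2_narrow <- m$r2[m$delta == 0.1]
  r2_wide <- m$r2[m$delta == 1.0]
  expect_true(all(r2_narrow > 0.95))          # narrow inputs: high and flat
  expect_true(all(r2_wide < min(r2_narrow)))  # wide inputs: overall lower
})
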