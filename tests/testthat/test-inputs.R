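test_that("static rate draws match the requested Gaussian and clip at zero", {
  d0 <- draw_static_rates(4, mean = 5, sd = 0, seed = 1)
  expect_equal(d0$rates, rep(5, 4))

  d <- draw_static_rates(1e5, mean = 0, sd = 1, seed = 2)
  expect_true(all(d$rates >= 0))
  # rectified standard normal has mean 1/sqrt(2*pi); allow 4 standard errors
  se <- sd(d$rates) / sqrt(1e5)
  expect_lt(abs(mean(d$rates) - 1 / sqrt(2 * pi)), 4 * se)
  # pre-clip draws keep the requested moments
  expect_lt(abs(mean(d$rates_raw)), 4 / sqrt(1e5))

  big <- draw_static_rates(5000, 10, 10, seed = 3)
  expect_lt(abs(mean(big$rates_raw) - 10), 4 * 10 / sqrt(5000))

  expect_error(draw_static_rates(0, 10, 10), "positive")
  expect_identical(draw_static_rates(100, 10, 10, seed = 7)$rates,
                   draw_static_rates(100, 10, 10, seed = 7)$rates)
})

test_that("group assignment is disjoint, random and size-exact", {
  g <- assign_groups(2500, c(250, 250), n_eligible = 2000, seed = 1)
  expect_equal(as.numeric(table(g)), c(2000, 250, 250))
  expect_true(all(which(g > 0) <= 2000))

  expect_equal(assign_groups(10, integer(0)), integer(10))
  expect_error(assign_groups(100, c(80, 30)), "exceed")

  g1 <- assign_groups(100, c(50, 50), seed = 1)
  g2 <- assign_groups(100, c(50, 50), seed = 2)
  expect_false(identical(g1, g2))
  expect_equal(as.numeric(table(g1)), as.numeric(table(g2)))
})

test_that("time-varying patterns are i.i.d. Gaussian per step", {
  p <- time_varying_pattern(10, 1000, sd = 25, seed = 1)
  expect_equal(dim(p), c(1000, 10))
  expect_lt(abs(sd(p) - 25), 4 * 25 / sqrt(2 * length(p)))
  # successive steps uncorrelated
  ac <- cor(as.numeric(p[-nrow(p), ]), as.numeric(p[-1, ]))
  expect_lt(abs(ac), 4 / sqrt(length(p)))
  expect_true(all(time_varying_pattern(3, 10, sd = 0, seed = 1) == 0))
})

test_that("orientation tuning is Gaussian in circular distance", {
  pref <- c(0, 45, 90, 180, 270)
  r <- orientation_rates(pref, stimulus_deg = 90)
  expect_equal(r[3], 22.5)                       # base 20 + peak 2.5
  expect_equal(orientation_rates(pref, 90, amplitude = 0), rep(20, 5))
  # at one tuning width from the stimulus the amplitude drops by exp(-1/2)
  r90 <- orientation_rates(0, 90, width = 90)
  expect_equal(r90, 20 + 2.5 * exp(-0.5))
  # circular wrap: 350 and -10 degrees are 20 degrees apart
  expect_equal(orientation_rates(350, 10), orientation_rates(30, 10))
})

test_that("poisson arrivals have the right count statistics", {
  steps <- 1e5  # 100 s at 1 ms
  ev <- poisson_arrivals(c(10, 0), dt_s = 1e-3, steps = steps, seed = 1)
  expect_equal(sum(ev[2, ]), 0)
  expect_lt(abs(sum(ev[1, ]) - 1000), 4 * sqrt(1000))
  expect_error(poisson_arrivals(-1, 1e-3, 10), "non-negative")
  a <- poisson_arrivals(5, 1e-3, 1000, seed = 1)
  b <- poisson_arrivals(5, 1e-3, 1000, seed = 2)
  expect_false(identical(a, b))
})
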