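test_that("response R^2 matches closed forms", {
  set.seed(1)
  dmu <- rnorm(5000)
  expect_equal(response_r2(dmu, 2 * dmu), 1)
  expect_lt(response_r2(dmu, rnorm(5000)), 0.01)
  # rectified response on symmetric Gaussian input:
  # R^2 = cov^2/(var_x var_y) = (1/2)^2 / (1/2 - 1/(2*pi))
  big <- rnorm(2e5)
  r2_rect <- response_r2(big, pmax(big, 0))
  expect_equal(r2_rect, 0.25 / (0.5 - 1 / (2 * pi)), tolerance = 0.01)
  # affine invariance
  expect_equal(response_r2(3 * dmu + 1, -5 * pmax(dmu, 0) + 2),
               response_r2(dmu, pmax(dmu, 0)), tolerance = 1e-12)
  expect_error(response_r2(rep(1, 10), rnorm(10)), "variance")
  expect_error(response_r2(1:2, 1:2), "at least 3")
})

test_that("persistence time finds the SNR zero crossing", {
  t <- seq(0.5, 200, by = 1)
  # group difference decays linearly and crosses zero at t = 100 s
  g1 <- matrix(rep(5 + pmax(100 - t, -50) / 50, each = 30), nrow = 30,
               byrow = FALSE) + matrix(rnorm(30 * length(t), 0, 0.01), 30)
  g2 <- matrix(5, 30, length(t)) + matrix(rnorm(30 * length(t), 0, 0.01), 30)
  pt <- persistence_time(g1, g2, t, smooth_s = 1, onset_s = 0)
  expect_false(pt$censored)
  expect_lt(abs(pt$persistence_s - 100), 2)
  # identical groups: SNR hovers around zero, crossing almost immediately
  same <- matrix(rnorm(30 * 50, 5, 0.5), 30)
  pt0 <- persistence_time(same, same + rnorm(30 * 50, 0, 0.5),
                          seq_len(50), smooth_s = 1)
  expect_lt(pt0$persistence_s, 10)
  # constant separation: censored at the end of the series
  apart <- matrix(8, 30, 50); base <- matrix(5 + rnorm(1500, 0, 0.3), 30)
  pt1 <- persistence_time(apart, base, seq_len(50), smooth_s = 1)
  expect_true(pt1$censored)
  expect_error(persistence_time(matrix(0, 0, 5), base, 1:5), "empty")
})

test_that("tracking RMS has its closed-form values", {
  set.seed(2)
  x <- rnorm(500)
  expect_equal(tracking_rms(x, x), 0)
  expect_equal(tracking_rms(x, -x), 2)
  expect_equal(tracking_rms(x, 5 * x + 3), 0)   # z-scoring removes scale
  y <- rnorm(2e5); z <- rnorm(2e5)
  expect_equal(tracking_rms(y, z), sqrt(2), tolerance = 0.01)
  expect_error(tracking_rms(x, x[-1]), "mismatch")
  expect_error(tracking_rms(rep(1, 10), rnorm(10)), "constant")
})

test_that("population-vector decoding is exact and equivariant", {
  expect_equal(population_vector_decode(c(0, 0, 7, 0), c(10, 50, 123, 300)),
               123)
  # noiseless Gaussian tuning centred at 90 degrees decodes 90 exactly
  pref <- seq(0, 359, by = 1)
  rates <- orientation_rates(pref, 90) - 20  # tuned response above base
  expect_equal(population_vector_decode(rates, pref), 90, tolerance = 1e-6)
  # rotating stimulus and preferences rotates the decode
  d1 <- population_vector_decode(rates, (pref + 35) %% 360)
  expect_equal(d1, 125, tolerance = 1e-6)
  expect_error(population_vector_decode(rep(1, 4), c(0, 90, 180, 270)),
               "zero population vector")
  expect_error(population_vector_decode(c(-1, 1), c(0, 90)), "non-negative")
  # circular differences map to (-180, 180]
  expect_equal(circular_diff_deg(350, 10), -20)
  expect_equal(circular_diff_deg(10, 350), 20)
})

test_that("spike statistics recover CV and flat Poisson autocorrelograms", {
  # perfectly periodic train: CV = 0
  per <- data.frame(time_s = seq(0.1, 50, by = 0.2), neuron_id = 1L)
  s1 <- spike_statistics(per, 1)
  expect_equal(unname(s1$cv), 0)
  # Poisson trains: CV near 1, autocorrelogram flat near rate^2
  set.seed(3)
  r <- 10; T_end <- 100
  sp <- do.call(rbind, lapply(1:30, function(i) {
    t <- cumsum(rexp(2 * r * T_end, r))
    data.frame(time_s = t[t < T_end], neuron_id = i)
  }))
  s2 <- spike_statistics(sp, 30)
  expect_equal(mean(s2$cv), 1, tolerance = 0.05)
  ac <- s2$autocorrelogram
  off <- abs(ac$lag_s) > 0.005
  expect_equal(mean(ac$coincidence_rate[off]), r^2, tolerance = 0.1)
  slope <- coef(lm(ac$coincidence_rate[off] ~ ac$lag_s[off]))[2]
  expect_lt(abs(slope) * 0.1, r^2 * 0.1)  # no trend across lags
})
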