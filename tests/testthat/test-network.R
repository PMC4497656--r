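test_that("connectivity has binomial in-degree around C and supports C = 0", {
  conn <- build_connectivity(2000, 100, seed = 1)
  # mean in-degree has sd sqrt(C (1 - C/N) / N) ~ 0.22
  expect_lt(abs(mean_in_degree(conn) - 100), 1)
  # no autapses
  pre <- rep.int(seq_len(conn$N), diff(conn$ptr))
  expect_true(all(pre != conn$post))

  empty <- build_connectivity(10, 0, seed = 1)
  expect_equal(length(empty$post), 0)
  expect_error(build_connectivity(10, 10), "C must satisfy")
})

test_that("spatial connectivity follows the Gaussian distance profile", {
  s <- 0.1
  conn <- build_connectivity(1500, 150, seed = 2, spatial_s = s)
  pre <- rep.int(seq_len(conn$N), diff(conn$ptr))
  # empirical connection probability in distance bins vs eps*exp(-d^2/2s^2)
  set.seed(3)
  i <- sample.int(1500, 4e5, replace = TRUE)
  j <- sample.int(1500, 4e5, replace = TRUE)
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  dx <- pmin(abs(conn$x[i] - conn$x[j]), 1 - abs(conn$x[i] - conn$x[j]))
  dy <- pmin(abs(conn$y[i] - conn$y[j]), 1 - abs(conn$y[i] - conn$y[j]))
  d2 <- dx^2 + dy^2
  key <- paste(i, j)
  edge_key <- paste(pre, conn$post)
  is_edge <- key %in% edge_key
  bins <- cut(d2, quantile(d2[d2 < (3 * s)^2], seq(0, 1, 0.25)),
              include.lowest = TRUE)
  sel <- !is.na(bins)
  p_emp <- tapply(is_edge[sel], bins[sel], mean)
  d2_mid <- tapply(d2[sel], bins[sel], mean)
  fit <- lm(log(p_emp) ~ d2_mid)
  expect_equal(unname(coef(fit)[2]), -1 / (2 * s^2), tolerance = 0.25)
})

test_that("a passive neuron relaxes from reset to the leak potential", {
  cfg <- sim_config(N = 1, C = 0, sigma_OU = 0, ds = 100)
  conn <- build_connectivity(1, 0, seed = 1)
  st <- init_network_state(cfg, conn, seed = 1)
  st$v <- cfg$v_r
  res <- run_network(st, cfg, 0.02, drive = 0, mode = "off", rate_window_s = 0,
                     seed = 1)
  v_pred <- cfg$E_l + (cfg$v_r - cfg$E_l) * exp(-20 / cfg$tau_m)
  expect_equal(res$state$v, v_pred, tolerance = 1e-3)
  expect_equal(res$n_spikes, 0)  # no input, no noise, theta0 above E_l
})

test_that("constant-current firing matches the LIF f-I curve and converges in dt", {
  # dv/dt = (E_l - v)/tau_m + I with I = 2 mV/ms: v_inf = -40 mV above theta
  I <- 2
  v_inf <- -80 + I * 20
  T_isi <- 20 * log((v_inf - (-60)) / (v_inf - (-50)))
  rate_pred <- 1000 / (T_isi + 5)
  for (dt in c(0.1, 0.05)) {
    cfg <- sim_config(N = 1, C = 0, sigma_OU = 0, i_const = I, dt = dt,
                      ds = 100)
    conn <- build_connectivity(1, 0, seed = 1)
    st <- init_network_state(cfg, conn, seed = 1)
    res <- run_network(st, cfg, 10, drive = 0, mode = "off",
                       rate_window_s = 0, seed = 1)
    rate <- res$n_spikes / 10
    expect_equal(rate, rate_pred, tolerance = 0.02)
    if (dt == 0.1) r01 <- rate else r005 <- rate
  }
  expect_lt(abs(r01 - r005) / r005, 0.01)
})

test_that("the refractory contract holds under strong drive", {
  cfg <- sim_config(N = 20, C = 0, ds = 100)
  conn <- build_connectivity(20, 0, seed = 1)
  st <- init_network_state(cfg, conn, seed = 2)
  res <- run_network(st, cfg, 5, drive = 200, mode = "off",
                     record_spikes = TRUE, rate_window_s = 0, seed = 3)
  isi <- unlist(tapply(res$spikes$time_s, res$spikes$neuron_id,
                       function(t) diff(sort(t))))
  expect_gte(min(isi) * 1000, cfg$tau_ref - 1e-9)
})

test_that("seeded runs are bit-reproducible", {
  cfg <- sim_config(N = 100, C = 20, ds = 50)
  conn <- build_connectivity(100, 20, seed = 4)
  st <- init_network_state(cfg, conn, seed = 5)
  r1 <- run_network(st, cfg, 2, drive = 8, mode = "off",
                    record_spikes = TRUE, seed = 11)
  r2 <- run_network(st, cfg, 2, drive = 8, mode = "off",
                    record_spikes = TRUE, seed = 11)
  r3 <- run_network(st, cfg, 2, drive = 8, mode = "off",
                    record_spikes = TRUE, seed = 12)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$state$v, r2$state$v)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("the balanced network fires asynchronously and irregularly", {
  cfg <- scaled_config(n = 500, grid_n = 32)
  conn <- build_connectivity(cfg$N, cfg$C, seed = 6)
  st <- init_network_state(cfg, conn, seed = 7)
  res <- run_network(st, cfg, 10, drive = 5, mode = "off",
                     record_spikes = TRUE, seed = 8)
  rate <- res$n_spikes / cfg$N / 10
  expect_gt(rate, 1); expect_lt(rate, 40)
  stats <- spike_statistics(res$spikes, cfg$N)
  expect_gt(mean(stats$cv), 0.6)
  expect_lt(mean(stats$cv), 1.4)
  # conductances stay non-negative
  expect_true(all(res$state$ge >= 0) && all(res$state$gi >= 0))
})

test_that("duration zero returns an empty run", {
  cfg <- tiny_config()
  conn <- build_connectivity(cfg$N, cfg$C, seed = 1)
  st <- init_network_state(cfg, conn, seed = 1)
  res <- run_network(st, cfg, 0, drive = 5, mode = "off",
                     record_spikes = TRUE, seed = 1)
  expect_equal(res$n_spikes, 0)
  expect_equal(nrow(res$spikes), 0)
})
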