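test_that("pairwise weight changes match the additive rule", {
  # pre 20 ms before post: potentiation A+ * exp(-20/20) * g_max
  expect_equal(stdp_delta_w(-20), 0.025 * exp(-1) * 10)
  # coincident spikes fall in the depression branch
  expect_equal(stdp_delta_w(0), -0.0275 * 10)
  expect_equal(stdp_delta_w(40), -0.0275 * exp(-2) * 10)
  # vectorized, sign structure
  dts <- seq(-60, 60, by = 5)
  dw <- stdp_delta_w(dts)
  expect_true(all(dw[dts < 0] > 0) && all(dw[dts >= 0] < 0))
  expect_true(all(abs(dw) <= 0.0275 * 10))
})

test_that("uncorrelated Poisson pre/post trains drift toward depression", {
  # nearest-neighbour bookkeeping on two independent 5 Hz trains
  set.seed(1)
  drift <- replicate(40, {
    pre <- cumsum(rexp(400, 5)); post <- cumsum(rexp(400, 5))
    total <- 0; last_post <- -Inf; last_pre <- -Inf
    ev <- rbind(data.frame(t = pre, who = 1), data.frame(t = post, who = 2))
    ev <- ev[order(ev$t), ]
    for (k in seq_len(nrow(ev))) {
      if (ev$who[k] == 1) {
        if (is.finite(last_post))
          total <- total + stdp_delta_w((ev$t[k] - last_post) * 1000)
        last_pre <- ev$t[k]
      } else {
        if (is.finite(last_pre))
          total <- total + stdp_delta_w(-(ev$t[k] - last_pre) * 1000)
        last_post <- ev$t[k]
      }
    }
    total
  })
  expect_lt(mean(drift), 0)
})

test_that("weight shuffling preserves the histogram but not the assignment", {
  set.seed(2)
  w <- c(runif(500, 0, 10), rep(0, 100), rep(10, 150))
  ws <- shuffle_weights(w, seed = 3)
  expect_equal(sort(w), sort(ws))
  expect_false(identical(w, ws))
  expect_false(identical(shuffle_weights(w, seed = 3),
                         shuffle_weights(w, seed = 4)))
  # partial shuffles leave other entries alone
  ws2 <- shuffle_weights(w, which_edges = 1:100, seed = 5)
  expect_identical(ws2[101:750], w[101:750])
})

test_that("recurrent STDP drives weights to a bounded bimodal distribution", {
  cfg <- scaled_config(n = 600, grid_n = 32, C = 150, J_ext = 40)
  conn <- build_connectivity(cfg$N, cfg$C, seed = 8)
  st <- init_network_state(cfg, conn, seed = 9, stdp = TRUE)
  ee <- ee_edges(conn)
  w0 <- st$weights[ee]
  expect_true(all(w0 >= 0 & w0 <= cfg$g_max))
  res <- run_network(st, cfg, 250, drive = draw_static_rates(cfg$N, 10, 10,
                                                             seed = 10),
                     mode = "off", stdp = TRUE, seed = 11)
  w1 <- res$weights[ee]
  expect_true(all(w1 >= 0 & w1 <= cfg$g_max + 1e-12))
  # additive STDP with hard bounds splits weights toward the bounds
  expect_gt(weight_bimodality(w1, cfg$g_max, cfg$g_min), 0.5)
  expect_gt(weight_bimodality(w1, cfg$g_max, cfg$g_min),
            weight_bimodality(w0, cfg$g_max, cfg$g_min) + 0.3)
  # A+ = A- = 0 leaves weights untouched
  cfg0 <- scaled_config(n = 100, grid_n = 16, C = 30, J_ext = 40,
                        A_plus = 0, A_minus = 0)
  conn0 <- build_connectivity(cfg0$N, cfg0$C, seed = 12)
  st0 <- init_network_state(cfg0, conn0, seed = 13, stdp = TRUE)
  res0 <- run_network(st0, cfg0, 5, drive = 10, mode = "off", stdp = TRUE,
                      seed = 14)
  expect_identical(res0$weights, st0$weights)
})
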