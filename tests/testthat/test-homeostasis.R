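test_that("threshold update has the stated fixed point and slope", {
  th <- c(-50, -48)
  expect_equal(update_thresholds(th, no = c(1, 2), target = c(1, 2),
                                 dt_ms = 1, tau_hip = 2500), th)
  # [NO] = 2*[NO]0: dtheta = + dt/tau * 0.5 (threshold rises)
  out <- update_thresholds(-50, no = 2, target = 1, dt_ms = 1,
                           tau_hip = 2500)
  expect_equal(out, -50 + 0.5 / 2500)
  # non-positive NO: neuron skipped, not poisoned
  out2 <- update_thresholds(c(-50, -50), no = c(0, 2), target = 1,
                            dt_ms = 1, tau_hip = 2500)
  expect_equal(out2, c(-50, -50 + 0.5 / 2500))
})

test_that("combined rule reduces to single-signal limits", {
  th <- -50
  both <- update_thresholds_combined(th, no_diff = 2, no_nondiff = 2,
                                     target_diff = 1, target_nondiff = 1,
                                     dt_ms = 1, tau_diffusive = 2500,
                                     tau_nondiffusive = 1e12)
  only_diff <- update_thresholds(th, 2, 1, 1, 2500)
  expect_equal(both, only_diff, tolerance = 1e-9)
  # both signals at target: stationary
  expect_equal(update_thresholds_combined(th, 1, 3, 1, 3, 1, 2500, 2500), th)
})

test_that("closed-loop homeostasis returns a perturbed neuron group to the calibration rate", {
  # small uncoupled population sensing its own intracellular NO
  cfg <- scaled_config(n = 40, grid_n = 16, C = 0)
  conn <- build_connectivity(cfg$N, 0, seed = 1)
  st <- init_network_state(cfg, conn, seed = 2)
  cal <- calibrate_no_target(st, cfg, rate_hz = 5, duration_s = 30, seed = 3)
  r_cal <- cal$mean_rate
  # triple the drive, let homeostasis act, measure the recovered rate
  res <- run_network(cal$state, cfg, 80, drive = 15, mode = "nondiffusive",
                     target_nondiff = cal$target_nondiff, seed = 4)
  r_end <- mean(mean_rates(res, last_s = 15))
  expect_equal(r_end, r_cal, tolerance = 0.10)
  # and the perturbation had an effect to recover from
  r_start <- max(colMeans(res$rates[, 1:3]))
  expect_gt(r_start, 1.5 * r_cal)
})

test_that("variable targets are broad, right-skewed draws from the NO pool", {
  cfg <- scaled_config(n = 150, grid_n = 16)
  conn <- build_connectivity(cfg$N, cfg$C, seed = 5)
  st <- init_network_state(cfg, conn, seed = 6)
  vt <- draw_variable_targets(st, cfg, mean_hz = 2, sd_hz = 5,
                              duration_s = 25, seed = 7)
  expect_equal(length(vt$targets), cfg$N)
  expect_true(all(vt$targets > 0))
  expect_true(all(vt$targets %in% vt$no_nondiff))  # resampled from the pool
  sk <- mean((vt$targets - mean(vt$targets))^3) / sd(vt$targets)^3
  expect_gt(sk, 0)
})

test_that("degenerate calibration inputs are rejected", {
  cfg <- tiny_config()
  conn <- build_connectivity(cfg$N, cfg$C, seed = 1)
  st <- init_network_state(cfg, conn, seed = 1)
  expect_error(calibrate_no_target(st, cfg, rate_hz = 0, duration_s = 1),
               "positive")
})
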