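test_that("calcium decays exponentially and steps per spike", {
  # one spike at t = 0, then free decay for 10 ms = tau_Ca
  ca <- update_calcium(0, 1, dt_ms = 0)
  for (k in 1:100) ca <- update_calcium(ca, 0, dt_ms = 0.1)
  expect_equal(ca, exp(-1), tolerance = 1e-10)
  expect_equal(update_calcium(0, 0, 0.1), 0)

  # periodic spiking at rate r: steady-state mean Ca = r * tau_Ca * Ca_spike
  r <- 20  # Hz, one spike every 50 ms
  ca <- 0; trace <- numeric(0)
  for (k in 1:20000) {
    ca <- update_calcium(ca, k %% 500 == 0, dt_ms = 0.1)
    if (k > 10000) trace <- c(trace, ca)
  }
  expect_equal(mean(trace), r * 0.010 * 1, tolerance = 0.05)
})

test_that("nNOS relaxes toward the Hill activation of calcium", {
  expect_equal(hill_activation(1, n = 3, K = 1), 0.5)  # midpoint by definition
  expect_equal(hill_activation(0), 0)
  # step calcium: relaxation with time constant 100 ms
  nn <- 0
  for (k in 1:1000) nn <- update_nnos(nn, ca = 1, dt_ms = 0.1)
  expect_equal(nn, 0.5 * (1 - exp(-1)), tolerance = 1e-3)
  # calcium removed: decay to zero
  for (k in 1:20000) nn <- update_nnos(nn, ca = 0, dt_ms = 0.1)
  expect_lt(nn, 1e-8)
})

test_that("diffusion conserves mass on the torus and decays uniformly", {
  set.seed(1)
  f <- matrix(runif(48 * 48), 48)
  tot <- sum(f)
  g <- f
  for (k in 1:1000) g <- step_diffusion(g, dt_s = 1e-3, D = 1000, lambda = 0,
                                        ds = 10)
  expect_lt(abs(sum(g) - tot) / tot, 1e-10)
  expect_true(all(g >= 0))

  # uniform field with decay only: exact exponential per step
  u <- matrix(2, 20, 20)
  for (k in 1:100) u <- step_diffusion(u, dt_s = 1e-3, D = 1000,
                                       lambda = 0.1, ds = 10)
  expect_equal(u[5, 7], 2 * (1 - 0.1 * 1e-3)^100, tolerance = 1e-12)

  expect_error(step_diffusion(f, dt_s = 1, D = 1000, lambda = 0, ds = 10),
               "stability")
})

test_that("an impulse spreads like the analytic 2D heat kernel", {
  nx <- 101; ds <- 10; D <- 1000
  f <- matrix(0, nx, nx); f[51, 51] <- 1
  t_s <- 2.0
  for (k in 1:2000) f <- step_diffusion(f, dt_s = 1e-3, D = D, lambda = 0,
                                        ds = ds)
  # the kernel is separable: exact mass per cell is a product of Gaussian
  # CDF differences
  s <- sqrt(2 * D * t_s)
  x <- (seq_len(nx) - 51) * ds
  m1 <- pnorm((x + ds / 2) / s) - pnorm((x - ds / 2) / s)
  pred <- outer(m1, m1)
  within <- sqrt(outer(x^2, rep(1, nx)) + outer(rep(1, nx), x^2)) <= 2 * s
  expect_lt(max(abs(f[within] - pred[within])) / max(pred), 0.01)
})

test_that("R and compiled diffusion kernels agree step for step", {
  set.seed(2)
  f <- matrix(runif(30 * 30), 30)
  fR <- f
  for (k in 1:50) fR <- step_diffusion(fR, 1e-3, D = 2000, lambda = 0.3,
                                       ds = 10)
  fC <- diffhomeo:::cpp_diffuse(f, 50, 2000, 0.3, 10, 1e-3)
  expect_equal(fR, fC, tolerance = 1e-13)
})

test_that("grid sampling and the non-diffusive ODE behave as stated", {
  f <- matrix(3.5, 10, 10)
  expect_equal(sample_no(f, c(1, 55, 100)), rep(3.5, 3))
  expect_equal(sample_no(f, c(7, 7)), c(3.5, 3.5))
  expect_error(sample_no(f, 101), "invalid")

  # fixed point: constant nNOS a gives steady NO = a / lambda
  no <- 0
  for (k in 1:4e4) no <- update_no_nondiffusive(no, nnos = 0.2, dt_s = 1e-3,
                                                lambda = 0.5)
  expect_equal(no, 0.2 / 0.5, tolerance = 1e-6)
  # pure decay
  no <- 4
  for (k in 1:1000) no <- update_no_nondiffusive(no, 0, 1e-3, lambda = 0.5)
  expect_equal(no, 4 * (1 - 0.5e-3)^1000, tolerance = 1e-12)

  # D = 0 diffusion on a neuron's own cell matches the non-diffusive ODE
  f <- matrix(0, 5, 5); nol <- 0
  for (k in 1:500) {
    f <- step_diffusion(f, 1e-3, D = 0, lambda = 0.5, ds = 10,
                        sources = 0.3, cells = 13)
    nol <- update_no_nondiffusive(nol, 0.3, 1e-3, lambda = 0.5)
  }
  expect_equal(f[13], nol, tolerance = 1e-3)
  expect_equal(sum(f[-13]), 0)
})

test_that("an impulse on the torus relaxes to the uniform average", {
  f <- matrix(0, 16, 16); f[4, 9] <- 1
  for (k in 1:20000) f <- step_diffusion(f, 1e-3, D = 5000, lambda = 0,
                                         ds = 20)
  expect_lt(max(abs(f - 1 / 256)) / (1 / 256), 0.01)
})
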