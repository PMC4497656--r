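# Dynamic mean-field model: Ricciardi transfer function for the LIF neuron,
# self-consistent population rate, and threshold homeostasis in which a
# mixing parameter alpha interpolates between a purely local activity
# read-out (alpha = 0, non-diffusive homeostasis) and a purely global one
# (alpha = 1). Reduced dimensionless voltage coordinates: theta0 = 10,
# v_r = 0.

# Gauss-Legendre nodes/weights on [-1, 1], cached per order.
.gl_cache <- new.env(parent = emptyenv())
gl_rule <- function(order) {
  key <- as.character(order)
  if (is.null(.gl_cache[[key]]))
    .gl_cache[[key]] <- pracma::gaussLegendre(order, -1, 1)
  .gl_cache[[key]]
}

#' LIF transfer function (Ricciardi)
#'
#' Mean firing rate of an LIF neuron driven by Gaussian white-noise current
#' with mean `mu` and stationary membrane sd `sigma`:
#' `rate = 1 / (sqrt(pi) * tau_m * I)` with
#' `I = int exp(v^2) erfc(-v) dv` taken from `(v_r-mu)/sigma` to
#' `(theta-mu)/sigma`. The integrand is evaluated through the
#' scaled complementary error function (erfcx), which is stable for large
#' |v|; the integral uses fixed-order Gauss-Legendre quadrature, vectorized
#' over neurons. No refractory term is included.
#'
#' @param mu mean input (dimensionless voltage units); vectorized.
#' @param sigma input sd (> 0); recycled.
#' @param theta firing threshold (default 10); recycled.
#' @param v_r reset potential (default 0).
#' @param tau_m membrane time constant in seconds (default 0.02), which
#'   sets the rate unit (Hz).
#' @param order quadrature order.
#' @return firing rate(s) in Hz.
#' @export
lif_transfer_rate <- function(mu, sigma, theta = 10, v_r = 0, tau_m = 0.02,
                              order = 80) {
  n <- max(length(mu), length(sigma), length(theta))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n); theta <- rep_len(theta, n)
  if (any(sigma <= 0)) stop("sigma must be positive")
  a <- (v_r - mu) / sigma
  b <- (theta - mu) / sigma
  gl <- gl_rule(order)
  half <- (b - a) / 2
  mid <- (b + a) / 2
  # nodes: n x order matrix
  x <- outer(mid, rep(1, order)) + outer(half, gl$x)
  fx <- matrix(pracma::erfcx(-as.numeric(x)), nrow = n)
  I <- half * as.numeric(fx %*% gl$w)
  rate <- 1 / (sqrt(pi) * tau_m * I)
  if (any(!is.finite(rate) & b > a))
    stop("non-finite transfer integral; check (mu, sigma, theta)")
  # theta <= v_r would mean instantaneous firing; flag rather than return Inf
  if (any(b <= a)) stop("theta must exceed v_r")
  rate
}

#' Brute-force LIF rate by direct stochastic simulation
#'
#' Euler-Maruyama integration of the white-noise-driven LIF neuron in the
#' reduced coordinates of the mean-field model (no refractory period),
#' counting threshold crossings. Slow but assumption-free; serves as the
#' independent check of [lif_transfer_rate()].
#'
#' @param mu,sigma,theta input mean, input sd and threshold (vectorized).
#' @param v_r reset potential.
#' @param tau_m membrane time constant (s).
#' @param T_s simulated time per grid point (s).
#' @param dt_s integration step (s); threshold-crossing discretization
#'   bias scales with sqrt(dt_s), so keep it well below tau_m.
#' @param seed integer seed.
#' @return empirical firing rate(s) in Hz.
#' @export
lif_sim_rate <- function(mu, sigma, theta = 10, v_r = 0, tau_m = 0.02,
                         T_s = 200, dt_s = 1e-5, seed = 1) {
  n <- max(length(mu), length(sigma), length(theta))
  cpp_lif_rate(rep_len(as.numeric(mu), n), rep_len(as.numeric(sigma), n),
               rep_len(as.numeric(theta), n), v_r, tau_m, T_s, dt_s,
               as.integer(seed))
}

#' Mean-field input statistics from the population rate
#'
#' Diffusion-approximation statistics of the recurrent synaptic current:
#' mu_rec = J*C*nu*tau, sigma_rec^2 = J^2*C*nu*tau, plus an additive
#' per-neuron external offset `mu_ext` contributing its own mean and (for
#' Poisson-like input) variance: mu_i = mu_rec + mu_ext_i, sigma_i^2 =
#' J^2*C*nu*tau + mu_ext_i.
#'
#' @param nu population rate (Hz).
#' @param mu_ext per-neuron external input offsets.
#' @param J synaptic efficacy (dimensionless voltage units).
#' @param C synapses per neuron.
#' @param tau integration interval (s), conventionally tau_m.
#' @return list with vectors `mu`, `sigma`.
#' @export
mf_input_stats <- function(nu, mu_ext, J = 0, C = 100, tau = 0.02) {
  mu <- J * C * nu * tau + mu_ext
  s2 <- J^2 * C * nu * tau + pmax(mu_ext, 0)
  list(mu = mu, sigma = sqrt(pmax(s2, 1e-12)))
}

#' Solve the self-consistent population rate
#'
#' Damped fixed-point iteration on nu: compute per-neuron input statistics
#' from nu, evaluate the transfer function, average, and iterate until the
#' residual |mean(phi) - nu| falls below `tol` (default 1e-4 Hz).
#'
#' @param mu_ext per-neuron external input offsets.
#' @param theta per-neuron thresholds (recycled).
#' @param J,C,tau recurrent coupling parameters (see [mf_input_stats()]).
#' @param v_r,tau_m transfer-function parameters.
#' @param nu0 starting rate (Hz).
#' @param damping step fraction in (0, 1].
#' @param tol convergence tolerance (Hz).
#' @param max_iter iteration cap.
#' @return list with `nu` (the self-consistent rate), `rates` (per-neuron),
#'   `iterations`, `residual`.
#' @export
solve_self_consistent <- function(mu_ext, theta = 10, J = 0, C = 100,
                                  tau = 0.02, v_r = 0, tau_m = 0.02,
                                  nu0 = 5, damping = 0.5, tol = 1e-4,
                                  max_iter = 500) {
  nu <- nu0
  for (it in seq_len(max_iter)) {
    stats <- mf_input_stats(nu, mu_ext, J, C, tau)
    phi <- lif_transfer_rate(stats$mu, stats$sigma, theta, v_r, tau_m)
    phibar <- mean(phi)
    resid <- abs(phibar - nu)
    nu <- (1 - damping) * nu + damping * phibar
    if (resid < tol)
      return(list(nu = nu, rates = phi, iterations = it, residual = resid))
    if (J == 0)  # decoupled: one evaluation is exact
      return(list(nu = phibar, rates = phi, iterations = it, residual = 0))
  }
  stop(sprintf("self-consistency not reached after %d iterations (residual %.2e Hz)",
               max_iter, resid))
}

#' Threshold homeostasis with local/global mixing
#'
#' Evolves per-neuron thresholds under
#' d(theta_i)/dt = (1/tau_HIP) * ( (1-alpha)*(phi_i-phi0)/phi_i
#'                                + alpha*(phibar-phi0)/phibar ),
#' recalculating all rates (and, if J > 0, the self-consistent population
#' rate) after every Euler step. alpha = 0 is a purely local read-out
#' (non-diffusive homeostasis), alpha = 1 purely global.
#'
#' @param mu_ext per-neuron external input offsets.
#' @param alpha mixing parameter in `[0, 1]`.
#' @param phi0 target rate (Hz); scalar or per-neuron (variable targets).
#' @param theta0 initial thresholds.
#' @param n_steps number of Euler steps.
#' @param dt_over_tau Euler step as a fraction of tau_HIP.
#' @param J,C,tau,v_r,tau_m model parameters.
#' @param record_every store thresholds/rates every this many steps
#'   (0 = final state only).
#' @param err_clip lower clamp on the relative-error terms (a neuron whose
#'   rate collapses toward zero otherwise takes an unboundedly large Euler
#'   step).
#' @return list with final `theta`, `rates`, `phibar`, and (if recording)
#'   `trace` = list of `t` (units of tau_HIP), `rates` matrices.
#' @export
mf_homeostasis <- function(mu_ext, alpha, phi0 = 2, theta0 = 10,
                           n_steps = 400, dt_over_tau = 0.05, J = 0,
                           C = 100, tau = 0.02, v_r = 0, tau_m = 0.02,
                           record_every = 0, err_clip = -50) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  n <- length(mu_ext)
  theta <- rep_len(theta0, n)
  phi0 <- rep_len(phi0, n)
  rec_t <- c(); rec_rates <- list(); rec_theta <- list()
  rate_of <- function(theta) {
    if (J == 0) {
      stats <- mf_input_stats(0, mu_ext, 0, C, tau)
      lif_transfer_rate(stats$mu, stats$sigma, theta, v_r, tau_m)
    } else {
      solve_self_consistent(mu_ext, theta, J, C, tau, v_r, tau_m)$rates
    }
  }
  phi <- rate_of(theta)
  for (k in seq_len(n_steps)) {
    phibar <- mean(phi)
    e_loc <- pmax((phi - phi0) / phi, err_clip)
    e_glob <- pmax((phibar - phi0) / phibar, err_clip)
    theta <- theta + dt_over_tau * ((1 - alpha) * e_loc + alpha * e_glob)
    phi <- rate_of(theta)
    if (record_every > 0 && k %% record_every == 0) {
      rec_t <- c(rec_t, k * dt_over_tau)
      rec_rates[[length(rec_rates) + 1]] <- phi
      rec_theta[[length(rec_theta) + 1]] <- theta
    }
  }
  out <- list(theta = theta, rates = phi, phibar = mean(phi), mu_ext = mu_ext)
  if (record_every > 0)
    out$trace <- list(t = rec_t, rates = do.call(cbind, rec_rates),
                      theta = do.call(cbind, rec_theta))
  out
}

#' Population with prescribed input-threshold covariance
#'
#' Imitates the outcome of homeostasis by drawing (mu_i, theta_i) jointly
#' from a Gaussian copula with correlation `rho`: high covariance mimics a
#' local (non-diffusive) process that matches each threshold to its input;
#' low covariance mimics the decorrelation produced by a diffusive signal.
#'
#' @param rho requested correlation in `[-1, 1]`.
#' @param n population size.
#' @param mu_mean,mu_sd Gaussian marginal of the inputs.
#' @param theta_marginal either c(mean, sd) for a Gaussian threshold
#'   marginal, or a numeric sample whose empirical distribution is used.
#' @param seed optional integer seed.
#' @param tau_m transfer-function time constant (s).
#' @return list with `mu`, `theta`, `rates`, `rho_empirical`.
#' @export
build_covariance_population <- function(rho, n, mu_mean = 5.7, mu_sd = 0.4,
                                        theta_marginal = c(10, 0.5),
                                        seed = NULL, tau_m = 0.02) {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  mu <- mu_mean + mu_sd * z1
  mu <- pmax(mu, 0.05)
  if (length(theta_marginal) == 2 && is.null(dim(theta_marginal))) {
    theta <- theta_marginal[1] + theta_marginal[2] * z2
  } else {
    theta <- as.numeric(quantile(theta_marginal, pnorm(z2), type = 8))
  }
  theta <- pmax(theta, 0.1)  # threshold must exceed v_r = 0
  rates <- lif_transfer_rate(mu, sqrt(mu), theta, tau_m = tau_m)
  list(mu = mu, theta = theta, rates = rates,
       rho_empirical = suppressWarnings(stats::cor(mu, theta)))
}

#' Response-linearity sweep over the mixing parameter
#'
#' For each (alpha, delta): run homeostasis to steady state under inputs
#' mu_i ~ N(mu_mean, delta^2), freeze thresholds, redraw the inputs from
#' the same distribution, and regress the rate changes on the input
#' changes. Averaged over `trials` independent populations.
#'
#' @param alpha_grid,delta_grid parameter grids.
#' @param n population size per trial.
#' @param trials independent repetitions.
#' @param mu_mean mean input.
#' @param phi0 target rate (Hz).
#' @param n_steps,dt_over_tau homeostasis settings (see
#'   [mf_homeostasis()]).
#' @param seed integer seed.
#' @return data frame (alpha, delta, trial, r2, rate_var).
#' @export
mf_response_linearity <- function(alpha_grid, delta_grid, n = 500,
                                  trials = 5, mu_mean = 5.7, phi0 = 2,
                                  n_steps = 300, dt_over_tau = 0.05,
                                  seed = 1) {
  out <- list()
  for (delta in delta_grid) {
    for (alpha in alpha_grid) {
      for (tr in seq_len(trials)) {
        set.seed(seed + 7919 * tr + round(1000 * alpha) + round(1e6 * delta))
        mu <- pmax(rnorm(n, mu_mean, delta), 0.05)
        fit <- mf_homeostasis(mu, alpha, phi0 = phi0, n_steps = n_steps,
                              dt_over_tau = dt_over_tau)
        mu2 <- pmax(rnorm(n, mu_mean, delta), 0.05)
        phi2 <- lif_transfer_rate(mu2, sqrt(mu2), fit$theta)
        r2 <- response_r2(mu2 - mu, phi2 - fit$rates)
        out[[length(out) + 1]] <-
          data.frame(alpha = alpha, delta = delta, trial = tr, r2 = r2,
                     rate_var = var(fit$rates))
      }
    }
  }
  do.call(rbind, out)
}

#' Mean-field input-group experiment
#'
#' Two small groups receive elevated inputs on top of a uniform background;
#' homeostasis with mixing `alpha` then acts. Returns the time course of
#' each group's mean rate, from which the decay speed of group differences
#' can be measured (for alpha < 1 the differences decay at about (1-alpha)
#' times the alpha = 0 speed; at alpha = 1 they persist).
#'
#' @param alpha mixing parameter.
#' @param n population size.
#' @param group_frac fraction of neurons in each of the two elevated
#'   groups.
#' @param mu_base background input; `dmu` the two elevations.
#' @param phi0 target rate (Hz).
#' @param n_steps,dt_over_tau,record_every evolution settings.
#' @param seed integer seed.
#' @return list with `t` (units of tau_HIP), `g1`, `g2`, `bg` (group mean
#'   rate series), `diff` = g1 - g2.
#' @export
mf_input_groups <- function(alpha, n = 1000, group_frac = 0.1,
                            mu_base = 5.7, dmu = c(1, 2), phi0 = 2,
                            n_steps = 600, dt_over_tau = 0.05,
                            record_every = 5, seed = 1) {
  set.seed(seed)
  ng <- round(group_frac * n)
  labels <- integer(n)
  labels[sample.int(n, 2 * ng)] <- rep(1:2, each = ng)
  mu <- rep(mu_base, n)
  mu[labels == 1] <- mu_base + dmu[1]
  mu[labels == 2] <- mu_base + dmu[2]
  fit <- mf_homeostasis(mu, alpha, phi0 = phi0, n_steps = n_steps,
                        dt_over_tau = dt_over_tau,
                        record_every = record_every)
  rates <- fit$trace$rates
  list(t = fit$trace$t,
       g1 = colMeans(rates[labels == 1, , drop = FALSE]),
       g2 = colMeans(rates[labels == 2, , drop = FALSE]),
       bg = colMeans(rates[labels == 0, , drop = FALSE]),
       diff = colMeans(rates[labels == 2, , drop = FALSE]) -
              colMeans(rates[labels == 1, , drop = FALSE]))
}
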