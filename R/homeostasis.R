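#' Homeostatic threshold update
#'
#' One Euler step of the negative-feedback rule
#' `d(theta_i)/dt = (1/tau_hip) * ([NO]_i - [NO]0_i) / [NO]_i`.
#' The same rule serves the diffusive and non-diffusive variants; they
#' differ only in which NO signal is passed. Neurons whose NO signal is not
#' yet positive (startup transient) are skipped.
#'
#' @param theta firing thresholds (mV).
#' @param no per-neuron NO signal.
#' @param target target concentration(s), scalar or per-neuron.
#' @param dt_ms timestep (ms).
#' @param tau_hip homeostasis timescale (ms).
#' @return updated thresholds.
#' @export
update_thresholds <- function(theta, no, target, dt_ms, tau_hip = 2500) {
  ok <- no > 0
  dth <- numeric(length(theta))
  dth[ok] <- (dt_ms / tau_hip) * (no[ok] - rep(target, length.out = length(no))[ok]) / no[ok]
  theta + dth
}

#' Combined diffusive + non-diffusive threshold update
#'
#' Sum of two relative-error terms, each with its own timescale and its own
#' independently calibrated target.
#'
#' @param theta firing thresholds (mV).
#' @param no_diff,no_nondiff the two NO signals.
#' @param target_diff,target_nondiff their targets.
#' @param dt_ms timestep (ms).
#' @param tau_diffusive,tau_nondiffusive timescales (ms).
#' @return updated thresholds.
#' @export
update_thresholds_combined <- function(theta, no_diff, no_nondiff,
                                       target_diff, target_nondiff, dt_ms,
                                       tau_diffusive = 2500,
                                       tau_nondiffusive = 2500) {
  th <- update_thresholds(theta, no_diff, target_diff, dt_ms, tau_diffusive)
  update_thresholds(th, no_nondiff, target_nondiff, dt_ms, tau_nondiffusive)
}

#' Calibrate the homeostatic NO target
#'
#' Runs the network without homeostasis, with every neuron receiving the
#' same Poisson input rate, and defines the target concentration as the
#' mean NO concentration across neurons at the end of the run. Both the
#' diffusive (grid-sampled) and non-diffusive (intracellular) targets are
#' returned, so either homeostasis mode can use its own calibration.
#'
#' @param state a fresh `network_state`.
#' @param cfg the matching [sim_config()].
#' @param rate_hz calibration input rate (Hz).
#' @param duration_s calibration duration (s).
#' @param seed integer seed.
#' @return list with `target_diff`, `target_nondiff`, the per-neuron
#'   end-of-run concentrations (`no_diff`, `no_nondiff`), and `state` (the
#'   calibrated network, useful to continue from).
#' @export
calibrate_no_target <- function(state, cfg, rate_hz = 5, duration_s = 100,
                                seed = 1L) {
  if (rate_hz <= 0) stop("calibration drive must be positive")
  res <- run_network(state, cfg, duration_s, drive = rate_hz, mode = "off",
                     rate_window_s = min(duration_s, 10), seed = seed)
  no_d <- res$no_sample
  no_n <- res$state$NO_local
  tg_d <- mean(no_d)
  tg_n <- mean(no_n)
  if (!is.finite(tg_d) || tg_d <= 0 || tg_n <= 0)
    stop("calibration produced a non-positive NO target; increase the drive or duration")
  list(target_diff = tg_d, target_nondiff = tg_n, no_diff = no_d,
       no_nondiff = no_n, state = res$state,
       mean_rate = res$n_spikes / cfg$N / duration_s)
}

#' Draw per-neuron variable homeostatic targets
#'
#' Runs a network without homeostasis under a broad Gaussian input-rate
#' distribution and samples per-neuron targets (with replacement) from the
#' resulting steady-state distribution of intracellular NO. This yields a
#' broad, right-skewed target distribution for the variable-target control.
#'
#' @param state a fresh `network_state`.
#' @param cfg the matching [sim_config()].
#' @param mean_hz,sd_hz parameters of the calibration input distribution
#'   (Hz); negative draws are clipped at zero.
#' @param duration_s calibration duration (s).
#' @param seed integer seed.
#' @return list with `targets` (per-neuron, non-diffusive signal), the
#'   source `no_nondiff` distribution and the calibration `state`.
#' @export
draw_variable_targets <- function(state, cfg, mean_hz = 2, sd_hz = 5,
                                  duration_s = 100, seed = 1L) {
  set.seed(seed)
  drive <- draw_static_rates(cfg$N, mean_hz, sd_hz)
  res <- run_network(state, cfg, duration_s, drive = drive, mode = "off",
                     rate_window_s = min(duration_s, 10), seed = seed + 1L)
  pool <- res$state$NO_local
  pool <- pool[pool > 0]
  if (length(pool) < 2)
    stop("calibration produced no positive NO concentrations")
  targets <- sample(pool, cfg$N, replace = TRUE)
  list(targets = targets, no_nondiff = res$state$NO_local, state = res$state)
}
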