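#' Simulation configuration
#'
#' Builds the full parameter set of the spiking-network model: LIF membrane
#' and synapse constants, balanced-network connectivity scales, NO synthesis
#' and diffusion constants, and homeostasis/STDP settings. Defaults are the
#' reference parameter table of the model (conductances in nS, potentials in
#' mV, time constants in ms, diffusion coefficient in um^2/s, decay rate in
#' 1/s, 1 mm^2 sheet).
#'
#' @param N number of neurons; 0.8*N excitatory, 0.2*N inhibitory.
#' @param C mean number of synapses per neuron; connection probability C/N.
#' @param J_e,J_i excitatory/inhibitory synaptic conductance (nS). The
#'   default inhibitory scale J_i = g*J_e with g ~ 11.6 puts the network in
#'   the inhibition-dominated balanced state.
#' @param J_ext external-input conductance (nS).
#' @param E_l,v_r,E_e,E_i leak reversal, reset, excitatory and inhibitory
#'   reversal potentials (mV).
#' @param c_m membrane capacitance (nF).
#' @param tau_m,tau_ref,tau_e,tau_i,tau_OU membrane, refractory, synaptic and
#'   noise-correlation time constants (ms).
#' @param theta0 initial firing threshold (mV).
#' @param sigma_OU amplitude of the Ornstein-Uhlenbeck voltage noise; the
#'   unit-variance OU process enters dv/dt scaled by this value (mV/ms).
#' @param dt integration timestep (ms).
#' @param Ca_spike calcium influx per spike (arbitrary concentration units).
#' @param tau_Ca,tau_nNOS calcium decay and nNOS activation timescales (ms).
#' @param hill_n,hill_K Hill exponent and half-activation of nNOS by calcium.
#' @param D NO diffusion coefficient (um^2/s).
#' @param lambda NO decay rate (1/s).
#' @param L_mm side of the (periodic) square sheet (mm).
#' @param ds spatial resolution of the diffusion grid (um); the grid has
#'   (1000*L_mm/ds)^2 cells. FTCS stability requires D*dt_diff/ds^2 <= 0.25.
#' @param dt_diff timestep of diffusion, chemistry and threshold updates
#'   (ms); must be a multiple of `dt`.
#' @param tau_HIP homeostasis timescale (ms).
#' @param A_plus,A_minus,tau_plus,tau_minus,g_max,g_min additive STDP
#'   parameters (depression slightly stronger than potentiation).
#' @param w0_mean,w0_sd mean and sd (nS) of the initial Gaussian E-to-E
#'   weights used when STDP is enabled.
#' @param i_const constant current injection (mV/ms), used mainly for
#'   single-neuron validation against the deterministic LIF f-I curve.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(N = 5000, C = 100, J_e = 5.5, J_i = 64.0, J_ext = 80.0,
                       E_l = -80, v_r = -60, E_e = 0, E_i = -70, c_m = 0.2,
                       tau_m = 20, tau_ref = 5, theta0 = -50, tau_e = 3,
                       tau_i = 7, tau_OU = 1, sigma_OU = 1, dt = 0.1,
                       Ca_spike = 1, tau_Ca = 10, tau_nNOS = 100, hill_n = 3,
                       hill_K = 1, D = 1000, lambda = 0.1, L_mm = 1, ds = 2,
                       dt_diff = 1, tau_HIP = 2500,
                       A_plus = 0.025, A_minus = 0.0275, tau_plus = 20,
                       tau_minus = 20, g_max = 10, g_min = 0,
                       w0_mean = 7.5, w0_sd = 2.5, i_const = 0) {
  cfg <- list(N = as.integer(N), C = C, J_e = J_e, J_i = J_i, J_ext = J_ext,
              E_l = E_l, v_r = v_r, E_e = E_e, E_i = E_i, c_m = c_m,
              tau_m = tau_m, tau_ref = tau_ref, theta0 = theta0,
              tau_e = tau_e, tau_i = tau_i, tau_OU = tau_OU,
              sigma_OU = sigma_OU, dt = dt, Ca_spike = Ca_spike,
              tau_Ca = tau_Ca, tau_nNOS = tau_nNOS, hill_n = hill_n,
              hill_K = hill_K, D = D, lambda = lambda, L_mm = L_mm, ds = ds,
              dt_diff = dt_diff, tau_HIP = tau_HIP, A_plus = A_plus,
              A_minus = A_minus, tau_plus = tau_plus, tau_minus = tau_minus,
              g_max = g_max, g_min = g_min, w0_mean = w0_mean, w0_sd = w0_sd,
              i_const = i_const)
  cfg$Ne <- as.integer(round(0.8 * cfg$N))
  cfg$grid_n <- as.integer(round(1000 * L_mm / ds))
  if (cfg$N < 1) stop("N must be positive")
  if (C < 0 || C >= cfg$N) stop("C must satisfy 0 <= C < N")
  tcs <- c(tau_m, tau_ref, tau_e, tau_i, tau_OU, tau_Ca, tau_nNOS, tau_HIP)
  if (any(tcs <= 0)) stop("all time constants must be positive")
  if (dt <= 0 || dt_diff <= 0) stop("timesteps must be positive")
  k <- dt_diff / dt
  if (abs(k - round(k)) > 1e-9) stop("dt_diff must be a multiple of dt")
  stab <- D * (dt_diff / 1000) / ds^2
  if (stab > 0.25)
    stop(sprintf("FTCS stability bound violated: D*dt_diff/ds^2 = %.3f > 0.25",
                 stab))
  if (A_minus < A_plus)
    warning("A_minus < A_plus: runaway potentiation likely")
  class(cfg) <- "sim_config"
  cfg
}

#' Time-compressed configuration for reduced-scale runs
#'
#' Produces a configuration for desk-scale runs of the full protocols.
#' Two scalings are applied jointly:
#'
#' * Time compression: the slow processes are sped up by a factor `k`
#'   (tau_HIP -> tau_HIP/k, lambda -> k*lambda) and protocol durations are
#'   divided by the same factor. Fast membrane, synaptic and calcium/nNOS
#'   constants are untouched, so the spiking regime is unchanged.
#' * Neighborhood matching: the diffusive range ell = sqrt(D/lambda) is
#'   enlarged so that the expected number of neurons within range,
#'   n*pi*ell^2/L^2, matches the reference network (`n_full` neurons with
#'   ell = 100 um on 1 mm^2). Holding ell fixed in um at small n would
#'   leave so few neurons within range that each neuron's own point source
#'   dominates its sampled NO, turning diffusive homeostasis effectively
#'   cell-autonomous — a finite-size artifact, not a property of the model.
#'
#' `D` is capped at the FTCS stability bound for the chosen grid.
#'
#' @param n number of neurons.
#' @param k time-compression factor for the slow (homeostatic) processes.
#' @param grid_n diffusion grid side; `ds` is set to 1000*L_mm/grid_n.
#' @param n_full reference network size for neighborhood matching.
#' @param range_um override for the diffusive range (um).
#' @param ... further overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
scaled_config <- function(n = 1000, k = 5, grid_n = 100, n_full = 5000,
                          range_um = NULL, ...) {
  ds <- 1000 / grid_n
  lambda <- 0.1 * k
  if (is.null(range_um)) range_um <- 100 * sqrt(n_full / n)
  D <- lambda * range_um^2
  D <- min(D, 0.249 * ds^2 * 1000)  # FTCS bound at dt_diff = 1 ms
  sim_config(N = n, ds = ds, tau_HIP = 2500 / k, lambda = lambda, D = D, ...)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  N = %d (%d exc / %d inh), C = %g, J_e = %g nS, J_i = %g nS, J_ext = %g nS\n",
              x$N, x$Ne, x$N - x$Ne, x$C, x$J_e, x$J_i, x$J_ext))
  cat(sprintf("  membrane: E_l %g, v_r %g, theta0 %g mV; tau_m %g ms, dt %g ms\n",
              x$E_l, x$v_r, x$theta0, x$tau_m, x$dt))
  cat(sprintf("  NO: D %g um^2/s, lambda %g /s, grid %dx%d (ds %g um), dt_diff %g ms\n",
              x$D, x$lambda, x$grid_n, x$grid_n, x$ds, x$dt_diff))
  cat(sprintf("  homeostasis tau_HIP %g ms\n", x$tau_HIP))
  invisible(x)
}
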