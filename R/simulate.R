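#' Initialize network state
#'
#' Membrane potentials start uniformly between E_l and theta0 (to
#' desynchronize onset), conductances and chemical concentrations at zero,
#' thresholds at theta0.
#'
#' @param cfg a [sim_config()].
#' @param conn a [build_connectivity()] object for the same N.
#' @param seed optional integer seed.
#' @param stdp logical; draw Gaussian initial E-to-E weights for STDP runs.
#' @return a `network_state` list (also carries the connectivity and edge
#'   weights so a run is self-contained).
#' @export
init_network_state <- function(cfg, conn, seed = NULL, stdp = FALSE) {
  stopifnot(inherits(cfg, "sim_config"), inherits(conn, "connectivity"))
  if (conn$N != cfg$N) stop("connectivity and config disagree on N")
  if (!is.null(seed)) set.seed(seed)
  N <- cfg$N
  cell_i <- pmin(floor(conn$x / (cfg$L_mm / cfg$grid_n)), cfg$grid_n - 1)
  cell_j <- pmin(floor(conn$y / (cfg$L_mm / cfg$grid_n)), cfg$grid_n - 1)
  st <- list(
    v = runif(N, cfg$E_l, cfg$theta0),
    ge = numeric(N), gi = numeric(N), gx = numeric(N), eta = numeric(N),
    refr = numeric(N), theta = rep(cfg$theta0, N),
    Ca = numeric(N), nNOS = numeric(N), NO_local = numeric(N),
    field = numeric(cfg$grid_n^2),
    last_spike = rep(-1e18, N), t_ms = 0,
    cell = as.integer(cell_i * cfg$grid_n + cell_j),
    conn = conn,
    weights = edge_weights(conn, cfg, stdp_init = stdp))
  class(st) <- "network_state"
  st
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state> N = %d, t = %.1f s, mean theta = %.2f mV\n",
              length(x$v), x$t_ms / 1000, mean(x$theta)))
  invisible(x)
}

#' Run the spiking network
#'
#' Advances the network by `duration_s` seconds of simulated time with
#' fixed-step (forward Euler) integration of the membrane equation at
#' `cfg$dt`, exact exponential synaptic decay, exact-update OU noise, and
#' chemistry/diffusion/threshold updates every `cfg$dt_diff`. External
#' Poisson input follows the provided drive, optionally piecewise-constant
#' in time.
#'
#' @param state a `network_state` (mutated copy is returned).
#' @param cfg the [sim_config()] used to build the state.
#' @param duration_s simulated duration in seconds.
#' @param drive either a numeric vector of per-neuron rates (Hz), an
#'   `external_drive`, or a list with `rates` (N x nseg matrix, Hz) and
#'   `seg_end_s` (segment end times) for time-varying input.
#' @param mode homeostasis mode: "off", "diffusive", "nondiffusive" or
#'   "combined".
#' @param freeze if TRUE, chemistry runs but thresholds are not updated.
#' @param target_diff,target_nondiff homeostatic NO targets (scalar or
#'   per-neuron) for the diffusive and non-diffusive signals.
#' @param tau_diffusive,tau_nondiffusive timescales (ms) of the two terms in
#'   "combined" mode; single-signal modes use `cfg$tau_HIP`.
#' @param stdp enable additive nearest-neighbour STDP on E-to-E synapses.
#' @param record_spikes record (time, neuron) of every spike.
#' @param rate_window_s window (s) for the per-neuron rate time series
#'   (0 disables).
#' @param snap_s cadence (s) for threshold/NO snapshots (0 disables).
#' @param seed integer seed for this run segment (Poisson arrivals and OU
#'   noise). Runs are bit-reproducible given state + seed.
#' @return a `sim_result`: list with `state` (to continue from), `rates`
#'   (N x windows matrix, Hz), `rate_t`, `theta_snap`, `no_diff_snap`,
#'   `no_nondiff_snap`, `snap_t`, `no_sample` (per-neuron diffusive NO at
#'   the end), `spikes` (data frame), `weights`, `n_spikes`, `guard_skips`.
#' @export
run_network <- function(state, cfg, duration_s, drive,
                        mode = c("off", "diffusive", "nondiffusive", "combined"),
                        freeze = FALSE, target_diff = 1, target_nondiff = 1,
                        tau_diffusive = cfg$tau_HIP,
                        tau_nondiffusive = cfg$tau_HIP,
                        stdp = FALSE, record_spikes = FALSE,
                        rate_window_s = 1, snap_s = 0, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "network_state"))
  N <- cfg$N
  if (inherits(drive, "external_drive")) drive <- drive$rates
  if (is.numeric(drive)) {
    if (length(drive) == 1) drive <- rep(drive, N)
    rates <- matrix(drive, nrow = N, ncol = 1)
    seg_end <- duration_s * 1000
  } else {
    rates <- drive$rates
    if (nrow(rates) != N) stop("drive rate matrix must have N rows")
    seg_end <- drive$seg_end_s * 1000
    if (length(seg_end) != ncol(rates))
      stop("seg_end_s must match the number of drive segments")
  }
  if (any(rates < 0)) stop("drive rates must be non-negative")
  mode_i <- match(mode, c("off", "diffusive", "nondiffusive", "combined")) - 1L

  conn <- state$conn
  if (stdp) {
    rev <- reverse_ee_adjacency(conn)
  } else {
    rev <- list(rev_ptr = integer(conn$Ne + 1), rev_edge = integer(0),
                rev_pre = integer(0))
  }
  ccfg <- list(
    N = N, Ne = conn$Ne, dt_ms = cfg$dt, duration_ms = duration_s * 1000,
    El = cfg$E_l, vr = cfg$v_r, Ee = cfg$E_e, Ei = cfg$E_i, cm = cfg$c_m,
    taum = cfg$tau_m, tref = cfg$tau_ref, taue = cfg$tau_e, taui = cfg$tau_i,
    tauOU = cfg$tau_OU, sigmaOU = cfg$sigma_OU, Jext = cfg$J_ext,
    i_const = cfg$i_const, Ca_spike = cfg$Ca_spike, tauCa = cfg$tau_Ca,
    taunNOS = cfg$tau_nNOS, hill_n = cfg$hill_n, hill_K = cfg$hill_K,
    D_um2s = cfg$D, lambda_s = cfg$lambda, ds_um = cfg$ds,
    dtdiff_ms = cfg$dt_diff, mode = mode_i, freeze = freeze,
    tauHIP_ms = cfg$tau_HIP, tauDiffusive_ms = tau_diffusive,
    tauNonDiffusive_ms = tau_nondiffusive, stdp = stdp,
    A_plus = cfg$A_plus, A_minus = cfg$A_minus, tau_plus = cfg$tau_plus,
    tau_minus = cfg$tau_minus, g_max = cfg$g_max, g_min = cfg$g_min,
    record_spikes = record_spikes, rate_window_ms = rate_window_s * 1000,
    snap_ms = snap_s * 1000, seed = as.integer(seed),
    adj_ptr = as.integer(conn$ptr - 1L), adj_post = as.integer(conn$post - 1L),
    w = state$weights, cell = state$cell,
    target_diff = as.numeric(target_diff),
    target_nondiff = as.numeric(target_nondiff),
    ext_rates = rates, seg_end_ms = as.numeric(seg_end),
    rev_ptr = rev$rev_ptr, rev_edge = rev$rev_edge, rev_pre = rev$rev_pre)

  out <- cpp_simulate(ccfg, unclass(state))
  new_state <- out$state
  new_state$cell <- state$cell
  new_state$conn <- conn
  new_state$weights <- out$weights
  class(new_state) <- "network_state"
  res <- list(state = new_state, rates = out$rates, rate_t = out$rate_t,
              theta_snap = out$theta_snap, no_diff_snap = out$no_diff_snap,
              no_nondiff_snap = out$no_nondiff_snap, snap_t = out$snap_t,
              no_sample = out$no_sample,
              spikes = data.frame(time_s = out$spike_t / 1000,
                                  neuron_id = out$spike_id),
              weights = out$weights, n_spikes = out$n_spikes,
              guard_skips = out$guard_skips,
              duration_s = duration_s, mode = mode)
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  N <- length(x$state$v)
  cat(sprintf("<sim_result> %.1f s, mode %s, %d neurons, mean rate %.2f Hz\n",
              x$duration_s, x$mode, N,
              x$n_spikes / N / x$duration_s))
  invisible(x)
}

#' Mean firing rates over a time window
#'
#' @param res a `sim_result` with a rate time series.
#' @param from_s,to_s window bounds in seconds (absolute simulation time);
#'   defaults to the final `last_s` seconds.
#' @param last_s shorthand window length counted back from the end.
#' @return numeric vector of per-neuron mean rates (Hz).
#' @export
mean_rates <- function(res, from_s = NULL, to_s = NULL, last_s = 50) {
  tt <- res$rate_t
  if (is.null(from_s)) from_s <- max(tt) - last_s
  if (is.null(to_s)) to_s <- max(tt)
  sel <- tt >= from_s & tt <= to_s + 1e-9
  if (!any(sel)) stop("empty rate window")
  rowMeans(res$rates[, sel, drop = FALSE])
}
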