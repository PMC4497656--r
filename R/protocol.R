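#' Desk-scale study conditions
#'
#' The canonical reduced-scale protocol used by the test suite and the
#' acceptance script: n = 1000 neurons, 48x48 diffusion grid, slow
#' processes time-compressed 5x (tau_HIP = 500 ms, lambda = 0.5 /s),
#' diffusive range enlarged so that the NO field a neuron samples is as
#' smooth, relative to the gain sensitivity of the neurons, as in the
#' N = 5000 reference network, and calibration drives chosen so the
#' homeostatic target rate sits at about half the mean probe input — the
#' same target-to-input ratio as the full-scale protocol. See the methods
#' vignette for the reasoning behind each choice.
#'
#' @param n,k,grid_n,range_um passed to [scaled_config()].
#' @param ... further [sim_config()] overrides.
#' @return list with `cfg` (a `sim_config`) and the protocol parameters
#'   (`cal_rate_hz`, `var_mean`, `var_sd`, `t_homeo_s`, `cal_s`,
#'   `window_s`, `probe_s`).
#' @export
desk_protocol <- function(n = 1000, k = 5, grid_n = 48, range_um = 450,
                          ...) {
  list(cfg = scaled_config(n = n, k = k, grid_n = grid_n,
                           range_um = range_um, ...),
       cal_rate_hz = 1.5, var_mean = 0.8, var_sd = 2.5,
       t_homeo_s = 350 / k, cal_s = 100 / k, window_s = 50 / k,
       probe_s = 20, k = k)
}
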