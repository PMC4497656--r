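#' Calcium update
#'
#' Exponential decay with time constant `tau_ca`, plus a fixed increment per
#' spike. One step of length `dt_ms`.
#'
#' @param ca per-neuron calcium concentrations.
#' @param spikes logical or 0/1 vector marking neurons that spiked during
#'   the step.
#' @param dt_ms timestep (ms).
#' @param tau_ca decay time constant (ms).
#' @param ca_spike increment per spike.
#' @return updated calcium vector.
#' @export
update_calcium <- function(ca, spikes, dt_ms, tau_ca = 10, ca_spike = 1) {
  ca * exp(-dt_ms / tau_ca) + ca_spike * as.numeric(spikes)
}

#' Hill activation of nNOS by calcium
#'
#' @param ca calcium concentration(s).
#' @param n Hill exponent.
#' @param K half-activation constant.
#' @return activation in [0, 1).
#' @export
hill_activation <- function(ca, n = 3, K = 1) {
  cn <- pmax(ca, 0)^n
  cn / (cn + K^n)
}

#' nNOS update
#'
#' First-order relaxation of active nNOS toward the Hill activation of the
#' current calcium level, with time constant `tau_nnos`. (The bounded
#' reading of the synthesis equation: production saturates at the Hill
#' ceiling instead of integrating without limit.)
#'
#' @param nnos current nNOS activation.
#' @param ca calcium concentration.
#' @param dt_ms timestep (ms).
#' @param tau_nnos activation timescale (ms).
#' @param n,K Hill parameters.
#' @return updated nNOS vector.
#' @export
update_nnos <- function(nnos, ca, dt_ms, tau_nnos = 100, n = 3, K = 1) {
  nnos + (dt_ms / tau_nnos) * (hill_activation(ca, n, K) - nnos)
}

#' One FTCS step of NO diffusion-decay on the periodic grid
#'
#' Forward-time centred-space update of `d[NO]/dt = D lap[NO] - lambda [NO]`
#' + sources, with the 5-point periodic Laplacian. Point sources deposit
#' `sources * dt_s` into the grid cells listed in `cells`. Stability
#' requires D*dt/ds^2 <= 0.25.
#'
#' @param field square matrix of NO concentrations.
#' @param dt_s timestep (s).
#' @param D diffusion coefficient (um^2/s).
#' @param lambda decay rate (1/s).
#' @param ds grid spacing (um).
#' @param sources per-neuron nNOS source strengths (concentration/s), or
#'   NULL.
#' @param cells 1-based linear (column-major) grid index per source.
#' @return updated field matrix.
#' @export
step_diffusion <- function(field, dt_s, D = 1000, lambda = 0.1, ds = 2,
                           sources = NULL, cells = NULL) {
  coef <- D * dt_s / ds^2
  if (coef > 0.25)
    stop(sprintf("FTCS stability violated: D*dt/ds^2 = %.3f > 0.25", coef))
  up <- rbind(field[-1, , drop = FALSE], field[1, , drop = FALSE])
  dn <- rbind(field[nrow(field), , drop = FALSE], field[-nrow(field), , drop = FALSE])
  lf <- cbind(field[, -1, drop = FALSE], field[, 1, drop = FALSE])
  rt <- cbind(field[, ncol(field), drop = FALSE], field[, -ncol(field), drop = FALSE])
  out <- field + coef * (up + dn + lf + rt - 4 * field) - lambda * dt_s * field
  if (!is.null(sources)) {
    if (is.null(cells) || length(cells) != length(sources))
      stop("cells must accompany sources")
    dep <- dt_s * sources
    for (k in seq_along(cells)) out[cells[k]] <- out[cells[k]] + dep[k]
  }
  out
}

#' Read the NO concentration at each neuron's grid cell
#'
#' @param field NO concentration matrix.
#' @param cells 1-based linear grid index per neuron.
#' @return per-neuron concentrations.
#' @export
sample_no <- function(field, cells) {
  if (any(cells < 1 | cells > length(field))) stop("invalid grid cells")
  field[cells]
}

#' Non-diffusive (intracellular) NO update
#'
#' Per-neuron ODE `d[NO]/dt = [nNOS] - lambda [NO]`, no spatial coupling.
#'
#' @param no current intracellular NO.
#' @param nnos nNOS activation (source term, concentration/s).
#' @param dt_s timestep (s).
#' @param lambda decay rate (1/s).
#' @return updated NO vector.
#' @export
update_no_nondiffusive <- function(no, nnos, dt_s, lambda = 0.1) {
  no + dt_s * (nnos - lambda * no)
}

#' Radially averaged concentration profile (for kernel checks)
#'
#' @param field square concentration matrix.
#' @param center 1-based (row, col) of the reference cell.
#' @param ds grid spacing (um).
#' @return data frame with columns r_um and conc (bin means at integer cell
#'   radii).
#' @export
radial_profile <- function(field, center, ds = 1) {
  nx <- nrow(field)
  idx <- seq_len(nx) - 1
  di <- outer(pmin((idx - (center[1] - 1)) %% nx, ((center[1] - 1) - idx) %% nx),
              rep(1, nx))
  dj <- t(outer(pmin((idx - (center[2] - 1)) %% nx, ((center[2] - 1) - idx) %% nx),
                rep(1, nx)))
  r <- sqrt(di^2 + dj^2)
  rb <- round(r)
  agg <- tapply(as.numeric(field), as.numeric(rb), mean)
  data.frame(r_um = as.numeric(names(agg)) * ds, conc = as.numeric(agg))
}
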