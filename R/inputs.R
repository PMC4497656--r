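#' Draw static external input rates
#'
#' Per-neuron rates of the independent homogeneous Poisson input, drawn
#' i.i.d. from a Gaussian. A Poisson process cannot have a negative rate, so
#' negative draws are clipped to zero; the pre-clip values are kept so that
#' analyses of input changes can use the underlying Gaussian draw.
#'
#' @param n number of neurons.
#' @param mean,sd mean and standard deviation of the rate distribution (Hz).
#' @param seed integer seed (optional; uses the current RNG state if NULL).
#' @return an `external_drive`: list with `rates` (clipped, Hz),
#'   `rates_raw` (pre-clip), `group` (integer labels, 0 = background).
#' @export
draw_static_rates <- function(n, mean = 10, sd = 10, seed = NULL) {
  if (length(n) != 1 || n < 1) stop("n must be a positive count")
  if (sd < 0) stop("sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  raw <- rnorm(n, mean, sd)
  drive <- list(rates = pmax(raw, 0), rates_raw = raw, group = integer(n))
  class(drive) <- "external_drive"
  drive
}

#' @export
print.external_drive <- function(x, ...) {
  cat(sprintf("<external_drive> %d neurons, mean rate %.2f Hz (%d clipped at 0), %d group(s)\n",
              length(x$rates), mean(x$rates), sum(x$rates_raw < 0),
              length(unique(x$group[x$group > 0]))))
  invisible(x)
}

#' Randomly assign neurons to input groups
#'
#' Draws disjoint random groups among the first `n_eligible` neurons
#' (conventionally the excitatory population), independent of neuron
#' position. Remaining neurons keep label 0 (background).
#'
#' @param n total number of neurons.
#' @param group_sizes integer vector of group sizes (may be empty).
#' @param n_eligible number of neurons eligible for group membership
#'   (default all `n`).
#' @param seed optional integer seed.
#' @return integer vector of length `n`: 0 for background, g for group g.
#' @export
assign_groups <- function(n, group_sizes, n_eligible = n, seed = NULL) {
  if (sum(group_sizes) > n_eligible)
    stop("group sizes exceed the number of eligible neurons")
  if (!is.null(seed)) set.seed(seed)
  labels <- integer(n)
  pool <- seq_len(n_eligible)
  for (g in seq_along(group_sizes)) {
    pick <- sample(pool, group_sizes[g])
    labels[pick] <- g
    pool <- setdiff(pool, pick)
  }
  labels
}

#' Generate a time-varying group input pattern
#'
#' Independent Gaussian rate offsets per group, regenerated at each pattern
#' timestep (default 1 s). Offsets may be negative; the total drive per
#' neuron (static rate + its group offset) is clipped at zero when the
#' pattern is applied.
#'
#' @param n_groups number of groups.
#' @param duration_s pattern duration (s).
#' @param sd standard deviation of the offsets (Hz).
#' @param dt_pattern_s pattern timestep (s).
#' @param seed optional integer seed.
#' @return matrix (timestep x group) of rate offsets in Hz, with attributes
#'   `dt_pattern_s` and `duration_s`.
#' @export
time_varying_pattern <- function(n_groups, duration_s, sd = 25,
                                 dt_pattern_s = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nt <- ceiling(duration_s / dt_pattern_s)
  m <- matrix(rnorm(nt * n_groups, 0, sd), nrow = nt, ncol = n_groups)
  attr(m, "dt_pattern_s") <- dt_pattern_s
  attr(m, "duration_s") <- duration_s
  m
}

#' Orientation-tuned external input rates
#'
#' Gaussian tuning curve in circular angular distance: each neuron with
#' preferred orientation `preferred[i]` receives
#' `base + amplitude * exp(-d(stim, preferred[i])^2 / (2*width^2))` Hz,
#' with d the circular distance on a 360-degree period.
#'
#' @param preferred per-neuron preferred orientations (degrees).
#' @param stimulus_deg stimulus orientation (degrees).
#' @param base base input rate (Hz).
#' @param amplitude peak amplitude above base (Hz).
#' @param width tuning width (degrees).
#' @return numeric vector of rates (Hz).
#' @export
orientation_rates <- function(preferred, stimulus_deg, base = 20,
                              amplitude = 2.5, width = 90) {
  d <- circular_diff_deg(stimulus_deg, preferred)
  base + amplitude * exp(-d^2 / (2 * width^2))
}

#' Circular difference in degrees, mapped to (-180, 180]
#' @param a,b angles in degrees.
#' @return signed circular difference a - b.
#' @export
circular_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Realize Poisson spike arrivals as per-step Bernoulli events
#'
#' External arrivals at the integration step `dt_s` with probability
#' rate*dt per step (the convention used inside the simulator; at the rates
#' and timestep used here, rate*dt << 1, so the Bernoulli approximation to
#' the Poisson process is negligible).
#'
#' @param rates per-neuron rates (Hz).
#' @param dt_s timestep (s).
#' @param steps number of steps.
#' @param seed optional integer seed.
#' @return integer matrix (neuron x step) of 0/1 events.
#' @export
poisson_arrivals <- function(rates, dt_s, steps, seed = NULL) {
  if (any(rates < 0)) stop("rates must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  p <- pmin(rates * dt_s, 1)
  matrix(rbinom(length(rates) * steps, 1, rep(p, steps)),
         nrow = length(rates), ncol = steps)
}

#' Tabulate an external drive
#'
#' @param drive an `external_drive`.
#' @return data frame with columns neuron_id, rate_hz, group.
#' @export
drive_table <- function(drive) {
  data.frame(neuron_id = seq_along(drive$rates), rate_hz = drive$rates,
             group = drive$group)
}
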