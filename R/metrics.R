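#' Linear-response R-squared
#'
#' Ordinary least-squares regression of per-neuron output-rate changes on
#' input-rate changes; R^2 = 1 - SS_res/SS_tot quantifies how linearly the
#' network transmits an input re-configuration.
#'
#' @param dmu per-neuron input changes (Hz).
#' @param dnu per-neuron output-rate changes (Hz).
#' @return R-squared of the least-squares fit.
#' @export
response_r2 <- function(dmu, dnu) {
  if (length(dmu) != length(dnu)) stop("dmu and dnu must be paired")
  if (length(dmu) < 3) stop("need at least 3 paired observations")
  if (var(dmu) == 0) stop("R^2 undefined: no variance in input changes")
  fit <- lm(dnu ~ dmu)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((dnu - mean(dnu))^2)
  if (ss_tot == 0) return(1)
  1 - ss_res / ss_tot
}

#' Rate-distribution summary
#'
#' @param rates per-neuron mean firing rates (Hz).
#' @return list with mean, variance, skewness, and log-rate sd (zero rates
#'   dropped for the log).
#' @export
rate_summary <- function(rates) {
  m <- mean(rates); v <- var(rates)
  sk <- if (v > 0) mean((rates - m)^3) / v^1.5 else 0
  lr <- log10(rates[rates > 0])
  list(mean = m, variance = v, skewness = sk,
       log_sd = if (length(lr) > 1) sd(lr) else NA_real_)
}

#' Signal-to-noise persistence time between two input groups
#'
#' SNR(t) = (mu1 - mu2) / (sd1 + sd2) over the two groups' per-neuron rate
#' series, smoothed with a uniform window. The persistence time is the
#' first time after onset at which SNR falls below zero; if it never does,
#' the result is censored at the end of the series.
#'
#' @param rates1,rates2 matrices (neuron x time) of the two groups' rate
#'   series; group 1 is the one with the higher input.
#' @param times_s time of each column (s).
#' @param smooth_s uniform smoothing window (s).
#' @param onset_s time of stimulus onset (s).
#' @return list with `persistence_s`, `censored`, and the smoothed `snr`
#'   series (with `t`).
#' @export
persistence_time <- function(rates1, rates2, times_s, smooth_s = 20,
                             onset_s = 0) {
  if (nrow(rates1) == 0 || nrow(rates2) == 0) stop("empty group")
  dt <- if (length(times_s) > 1) diff(times_s[1:2]) else smooth_s
  k <- max(1, round(smooth_s / dt))
  sm <- function(m) {
    t(apply(m, 1, function(x)
      as.numeric(filter(x, rep(1 / k, k), sides = 1))))
  }
  s1 <- sm(rates1); s2 <- sm(rates2)
  mu1 <- colMeans(s1); mu2 <- colMeans(s2)
  sd1 <- apply(s1, 2, sd); sd2 <- apply(s2, 2, sd)
  snr <- (mu1 - mu2) / (sd1 + sd2)
  valid <- !is.na(snr) & times_s >= onset_s
  idx <- which(valid & snr < 0)
  if (length(idx) == 0) {
    list(persistence_s = max(times_s) - onset_s, censored = TRUE,
         snr = snr, t = times_s)
  } else {
    list(persistence_s = times_s[min(idx)] - onset_s, censored = FALSE,
         snr = snr, t = times_s)
  }
}

#' Normalized RMS tracking error
#'
#' Both the input pattern and the response are z-scored over the evaluation
#' window, making the error scale-free: identical series give 0, sign-
#' inverted series 2, independent series about sqrt(2).
#'
#' @param pattern input pattern series.
#' @param response network response series (e.g. a group's rate deviation
#'   from the population mean).
#' @return RMS difference of the z-scored series.
#' @export
tracking_rms <- function(pattern, response) {
  if (length(pattern) != length(response)) stop("series length mismatch")
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  if (sd_pop(pattern) == 0 || sd_pop(response) == 0)
    stop("tracking RMS undefined for constant series")
  z <- function(x) (x - mean(x)) / sd_pop(x)
  sqrt(mean((z(pattern) - z(response))^2))
}

#' Population-vector decoding of stimulus orientation
#'
#' Decodes the angle of the vector sum of neural responses, each neuron
#' contributing its rate along its preferred orientation (period 360 deg).
#'
#' @param rates per-neuron responses (>= 0).
#' @param preferred_deg per-neuron preferred orientations (degrees).
#' @return decoded angle in [0, 360).
#' @export
population_vector_decode <- function(rates, preferred_deg) {
  if (any(rates < 0)) stop("rates must be non-negative")
  th <- preferred_deg * pi / 180
  xs <- sum(rates * cos(th)); ys <- sum(rates * sin(th))
  if (sqrt(xs^2 + ys^2) <= 1e-9 * max(sum(rates), 1e-300))
    stop("zero population vector: decoding undefined")
  (atan2(ys, xs) * 180 / pi) %% 360
}

#' Spike-train statistics: ISI distribution, CV, autocorrelogram
#'
#' @param spikes data frame with `time_s` and `neuron_id` (as returned in a
#'   `sim_result`).
#' @param n_neurons total number of neurons.
#' @param bin_s autocorrelogram bin width (s), default 2.5 ms.
#' @param max_lag_s maximum lag (s).
#' @return list with `isi` (all ISIs, s), `cv` (per neuron, >= 2 spikes
#'   required), and `autocorrelogram` (data frame lag_s, rate_hz: rate of
#'   coincident spikes per time bin, averaged across neurons, zero-lag
#'   self-counts excluded).
#' @export
spike_statistics <- function(spikes, n_neurons, bin_s = 0.0025,
                             max_lag_s = 0.1) {
  by_neuron <- split(spikes$time_s, spikes$neuron_id)
  isis <- unlist(lapply(by_neuron, function(t) diff(sort(t))),
                 use.names = FALSE)
  cv <- vapply(by_neuron, function(t) {
    if (length(t) < 2) return(NA_real_)
    d <- diff(sort(t))
    sd(d) / mean(d)
  }, numeric(1))
  cv <- cv[!is.na(cv)]
  T_total <- diff(range(spikes$time_s))
  nlag <- floor(max_lag_s / bin_s)
  counts <- numeric(2 * nlag + 1)
  for (t in by_neuron) {
    t <- sort(t)
    n <- length(t)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      j <- i + 1
      while (j <= n && t[j] - t[i] <= max_lag_s + bin_s / 2) {
        lag_bin <- round((t[j] - t[i]) / bin_s)
        if (lag_bin <= nlag) {
          counts[nlag + 1 + lag_bin] <- counts[nlag + 1 + lag_bin] + 1
          counts[nlag + 1 - lag_bin] <- counts[nlag + 1 - lag_bin] + 1
        }
        j <- j + 1
      }
    }
  }
  # coincidence rate per neuron per unit time per unit lag (Hz^2 scale);
  # for a Poisson train of rate r the expected level is r^2 at all lags
  ac <- counts / (length(by_neuron) * T_total * bin_s)
  list(isi = isis, cv = cv,
       autocorrelogram = data.frame(lag_s = (-nlag:nlag) * bin_s,
                                    coincidence_rate = ac))
}
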