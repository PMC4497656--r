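# Figure-level experiment drivers. Every driver is seed-reproducible and
# takes an explicit configuration, so the same protocol runs at full scale
# (N = 5000, 500x500 grid, tau_HIP = 2500 ms) or at the reduced desk scale
# produced by scaled_config() (smaller N, coarser grid, slow processes
# time-compressed by a factor k with durations divided by k).

#' Bring a network to its homeostatic steady state
#'
#' Builds a network, calibrates the homeostatic NO target (uniform input at
#' `cal_rate_hz` without homeostasis; for the variable-target condition,
#' per-neuron targets sampled from the steady-state NO distribution under a
#' broad input), then runs homeostasis under `drive`.
#'
#' @param cfg a [sim_config()].
#' @param condition "diffusive", "nondiffusive" or "variable" (non-diffusive
#'   homeostasis with per-neuron targets).
#' @param drive external drive for the homeostasis phase (anything accepted
#'   by [run_network()]).
#' @param seed integer seed.
#' @param t_homeo_s homeostasis duration (s).
#' @param cal_rate_hz,cal_s calibration input rate and duration.
#' @param var_mean,var_sd input distribution for the variable-target
#'   calibration (Hz).
#' @param stdp enable STDP during the homeostasis phase.
#' @param rate_window_s rate-recording window (s).
#' @return list with the final `result` (a `sim_result`), `targets`,
#'   `condition`, `drive`, and the network pieces needed to continue.
#' @export
steady_state_network <- function(cfg, condition, drive, seed,
                                 t_homeo_s, cal_rate_hz = 5, cal_s = 20,
                                 var_mean = 2, var_sd = 5, stdp = FALSE,
                                 rate_window_s = 1, init_weights = NULL) {
  condition <- match.arg(condition, c("diffusive", "nondiffusive", "variable"))
  conn <- build_connectivity(cfg$N, cfg$C, seed = seed)
  st0 <- init_network_state(cfg, conn, seed = seed + 1, stdp = stdp)
  if (!is.null(init_weights)) st0$weights <- init_weights
  if (condition == "variable") {
    vt <- draw_variable_targets(st0, cfg, var_mean, var_sd, cal_s,
                                seed = seed + 2)
    targets <- list(target_diff = 1, target_nondiff = vt$targets)
    st <- vt$state
  } else {
    cal <- calibrate_no_target(st0, cfg, cal_rate_hz, cal_s, seed = seed + 2)
    targets <- list(target_diff = cal$target_diff,
                    target_nondiff = cal$target_nondiff)
    st <- cal$state
  }
  mode <- if (condition == "diffusive") "diffusive" else "nondiffusive"
  res <- run_network(st, cfg, t_homeo_s, drive, mode = mode,
                     target_diff = targets$target_diff,
                     target_nondiff = targets$target_nondiff,
                     stdp = stdp, rate_window_s = rate_window_s,
                     seed = seed + 3)
  list(result = res, targets = targets, condition = condition, drive = drive,
       cfg = cfg, mode = mode, seed = seed)
}

#' Steady-state firing-rate distributions across homeostasis conditions
#'
#' The baseline heterogeneity experiment: static Gaussian input rates, one
#' network per condition (same seed, hence same connectivity and input
#' draw), homeostasis to steady state, rate distribution measured over the
#' final window. Diffusive homeostasis preserves a broad, right-skewed rate
#' distribution; non-diffusive homeostasis collapses it onto the target.
#'
#' @param cfg a [sim_config()].
#' @param conditions subset of c("diffusive", "nondiffusive", "variable").
#' @param seed integer seed.
#' @param t_homeo_s homeostasis duration (s).
#' @param window_s width of the steady-state measurement window (s).
#' @param input_mean,input_sd static input-rate distribution (Hz).
#' @param cal_s calibration duration (s).
#' @param cal_rate_hz calibration input rate (Hz).
#' @param var_mean,var_sd input distribution (Hz) for the variable-target
#'   calibration.
#' @return list of per-condition entries (`rates`, `theta`, `summary`,
#'   `network` for continuation) plus a `summary` data frame.
#' @export
exp_steady_state <- function(cfg, conditions = c("diffusive", "nondiffusive",
                                                 "variable"),
                             seed = 1, t_homeo_s = 70, window_s = 10,
                             input_mean = 10, input_sd = 10, cal_s = 20,
                             cal_rate_hz = 5, var_mean = 2, var_sd = 5) {
  set.seed(seed)
  drive <- draw_static_rates(cfg$N, input_mean, input_sd)
  out <- list()
  for (cond in conditions) {
    net <- steady_state_network(cfg, cond, drive, seed = seed,
                                t_homeo_s = t_homeo_s, cal_s = cal_s,
                                cal_rate_hz = cal_rate_hz,
                                var_mean = var_mean, var_sd = var_sd)
    rates <- mean_rates(net$result, last_s = window_s)
    out[[cond]] <- list(rates = rates, theta = net$result$state$theta,
                        summary = rate_summary(rates), network = net)
  }
  out$summary <- do.call(rbind, lapply(conditions, function(cond) {
    s <- out[[cond]]$summary
    data.frame(condition = cond, mean_rate = s$mean, rate_variance = s$variance,
               skewness = s$skewness, theta_sd = sd(out[[cond]]$theta))
  }))
  out
}

#' Response linearity after an input re-configuration
#'
#' Starting from converged networks (one per condition), homeostasis is
#' frozen, baseline rates are measured, the per-neuron input rates are
#' redrawn from the same distribution, and the change in output rate is
#' regressed on the change in input rate.
#'
#' @param ss output of [exp_steady_state()] (its `network` entries are
#'   continued).
#' @param probe_s duration of each measurement phase (s).
#' @param input_mean,input_sd distribution from which inputs are redrawn.
#' @param seed integer seed.
#' @return data frame (condition, r2, pop_rate_before, pop_rate_after) plus
#'   attribute `detail` with per-condition (dmu, dnu).
#' @export
exp_response_linearity <- function(ss, probe_s = 15, input_mean = 10,
                                   input_sd = 10, seed = 99) {
  conds <- setdiff(names(ss), "summary")
  rows <- list(); detail <- list()
  for (cond in conds) {
    net <- ss[[cond]]$network
    cfg <- net$cfg
    before <- run_network(net$result$state, cfg, probe_s, net$drive,
                          mode = net$mode, freeze = TRUE,
                          target_diff = net$targets$target_diff,
                          target_nondiff = net$targets$target_nondiff,
                          seed = seed + 11)
    set.seed(seed)
    drive2 <- draw_static_rates(cfg$N, input_mean, input_sd)
    after <- run_network(before$state, cfg, probe_s, drive2,
                         mode = net$mode, freeze = TRUE,
                         target_diff = net$targets$target_diff,
                         target_nondiff = net$targets$target_nondiff,
                         seed = seed + 12)
    dmu <- drive2$rates_raw - net$drive$rates_raw
    nu1 <- mean_rates(before, last_s = probe_s)
    nu2 <- mean_rates(after, last_s = probe_s)
    dnu <- nu2 - nu1
    rows[[cond]] <- data.frame(condition = cond,
                               r2 = response_r2(dmu, dnu),
                               pop_rate_before = mean(nu1),
                               pop_rate_after = mean(nu2))
    detail[[cond]] <- list(dmu = dmu, dnu = dnu)
  }
  out <- do.call(rbind, rows)
  attr(out, "detail") <- detail
  out
}

#' Persistence of elevated-input group differences
#'
#' Two random groups of excitatory neurons receive elevated Poisson input
#' (5 and 10 Hz against a 2.5 Hz background, all calibrated at 2.5 Hz);
#' homeostasis then pulls the population back to target. The persistence
#' time is how long the signal-to-noise ratio between the two elevated
#' groups stays positive.
#'
#' @param cfg a [sim_config()].
#' @param conditions homeostasis conditions to compare.
#' @param seed integer seed.
#' @param t_max_s run length after stimulus onset (persistence is censored
#'   here if the SNR never crosses zero).
#' @param group_frac fraction of excitatory neurons per group.
#' @param base_hz,mid_hz,high_hz background and elevated input rates.
#' @param smooth_s SNR smoothing window (s).
#' @param cal_s calibration duration (s).
#' @return data frame (condition, persistence_s, censored) with attribute
#'   `detail` (full SNR series and rate matrices).
#' @export
exp_input_groups <- function(cfg, conditions = c("diffusive", "nondiffusive",
                                                 "variable"),
                             seed = 1, t_max_s = 160, group_frac = 0.1,
                             base_hz = 2.5, mid_hz = 5, high_hz = 10,
                             smooth_s = 4, cal_s = 20) {
  ng <- round(group_frac * round(0.8 * cfg$N))
  labels <- assign_groups(cfg$N, c(ng, ng), n_eligible = round(0.8 * cfg$N),
                          seed = seed + 5)
  rates <- rep(base_hz, cfg$N)
  rates[labels == 1] <- mid_hz
  rates[labels == 2] <- high_hz
  drive <- list(rates = rates, rates_raw = rates, group = labels)
  class(drive) <- "external_drive"
  rows <- list(); detail <- list()
  for (cond in conditions) {
    net <- steady_state_network(cfg, cond, drive, seed = seed,
                                t_homeo_s = t_max_s, cal_rate_hz = base_hz,
                                cal_s = cal_s,
                                var_mean = base_hz, var_sd = 2 * base_hz)
    res <- net$result
    onset <- min(res$rate_t) - 0.5
    pt <- persistence_time(res$rates[labels == 2, , drop = FALSE],
                           res$rates[labels == 1, , drop = FALSE],
                           res$rate_t, smooth_s = smooth_s, onset_s = onset)
    rows[[cond]] <- data.frame(condition = cond,
                               persistence_s = pt$persistence_s,
                               censored = pt$censored)
    detail[[cond]] <- list(snr = pt, theta = res$state$theta,
                           rates = res$rates, rate_t = res$rate_t,
                           labels = labels, drive = rates)
  }
  out <- do.call(rbind, rows)
  attr(out, "detail") <- detail
  out
}

#' Simultaneous diffusive and non-diffusive homeostasis
#'
#' Both mechanisms act on the threshold with their own timescales and
#' independently calibrated targets. As the non-diffusive mechanism becomes
#' slower relative to the diffusive one, the steady-state rate distribution
#' broadens toward the purely diffusive outcome.
#'
#' @param cfg a [sim_config()].
#' @param ratios values of tau_nondiffusive / tau_diffusive to sweep.
#' @param seed integer seed.
#' @param t_homeo_s homeostasis duration (s).
#' @param window_s steady-state measurement window (s).
#' @param input_mean,input_sd static input distribution (Hz).
#' @param cal_s calibration duration (s).
#' @return data frame (ratio, rate_variance, mean_rate).
#' @export
exp_combined_timescales <- function(cfg, ratios = c(0.4, 2, 6), seed = 1,
                                    t_homeo_s = 70, window_s = 10,
                                    input_mean = 10, input_sd = 10,
                                    cal_s = 20, cal_rate_hz = 5) {
  set.seed(seed)
  drive <- draw_static_rates(cfg$N, input_mean, input_sd)
  conn <- build_connectivity(cfg$N, cfg$C, seed = seed)
  rows <- list()
  for (r in ratios) {
    st0 <- init_network_state(cfg, conn, seed = seed + 1)
    cal <- calibrate_no_target(st0, cfg, cal_rate_hz, cal_s, seed = seed + 2)
    res <- run_network(cal$state, cfg, t_homeo_s, drive, mode = "combined",
                       target_diff = cal$target_diff,
                       target_nondiff = cal$target_nondiff,
                       tau_diffusive = cfg$tau_HIP,
                       tau_nondiffusive = r * cfg$tau_HIP,
                       seed = seed + 3)
    rates <- mean_rates(res, last_s = window_s)
    rows[[as.character(r)]] <- data.frame(ratio = r,
                                          rate_variance = var(rates),
                                          mean_rate = mean(rates))
  }
  do.call(rbind, rows)
}

#' Tracking of a time-varying group input pattern
#'
#' Neurons are partitioned into groups; each group receives an independent
#' Gaussian rate offset regenerated every second, both during homeostasis
#' and (after freezing) during evaluation. The tracking error is the RMS
#' difference between the z-scored input pattern of a group and the
#' z-scored deviation of that group's rate from the population mean.
#'
#' @param cfg a [sim_config()].
#' @param conditions homeostasis conditions.
#' @param seed integer seed.
#' @param t_homeo_s homeostasis duration (s).
#' @param t_eval_s evaluation duration (s).
#' @param group_size neurons per group.
#' @param pattern_sd sd of the group offsets (Hz).
#' @param input_mean,input_sd static input distribution (Hz).
#' @param cal_s calibration duration (s).
#' @return data frame (condition, group, rms) with per-group errors.
#' @export
exp_tracking <- function(cfg, conditions = c("diffusive", "nondiffusive",
                                             "variable"),
                         seed = 1, t_homeo_s = 70, t_eval_s = 120,
                         group_size = 25, pattern_sd = 25,
                         input_mean = 10, input_sd = 10, cal_s = 20,
                         cal_rate_hz = 5, var_mean = 2, var_sd = 5) {
  set.seed(seed)
  n_groups <- floor(cfg$N / group_size)
  labels <- rep(0L, cfg$N)
  labels[sample.int(cfg$N, n_groups * group_size)] <-
    rep(seq_len(n_groups), each = group_size)
  static <- draw_static_rates(cfg$N, input_mean, input_sd)

  make_drive <- function(pattern) {
    nt <- nrow(pattern)
    rates <- matrix(0, cfg$N, nt)
    for (s in seq_len(nt)) {
      offs <- c(0, pattern[s, ])[labels + 1L]
      rates[, s] <- pmax(static$rates_raw + offs, 0)
    }
    list(rates = rates, seg_end_s = seq_len(nt))
  }
  pat_h <- time_varying_pattern(n_groups, t_homeo_s, sd = pattern_sd,
                                seed = seed + 21)
  pat_e <- time_varying_pattern(n_groups, t_eval_s, sd = pattern_sd,
                                seed = seed + 22)
  rows <- list()
  for (cond in conditions) {
    net <- steady_state_network(cfg, cond, make_drive(pat_h), seed = seed,
                                t_homeo_s = t_homeo_s, cal_s = cal_s,
                                cal_rate_hz = cal_rate_hz,
                                var_mean = var_mean, var_sd = var_sd)
    ev <- run_network(net$result$state, cfg, t_eval_s, make_drive(pat_e),
                      mode = net$mode, freeze = TRUE,
                      target_diff = net$targets$target_diff,
                      target_nondiff = net$targets$target_nondiff,
                      rate_window_s = 1, seed = seed + 23)
    pop <- colMeans(ev$rates)
    for (g in seq_len(n_groups)) {
      resp <- colMeans(ev$rates[labels == g, , drop = FALSE]) - pop
      rows[[paste(cond, g)]] <-
        data.frame(condition = cond, group = g,
                   rms = tracking_rms(pat_e[seq_along(resp), g], resp))
    }
  }
  do.call(rbind, rows)
}

#' Orientation decoding with the population vector
#'
#' Excitatory neurons get random preferred orientations; homeostasis runs
#' while random orientation stimuli are presented (1 s each), is then
#' frozen, and on each trial a random stimulus orientation is presented and
#' decoded as the angle of the population vector of stimulus-evoked
#' excitatory responses (trial rate minus the neuron's across-trial
#' baseline, rectified at zero; subtracting the baseline removes the
#' quenched rate-heterogeneity bias that otherwise dominates the decoder
#' in small networks).
#'
#' @param cfg a [sim_config()].
#' @param conditions homeostasis conditions.
#' @param seed integer seed.
#' @param n_networks independent networks per condition.
#' @param n_trials decoding trials per network.
#' @param t_homeo_s homeostasis duration (s).
#' @param trial_s stimulus duration per trial (s).
#' @param base_hz,amp_hz,width_deg tuning-curve parameters.
#' @param cal_s calibration duration (s).
#' @return data frame (condition, network, error_sd_deg, n_trials), with
#'   attribute `errors` (per-trial signed errors, degrees).
#' @export
exp_orientation <- function(cfg, conditions = c("diffusive", "nondiffusive",
                                                "variable"),
                            seed = 1, n_networks = 2, n_trials = 24,
                            t_homeo_s = 70, trial_s = 2, base_hz = 20,
                            amp_hz = 2.5, width_deg = 90, cal_s = 20,
                            cal_rate_hz = 5, var_mean = 2, var_sd = 5) {
  Ne <- round(0.8 * cfg$N)
  rows <- list(); all_err <- list()
  for (cond in conditions) {
    for (nw in seq_len(n_networks)) {
      sd_net <- seed + 1000 * nw
      set.seed(sd_net + 3)
      preferred <- runif(cfg$N, 0, 360)  # inhibitory neurons get input too
      # homeostasis under the stimulation ensemble: random orientation each 1 s
      nseg <- t_homeo_s
      angs <- runif(nseg, 0, 360)
      rates_h <- vapply(angs, function(a)
        orientation_rates(preferred, a, base_hz, amp_hz, width_deg),
        numeric(cfg$N))
      drive_h <- list(rates = rates_h, seg_end_s = seq_len(nseg))
      net <- steady_state_network(cfg, cond, drive_h, seed = sd_net,
                                  t_homeo_s = t_homeo_s, cal_s = cal_s,
                                  cal_rate_hz = cal_rate_hz,
                                  var_mean = var_mean, var_sd = var_sd)
      st <- net$result$state
      set.seed(sd_net + 4)
      stims <- runif(n_trials, 0, 360)
      resp <- matrix(0, Ne, n_trials)
      for (tr in seq_len(n_trials)) {
        dr <- orientation_rates(preferred, stims[tr], base_hz, amp_hz,
                                width_deg)
        trial <- run_network(st, cfg, trial_s, dr, mode = net$mode,
                             freeze = TRUE,
                             target_diff = net$targets$target_diff,
                             target_nondiff = net$targets$target_nondiff,
                             rate_window_s = trial_s, seed = sd_net + 10 + tr)
        st <- trial$state
        resp[, tr] <- rowMeans(trial$rates)[seq_len(Ne)]
      }
      # stimulus-evoked response: each neuron's rate relative to its own
      # across-trial baseline (stimulus angles are uniform, so the trial
      # average estimates the untuned operating point); rectified so the
      # population vector stays well defined
      evoked <- pmax(resp - rowMeans(resp), 0)
      errs <- vapply(seq_len(n_trials), function(tr) {
        dec <- population_vector_decode(evoked[, tr], preferred[seq_len(Ne)])
        circular_diff_deg(dec, stims[tr])
      }, numeric(1))
      rows[[paste(cond, nw)]] <- data.frame(condition = cond, network = nw,
                                            error_sd_deg = sd(errs),
                                            n_trials = n_trials)
      all_err[[paste(cond, nw)]] <- errs
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "errors") <- all_err
  out
}

#' Homeostasis combined with additive STDP
#'
#' Recurrent E-to-E synapses follow the additive nearest-neighbour STDP
#' rule (hard bounds, depression slightly stronger) while homeostasis acts
#' on thresholds; both are then frozen and the steady state is probed:
#' weight distribution, rate distribution, spike statistics, and response
#' linearity after an input redraw. Optionally re-runs each condition with
#' static weights obtained by shuffling the final weight matrix of the
#' no-homeostasis network.
#'
#' @param cfg a [sim_config()]; STDP protocols conventionally use
#'   J_ext = 40 nS and C = 250.
#' @param conditions homeostasis conditions; "none" runs STDP without any
#'   homeostasis.
#' @param seed integer seed.
#' @param t_plastic_s duration of the plasticity phase (s).
#' @param probe_s duration of each frozen measurement phase (s).
#' @param input_mean,input_sd static input distribution (Hz).
#' @param cal_s calibration duration (s).
#' @param shuffled_control re-run with shuffled static weights.
#' @return list with `summary` data frame (condition, r2, rate_variance,
#'   weight_bimodality, mean_cv) and per-condition detail (weights, rates,
#'   spike stats); when `shuffled_control`, also `shuffled` results.
#' @export
exp_stdp <- function(cfg, conditions = c("diffusive", "nondiffusive",
                                         "variable", "none"),
                     seed = 1, t_plastic_s = 400, probe_s = 15,
                     input_mean = 10, input_sd = 10, cal_s = 20,
                     cal_rate_hz = 5, var_mean = 2, var_sd = 5,
                     shuffled_control = FALSE) {
  set.seed(seed)
  drive <- draw_static_rates(cfg$N, input_mean, input_sd)
  out <- list(); rows <- list()
  run_cond <- function(cond, weights_override = NULL, stdp_on = TRUE) {
    if (cond == "none") {
      conn <- build_connectivity(cfg$N, cfg$C, seed = seed)
      st <- init_network_state(cfg, conn, seed = seed + 1,
                               stdp = is.null(weights_override))
      if (!is.null(weights_override)) st$weights <- weights_override
      res <- run_network(st, cfg, t_plastic_s, drive, mode = "off",
                         stdp = stdp_on, seed = seed + 3)
      list(result = res, targets = list(target_diff = 1, target_nondiff = 1),
           mode = "off", drive = drive, cfg = cfg)
    } else {
      steady_state_network(cfg, cond, drive, seed = seed,
                           t_homeo_s = t_plastic_s, cal_s = cal_s,
                           cal_rate_hz = cal_rate_hz, var_mean = var_mean,
                           var_sd = var_sd, stdp = stdp_on,
                           init_weights = weights_override)
    }
  }
  probe <- function(net) {
    res <- net$result
    before <- run_network(res$state, net$cfg, probe_s, net$drive,
                          mode = net$mode, freeze = TRUE,
                          target_diff = net$targets$target_diff,
                          target_nondiff = net$targets$target_nondiff,
                          record_spikes = TRUE, seed = seed + 31)
    set.seed(seed + 32)
    drive2 <- draw_static_rates(cfg$N, input_mean, input_sd)
    after <- run_network(before$state, net$cfg, probe_s, drive2,
                         mode = net$mode, freeze = TRUE,
                         target_diff = net$targets$target_diff,
                         target_nondiff = net$targets$target_nondiff,
                         seed = seed + 33)
    nu1 <- mean_rates(before, last_s = probe_s)
    nu2 <- mean_rates(after, last_s = probe_s)
    stats <- spike_statistics(before$spikes, cfg$N)
    list(r2 = response_r2(drive2$rates_raw - net$drive$rates_raw, nu2 - nu1),
         rates = nu1, stats = stats, weights = res$weights)
  }
  for (cond in conditions) {
    net <- run_cond(cond)
    pr <- probe(net)
    ee <- ee_edges(net$result$state$conn)
    rows[[cond]] <- data.frame(
      condition = cond, r2 = pr$r2, rate_variance = var(pr$rates),
      weight_bimodality = weight_bimodality(pr$weights[ee], cfg$g_max,
                                            cfg$g_min),
      mean_cv = mean(pr$stats$cv))
    out[[cond]] <- c(pr, list(network = net))
  }
  res <- list(summary = do.call(rbind, rows), detail = out)
  if (shuffled_control && "none" %in% conditions) {
    wshuf <- out[["none"]]$weights
    conn_none <- out[["none"]]$network$result$state$conn
    ee <- ee_edges(conn_none)
    wshuf <- shuffle_weights(wshuf, ee, seed = seed + 40)
    srows <- list()
    for (cond in setdiff(conditions, "none")) {
      net <- run_cond(cond, weights_override = wshuf, stdp_on = FALSE)
      pr <- probe(net)
      srows[[cond]] <- data.frame(condition = cond, r2 = pr$r2)
    }
    res$shuffled <- do.call(rbind, srows)
  }
  res
}
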