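#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Hill activation of nNOS by calcium, exponent n, half-activation K.
static inline double hill_cpp(double ca, double n, double K) {
  if (ca <= 0.0) return 0.0;
  double cn = std::pow(ca, n);
  return cn / (cn + std::pow(K, n));
}

// One forward-time centred-space step of the 2D diffusion-decay equation on
// a periodic (toroidal) grid. coef = D*dt/ds^2 (must satisfy coef <= 0.25),
// decay = lambda*dt.
static void ftcs_step(std::vector<double>& f, std::vector<double>& tmp,
                      int nx, double coef, double decay) {
  for (int i = 0; i < nx; ++i) {
    const int im = (i == 0) ? nx - 1 : i - 1;
    const int ip = (i == nx - 1) ? 0 : i + 1;
    const double* frow = &f[(size_t)i * nx];
    const double* frm = &f[(size_t)im * nx];
    const double* frp = &f[(size_t)ip * nx];
    double* trow = &tmp[(size_t)i * nx];
    for (int j = 0; j < nx; ++j) {
      const int jm = (j == 0) ? nx - 1 : j - 1;
      const int jp = (j == nx - 1) ? 0 : j + 1;
      const double c = frow[j];
      const double lap = frm[j] + frp[j] + frow[jm] + frow[jp] - 4.0 * c;
      trow[j] = c + coef * lap - decay * c;
    }
  }
  f.swap(tmp);
}

// [[Rcpp::export]]
NumericMatrix cpp_diffuse(NumericMatrix field, int nsteps, double D_um2s,
                          double lambda_s, double ds_um, double dt_s) {
  const int nx = field.nrow();
  if (field.ncol() != nx) stop("field must be square");
  const double coef = D_um2s * dt_s / (ds_um * ds_um);
  if (coef > 0.25) stop("FTCS stability violated: D*dt/ds^2 = %f > 0.25", coef);
  std::vector<double> f((size_t)nx * nx), tmp((size_t)nx * nx);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < nx; ++j) f[(size_t)i * nx + j] = field(i, j);
  const double decay = lambda_s * dt_s;
  for (int k = 0; k < nsteps; ++k) ftcs_step(f, tmp, nx, coef, decay);
  NumericMatrix out(nx, nx);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < nx; ++j) out(i, j) = f[(size_t)i * nx + j];
  return out;
}

// Direct Euler-Maruyama simulation of a white-noise-driven LIF neuron in the
// reduced (dimensionless-voltage) coordinates of the mean-field model:
//   tau_m dv/dt = (mu - v) dt + sigma*sqrt(tau_m) dW,
// threshold theta, reset vr, no refractory period. sigma follows the
// diffusion-approximation convention of the transfer function (stationary
// free membrane sd is sigma/sqrt(2)). Returns the empirical firing rate
// (Hz) for each (mu, sigma, theta) triple; serves as the independent
// oracle for the Ricciardi transfer function. The absorbing threshold is
// lowered by |zeta(1/2)| times the per-step noise sd - the standard
// half-order boundary correction for Euler first-passage times, which
// removes the O(sqrt(dt)) undercount of sub-step excursions.
// [[Rcpp::export]]
NumericVector cpp_lif_rate(NumericVector mu, NumericVector sigma,
                           NumericVector theta, double vr, double tau_m_s,
                           double T_s, double dt_s, int seed) {
  const int n = mu.size();
  if (sigma.size() != n || theta.size() != n) stop("length mismatch");
  NumericVector out(n);
  const long nsteps = (long)std::floor(T_s / dt_s);
  for (int i = 0; i < n; ++i) {
    Xoshiro256 rng((uint64_t)seed * 1000003ULL + (uint64_t)i + 1ULL);
    const double a = dt_s / tau_m_s;
    const double b = sigma[i] * std::sqrt(dt_s / tau_m_s);
    const double th_eff = theta[i] - 0.5826 * b;  // |zeta(1/2)| correction
    double v = vr;
    long count = 0;
    for (long k = 0; k < nsteps; ++k) {
      v += a * (mu[i] - v) + b * rng.norm();
      if (v >= th_eff) {
        ++count;
        v = vr;
      }
    }
    out[i] = (double)count / T_s;
  }
  return out;
}

// Full network simulator. cfg is a list assembled by run_network() in R;
// st is the mutable state list from init_network_state()/a previous call.
// Time unit inside the loop is ms. Chemistry rate constants (lambda, nNOS
// source) are specified per second and converted.
// [[Rcpp::export]]
List cpp_simulate(List cfg, List st) {
  // --- static configuration ---------------------------------------------
  const int N = as<int>(cfg["N"]);
  const int Ne = as<int>(cfg["Ne"]);
  const double dt = as<double>(cfg["dt_ms"]);
  const double duration_ms = as<double>(cfg["duration_ms"]);
  const double El = as<double>(cfg["El"]), vr = as<double>(cfg["vr"]);
  const double Ee = as<double>(cfg["Ee"]), Ei = as<double>(cfg["Ei"]);
  const double cm = as<double>(cfg["cm"]), taum = as<double>(cfg["taum"]);
  const double tref = as<double>(cfg["tref"]);
  const double taue = as<double>(cfg["taue"]), taui = as<double>(cfg["taui"]);
  const double tauOU = as<double>(cfg["tauOU"]);
  const double sigmaOU = as<double>(cfg["sigmaOU"]);
  const double Jext = as<double>(cfg["Jext"]);
  const double i_const = as<double>(cfg["i_const"]);
  const double CaSpike = as<double>(cfg["Ca_spike"]);
  const double tauCa = as<double>(cfg["tauCa"]);
  const double taunNOS = as<double>(cfg["taunNOS"]);
  const double hill_n = as<double>(cfg["hill_n"]);
  const double hill_K = as<double>(cfg["hill_K"]);
  const double D_um2s = as<double>(cfg["D_um2s"]);
  const double lambda_s = as<double>(cfg["lambda_s"]);
  const double ds_um = as<double>(cfg["ds_um"]);
  const double dtdiff = as<double>(cfg["dtdiff_ms"]);
  const int mode = as<int>(cfg["mode"]);  // 0 off, 1 diffusive, 2 non-diffusive, 3 combined
  const bool freeze = as<bool>(cfg["freeze"]);
  const double tauHIP = as<double>(cfg["tauHIP_ms"]);
  const double tauDiffusive = as<double>(cfg["tauDiffusive_ms"]);
  const double tauNonDiffusive = as<double>(cfg["tauNonDiffusive_ms"]);
  const bool stdp = as<bool>(cfg["stdp"]);
  const bool record_spikes = as<bool>(cfg["record_spikes"]);
  const double rate_window_ms = as<double>(cfg["rate_window_ms"]);
  const double snap_ms = as<double>(cfg["snap_ms"]);
  const int seed = as<int>(cfg["seed"]);

  IntegerVector adj_ptr = cfg["adj_ptr"];   // length N+1, 0-based CSR by presynaptic neuron
  IntegerVector adj_post = cfg["adj_post"]; // 0-based postsynaptic indices
  NumericVector w_in = cfg["w"];            // conductance increment per edge, nS
  IntegerVector cell = cfg["cell"];         // 0-based grid cell per neuron
  NumericVector target_diff = cfg["target_diff"];       // length 1 or N
  NumericVector target_nondiff = cfg["target_nondiff"]; // length 1 or N
  NumericMatrix ext_rates = cfg["ext_rates"];           // N x nseg, Hz
  NumericVector seg_end_ms = cfg["seg_end_ms"];         // nseg, increasing

  // STDP bookkeeping (empty unless stdp)
  IntegerVector rev_ptr = cfg["rev_ptr"];   // length Ne+1, incoming E->E edges per post
  IntegerVector rev_edge = cfg["rev_edge"]; // edge index into w
  IntegerVector rev_pre = cfg["rev_pre"];   // presynaptic neuron of that edge
  double Ap = 0, Am = 0, taup = 20, taum_stdp = 20, gmax = 10, gmin = 0;
  if (stdp) {
    Ap = as<double>(cfg["A_plus"]);
    Am = as<double>(cfg["A_minus"]);
    taup = as<double>(cfg["tau_plus"]);
    taum_stdp = as<double>(cfg["tau_minus"]);
    gmax = as<double>(cfg["g_max"]);
    gmin = as<double>(cfg["g_min"]);
  }

  // --- mutable state -----------------------------------------------------
  NumericVector v = clone(as<NumericVector>(st["v"]));
  NumericVector ge = clone(as<NumericVector>(st["ge"]));
  NumericVector gi = clone(as<NumericVector>(st["gi"]));
  NumericVector gx = clone(as<NumericVector>(st["gx"]));
  NumericVector eta = clone(as<NumericVector>(st["eta"]));
  NumericVector refr = clone(as<NumericVector>(st["refr"]));
  NumericVector theta = clone(as<NumericVector>(st["theta"]));
  NumericVector Ca = clone(as<NumericVector>(st["Ca"]));
  NumericVector nNOS = clone(as<NumericVector>(st["nNOS"]));
  NumericVector NOl = clone(as<NumericVector>(st["NO_local"]));
  NumericVector field_in = st["field"];
  NumericVector last_spike = clone(as<NumericVector>(st["last_spike"]));
  const double t0 = as<double>(st["t_ms"]);
  std::vector<double> w(w_in.begin(), w_in.end());

  // raw pointers for the hot loop (avoids SEXP indirection per access)
  double *p_v = v.begin(), *p_ge = ge.begin(), *p_gi = gi.begin(),
         *p_gx = gx.begin(), *p_eta = eta.begin(), *p_refr = refr.begin(),
         *p_theta = theta.begin(), *p_Ca = Ca.begin(), *p_nNOS = nNOS.begin(),
         *p_NOl = NOl.begin(), *p_last = last_spike.begin();
  const int *p_adjptr = adj_ptr.begin(), *p_adjpost = adj_post.begin(),
            *p_cell = cell.begin(), *p_revptr = rev_ptr.begin(),
            *p_revedge = rev_edge.begin(), *p_revpre = rev_pre.begin();

  const int nx = (int)std::lround(std::sqrt((double)field_in.size()));
  if ((size_t)nx * nx != (size_t)field_in.size()) stop("field is not square");
  std::vector<double> field(field_in.begin(), field_in.end());
  std::vector<double> ftmp(field.size());

  // --- precomputed constants --------------------------------------------
  const long nsteps = (long)std::llround(duration_ms / dt);
  const int diff_every = (int)std::llround(dtdiff / dt);
  if (diff_every < 1 || std::fabs(diff_every * dt - dtdiff) > 1e-9)
    stop("dtdiff_ms must be a positive multiple of dt_ms");
  const double dtd_s = dtdiff / 1000.0;
  const double coef = D_um2s * dtd_s / (ds_um * ds_um);
  if (coef > 0.25)
    stop("FTCS stability violated: D*dt/ds^2 = %f > 0.25", coef);
  const double decay = lambda_s * dtd_s;
  const double dge = std::exp(-dt / taue), dgi = std::exp(-dt / taui);
  const double dCa = std::exp(-dt / tauCa);
  const double ou_a = std::exp(-dt / tauOU);
  const double ou_b = std::sqrt(1.0 - ou_a * ou_a);
  const double inv_cm_ms = 0.001 / cm;  // nS*mV -> mV/ms
  const bool tg_diff_scalar = (target_diff.size() == 1);
  const bool tg_nond_scalar = (target_nondiff.size() == 1);

  Xoshiro256 rng((uint64_t)seed + 0x5DEECE66DULL);

  // external-arrival probabilities for the current drive segment
  const int nseg = seg_end_ms.size();
  std::vector<double> pext(N);
  int seg = 0;
  auto load_segment = [&](int s) {
    for (int i = 0; i < N; ++i) {
      double r = ext_rates(i, s);
      pext[i] = (r > 0.0) ? r * dt / 1000.0 : 0.0;
    }
  };
  load_segment(0);

  // recording
  const long win_steps =
      rate_window_ms > 0 ? (long)std::llround(rate_window_ms / dt) : 0;
  const int nwin = win_steps > 0 ? (int)(nsteps / win_steps) : 0;
  std::vector<int> win_counts((size_t)N * (nwin > 0 ? nwin : 0), 0);
  const long snap_steps = snap_ms > 0 ? (long)std::llround(snap_ms / dt) : 0;
  const int nsnap = snap_steps > 0 ? (int)(nsteps / snap_steps) : 0;
  NumericMatrix theta_snap(nsnap > 0 ? N : 0, nsnap > 0 ? nsnap : 0);
  NumericMatrix no_diff_snap(nsnap > 0 ? N : 0, nsnap > 0 ? nsnap : 0);
  NumericMatrix no_nond_snap(nsnap > 0 ? N : 0, nsnap > 0 ? nsnap : 0);
  std::vector<double> spike_t;
  std::vector<int> spike_id;
  if (record_spikes) {
    spike_t.reserve(100000);
    spike_id.reserve(100000);
  }
  long total_spikes = 0, guard_skips = 0;
  std::vector<int> spiked;
  spiked.reserve(256);

  // --- main loop ---------------------------------------------------------
  for (long step = 0; step < nsteps; ++step) {
    const double t = t0 + step * dt;
    // drive segments are timed relative to the start of this run
    if (seg < nseg - 1 && step * dt >= seg_end_ms[seg]) {
      ++seg;
      load_segment(seg);
    }
    spiked.clear();

    for (int i = 0; i < N; ++i) {
      p_ge[i] *= dge;
      p_gi[i] *= dgi;
      p_gx[i] *= dge;
      if (pext[i] > 0.0 && rng.unif() < pext[i]) p_gx[i] += Jext;
      p_eta[i] = ou_a * p_eta[i] + ou_b * rng.norm();
      p_Ca[i] *= dCa;
      if (p_refr[i] > 0.0) {
        p_refr[i] -= dt;
        p_v[i] = vr;
      } else {
        const double vi = p_v[i];
        const double dv =
            dt * ((El - vi) / taum +
                  (p_ge[i] * (Ee - vi) + p_gi[i] * (Ei - vi) +
                   p_gx[i] * (Ee - vi)) *
                      inv_cm_ms +
                  sigmaOU * p_eta[i] + i_const);
        double vn = vi + dv;
        if (vn >= p_theta[i]) {
          spiked.push_back(i);
          vn = vr;
          p_refr[i] = tref;
          p_Ca[i] += CaSpike;
          ++total_spikes;
          if (record_spikes) {
            spike_t.push_back(t + dt);
            spike_id.push_back(i + 1);
          }
          if (nwin > 0) {
            int wi = (int)(step / win_steps);
            if (wi < nwin) win_counts[(size_t)wi * N + i] += 1;
          }
        }
        p_v[i] = vn;
      }
    }

    // synaptic transmission (effective at the next integration step) and STDP
    for (size_t si = 0; si < spiked.size(); ++si) {
      const int s = spiked[si];
      const bool is_exc = s < Ne;
      if (is_exc) {
        for (int e = p_adjptr[s]; e < p_adjptr[s + 1]; ++e)
          p_ge[p_adjpost[e]] += w[e];
      } else {
        for (int e = p_adjptr[s]; e < p_adjptr[s + 1]; ++e)
          p_gi[p_adjpost[e]] += w[e];
      }
      if (stdp && is_exc) {
        const double tnow = t + dt;
        // presynaptic spike: depress its E->E synapses by the time since the
        // most recent postsynaptic spike (nearest-neighbour pairing)
        for (int e = p_adjptr[s]; e < p_adjptr[s + 1]; ++e) {
          const int post = p_adjpost[e];
          if (post >= Ne) continue;
          const double tp = p_last[post];
          if (tp > -1e17) {
            double nw = w[e] - Am * std::exp(-(tnow - tp) / taum_stdp) * gmax;
            w[e] = nw < gmin ? gmin : nw;
          }
        }
        // postsynaptic spike: potentiate incoming E->E synapses by the time
        // since each presynaptic neuron's most recent spike
        for (int e = p_revptr[s]; e < p_revptr[s + 1]; ++e) {
          const double tp = p_last[p_revpre[e]];
          if (tp > -1e17) {
            const int ei = p_revedge[e];
            double nw = w[ei] + Ap * std::exp(-(tnow - tp) / taup) * gmax;
            w[ei] = nw > gmax ? gmax : nw;
          }
        }
      }
    }
    if (stdp) {
      for (size_t si = 0; si < spiked.size(); ++si)
        p_last[spiked[si]] = t + dt;
    }

    // chemistry, diffusion and threshold homeostasis at the coarse timestep
    if ((step + 1) % diff_every == 0) {
      for (int i = 0; i < N; ++i)
        p_nNOS[i] += (dtdiff / taunNOS) *
                     (hill_cpp(p_Ca[i], hill_n, hill_K) - p_nNOS[i]);
      ftcs_step(field, ftmp, nx, coef, decay);
      for (int i = 0; i < N; ++i) field[p_cell[i]] += p_nNOS[i] * dtd_s;
      for (int i = 0; i < N; ++i)
        p_NOl[i] += dtd_s * (p_nNOS[i] - lambda_s * p_NOl[i]);

      if (!freeze && mode != 0) {
        for (int i = 0; i < N; ++i) {
          double dth = 0.0;
          bool ok = false;
          if (mode == 1 || mode == 3) {
            const double no = field[p_cell[i]];
            const double tg = tg_diff_scalar ? target_diff[0] : target_diff[i];
            if (no > 0.0) {
              dth += (dtdiff / (mode == 1 ? tauHIP : tauDiffusive)) *
                     (no - tg) / no;
              ok = true;
            }
          }
          if (mode == 2 || mode == 3) {
            const double no = p_NOl[i];
            const double tg = tg_nond_scalar ? target_nondiff[0] : target_nondiff[i];
            if (no > 0.0) {
              dth += (dtdiff / (mode == 2 ? tauHIP : tauNonDiffusive)) *
                     (no - tg) / no;
              ok = true;
            }
          }
          if (ok)
            p_theta[i] += dth;
          else
            ++guard_skips;
        }
      }

      if (nsnap > 0 && (step + 1) % snap_steps == 0) {
        const int sn = (int)((step + 1) / snap_steps) - 1;
        if (sn < nsnap) {
          for (int i = 0; i < N; ++i) {
            theta_snap(i, sn) = p_theta[i];
            no_diff_snap(i, sn) = field[p_cell[i]];
            no_nond_snap(i, sn) = p_NOl[i];
          }
        }
      }
    }

    if ((step & 1023) == 0 && !R_finite(v[0]))
      stop("numerical instability: non-finite membrane potential at t = %f ms",
           t);
  }

  for (int i = 0; i < N; ++i) {
    if (!R_finite(v[i]) || !R_finite(theta[i]))
      stop("numerical instability: non-finite state at end of run (neuron %d)",
           i + 1);
  }

  // --- pack results ------------------------------------------------------
  NumericVector field_out(field.size());
  std::copy(field.begin(), field.end(), field_out.begin());
  NumericVector w_out(w.size());
  std::copy(w.begin(), w.end(), w_out.begin());
  NumericVector no_sample(N);
  for (int i = 0; i < N; ++i) no_sample[i] = field[p_cell[i]];

  NumericMatrix rates(nwin > 0 ? N : 0, nwin > 0 ? nwin : 0);
  NumericVector rate_t(nwin > 0 ? nwin : 0);
  if (nwin > 0) {
    const double win_s = rate_window_ms / 1000.0;
    for (int wi = 0; wi < nwin; ++wi) {
      for (int i = 0; i < N; ++i)
        rates(i, wi) = win_counts[(size_t)wi * N + i] / win_s;
      rate_t[wi] = (t0 + (wi + 0.5) * rate_window_ms) / 1000.0;
    }
  }
  NumericVector snap_t(nsnap > 0 ? nsnap : 0);
  for (int sn = 0; sn < nsnap; ++sn)
    snap_t[sn] = (t0 + (sn + 1) * snap_ms) / 1000.0;

  List state = List::create(
      _["v"] = v, _["ge"] = ge, _["gi"] = gi, _["gx"] = gx, _["eta"] = eta,
      _["refr"] = refr, _["theta"] = theta, _["Ca"] = Ca, _["nNOS"] = nNOS,
      _["NO_local"] = NOl, _["field"] = field_out, _["last_spike"] = last_spike,
      _["t_ms"] = t0 + nsteps * dt);
  return List::create(
      _["state"] = state, _["weights"] = w_out, _["rates"] = rates,
      _["rate_t"] = rate_t, _["theta_snap"] = theta_snap,
      _["no_diff_snap"] = no_diff_snap, _["no_nondiff_snap"] = no_nond_snap,
      _["snap_t"] = snap_t, _["no_sample"] = no_sample,
      _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["n_spikes"] = (double)total_spikes,
      _["guard_skips"] = (double)guard_skips);
}
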