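// Stochastic mesoscopic population integrator.
//
// Evolves, for each population, circular buffers over K refractory states
// (expected survival numbers m_bar, survival-number variances v, membrane
// potentials u, conditional intensities lambda, spike-count history dn)
// plus the free-neuron scalars (h, g_l, x, z) and synaptic filters y, and
// samples one spike count per population per step from the expected count.
// All model tables (theta, quasi-renewal kernel, decay factors) are
// precomputed on the R side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double EXP_CAP = 20.0;

struct PopState {
  // parameters
  double N, u_th, u_r, u_rest, c, delta_u, em, coefA;
  int K, k_ref, variant; // variant: 0 = GIF, 1 = GLM
  std::vector<double> theta_tab, qr_tab, eta_tab; // indexed by lag 0..K+1
  std::vector<double> g_decay, g_w;               // adaptation components
  std::vector<double> Jcoup, es, coefY;           // per source population
  std::vector<int> delay_steps;
  // state
  std::vector<double> m, v, u, lam, dn, P; // circular buffers + scratch
  std::vector<double> g, y;
  double h, lam_free, x, z;
};

static double hazard(double u, double th, double c, double du) {
  double a = (u - th) / du;
  if (a > EXP_CAP) a = EXP_CAP;
  return c * std::exp(a);
}

// sampling_mode: 0 binomial, 1 poisson, 2 gaussian, 3 expected
static double draw_count(double dn_bar, double N, int mode) {
  if (mode == 3) return dn_bar;
  if (dn_bar <= 0.0) return 0.0;
  double out;
  if (mode == 0) {
    out = R::rbinom(N, dn_bar / N);
  } else if (mode == 1) {
    out = R::rpois(dn_bar);
  } else {
    out = std::floor(dn_bar + std::sqrt(dn_bar) * R::norm_rand() + 0.5);
  }
  if (out < 0.0) out = 0.0;
  if (out > N) out = N;
  return out;
}

// [[Rcpp::export]]
List meso_run_cpp(List pops, NumericMatrix stim, int n_steps, int n_warm,
                  double dt, int sampling_mode, bool record_expected,
                  bool record_free, bool init_free, Nullable<List> state0,
                  NumericVector A_pre) {
  int M = pops.size();
  int n_tot = n_steps + n_warm;
  std::vector<PopState> st(M);
  for (int a = 0; a < M; ++a) {
    List pp = pops[a];
    PopState &s = st[a];
    s.N = as<double>(pp["N"]);
    s.K = as<int>(pp["K"]);
    s.k_ref = as<int>(pp["k_ref"]);
    s.variant = as<int>(pp["variant"]);
    s.u_th = as<double>(pp["u_th"]);
    s.u_r = as<double>(pp["u_r"]);
    s.u_rest = as<double>(pp["u_rest"]);
    s.c = as<double>(pp["c"]);
    s.delta_u = as<double>(pp["delta_u"]);
    s.em = as<double>(pp["em"]);
    s.coefA = as<double>(pp["coefA"]);
    s.theta_tab = as<std::vector<double> >(pp["theta_tab"]);
    s.qr_tab = as<std::vector<double> >(pp["qr_tab"]);
    s.eta_tab = as<std::vector<double> >(pp["eta_tab"]);
    s.g_decay = as<std::vector<double> >(pp["g_decay"]);
    s.g_w = as<std::vector<double> >(pp["g_w"]);
    s.Jcoup = as<std::vector<double> >(pp["Jcoup"]);
    s.es = as<std::vector<double> >(pp["es"]);
    s.coefY = as<std::vector<double> >(pp["coefY"]);
    s.delay_steps = as<std::vector<int> >(pp["delay_steps"]);
    int K = s.K;
    s.m.assign(K, 0.0); s.v.assign(K, 0.0); s.u.assign(K, s.u_r);
    s.lam.assign(K, 0.0); s.dn.assign(K, 0.0); s.P.assign(K, 0.0);
    s.g.assign(s.g_decay.size(), 0.0);
    s.y.assign(M, 0.0);
    s.h = s.u_rest;
    s.lam_free = hazard(s.h, s.u_th, s.c, s.delta_u);
    s.x = 0.0; s.z = 0.0;
    if (state0.isNotNull()) {
      // explicit initial state (e.g. the asynchronous stationary state)
      List s0 = as<List>(as<List>(state0)[a]);
      s.m = as<std::vector<double> >(s0["m"]);
      s.v = as<std::vector<double> >(s0["v"]);
      s.u = as<std::vector<double> >(s0["u"]);
      s.lam = as<std::vector<double> >(s0["lam"]);
      s.dn = as<std::vector<double> >(s0["dn"]);
      s.g = as<std::vector<double> >(s0["g"]);
      s.y = as<std::vector<double> >(s0["y"]);
      s.h = as<double>(s0["h"]);
      s.lam_free = as<double>(s0["lam_free"]);
      s.x = as<double>(s0["x"]);
      s.z = as<double>(s0["z"]);
    } else if (init_free) {
      // desynchronized start: all neurons in the free pool, no history
      s.x = s.N;
    } else {
      // full synchronization at t = -dt: bin -1 holds all N neurons
      int slot = ((-1) % K + K) % K;
      s.m[slot] = s.N;
      s.dn[slot] = s.N;
    }
  }

  // full activity history (1/s); index j+1 corresponds to bin j, entry 0 is
  // the synchronization pulse in bin -1 (absent for the free start); bins
  // before the stored history are read from A_pre (stationary start)
  std::vector<std::vector<double> > A(M, std::vector<double>(n_tot + 1, 0.0));
  if (state0.isNotNull()) {
    for (int a = 0; a < M; ++a) A[a][0] = A_pre[a];
  } else if (!init_free) {
    for (int a = 0; a < M; ++a) A[a][0] = 1.0 / dt;
  }

  NumericMatrix counts(n_steps, M);
  NumericMatrix expected(record_expected ? n_steps : 0, record_expected ? M : 0);
  NumericMatrix free_pot(record_free ? n_steps : 0, record_free ? M : 0);
  NumericMatrix free_th(record_free ? n_steps : 0, record_free ? M : 0);

  for (int l = 0; l < n_tot; ++l) {
    int mode = (l < n_warm) ? 3 : sampling_mode;
    for (int a = 0; a < M; ++a) {
      PopState &s = st[a];
      int K = s.K;
      // 1. total integrated input over the step (exact for piecewise-
      //    constant stimulus and delayed activities)
      double h_tot = stim(l, a) * (1.0 - s.em);
      for (int b = 0; b < M; ++b) {
        int idx = l - s.delay_steps[b] + 1;
        double Ad = (idx >= 0) ? A[b][idx] : A_pre[b];
        if (s.Jcoup[b] == 0.0) { // still decay the filter
          s.y[b] = Ad + (s.y[b] - Ad) * s.es[b];
          continue;
        }
        h_tot += s.Jcoup[b] * (Ad * s.coefA + (s.y[b] - Ad) * s.coefY[b]);
        s.y[b] = Ad + (s.y[b] - Ad) * s.es[b];
      }
      // 2. free neurons: adaptation variables g (driven by the bin leaving
      //    the explicit history), threshold, potential, intensity
      int slot_old = ((l - K) % K + K) % K; // == l mod K
      double A_old = s.dn[slot_old] / (s.N * dt);
      double th_free = s.u_th;
      for (size_t q = 0; q < s.g.size(); ++q) {
        s.g[q] = s.g[q] * s.g_decay[q] + A_old * (1.0 - s.g_decay[q]);
        th_free += s.g_w[q] * s.g[q];
      }
      double h_new = s.u_rest + (s.h - s.u_rest) * s.em + h_tot;
      double lam_free_new = hazard(h_new, th_free, s.c, s.delta_u);
      double P_free = 1.0 - std::exp(-0.5 * (s.lam_free + lam_free_new) * dt);
      // 3. refractory sweep at the advanced time t_{l+1}
      double th_hat = th_free - s.qr_tab[K + 1] * s.dn[slot_old];
      double sum_Pm = 0.0, sum_m = 0.0, sum_Pv = 0.0, sum_v = 0.0;
      for (int jj = 0; jj < K; ++jj) {
        int k = l - K + jj;
        int slot = (k % K + K) % K;
        int lag_next = K + 1 - jj;      // (l+1) - k
        int elapsed = K - jj;           // l - k
        double u_val;
        if (s.variant == 0) {
          if (elapsed >= s.k_ref) {
            s.u[slot] = s.u_rest + (s.u[slot] - s.u_rest) * s.em + h_tot;
          } else {
            s.u[slot] = s.u_r;
          }
          u_val = s.u[slot];
        } else {
          u_val = h_new + s.eta_tab[lag_next];
        }
        double lam_new = 0.0;
        if (elapsed + 1 > s.k_ref) {
          lam_new = hazard(u_val, th_hat + s.theta_tab[lag_next], s.c,
                           s.delta_u);
        }
        s.P[jj] = 1.0 - std::exp(-0.5 * (s.lam[slot] + lam_new) * dt);
        s.lam[slot] = lam_new;
        sum_Pm += s.P[jj] * s.m[slot];
        sum_m += s.m[slot];
        sum_Pv += s.P[jj] * s.v[slot];
        sum_v += s.v[slot];
        th_hat += s.qr_tab[lag_next] * s.dn[slot];
      }
      // 4. effective firing probability (variance-weighted)
      double denom = sum_v + s.z;
      double P_Lam = (denom > 0.0) ? (sum_Pv + P_free * s.z) / denom : P_free;
      // 5. expected spike count, clipped to [0, N]
      double dn_bar = sum_Pm + P_free * s.x + P_Lam * (s.N - sum_m - s.x);
      if (dn_bar < 0.0) dn_bar = 0.0;
      if (dn_bar > s.N) dn_bar = s.N;
      if (!R_finite(dn_bar)) {
        stop("non-finite expected spike count at step %d, population %d",
             l + 1, a + 1);
      }
      double dn_new = draw_count(dn_bar, s.N, mode);
      // 6. moment updates; oldest bin is absorbed into the free pool
      double m_oldest = 0.0, v_oldest = 0.0;
      for (int jj = 0; jj < K; ++jj) {
        int slot = ((l - K + jj) % K + K) % K;
        double q = 1.0 - s.P[jj];
        double m_old = s.m[slot];
        s.m[slot] = q * m_old;
        s.v[slot] = q * q * s.v[slot] + s.P[jj] * m_old;
        if (jj == 0) { m_oldest = s.m[slot]; v_oldest = s.v[slot]; }
      }
      double qf = 1.0 - P_free;
      double z_new = qf * qf * s.z + P_free * s.x + v_oldest;
      s.x = qf * s.x + m_oldest;
      s.z = z_new;
      // 7. boundary conditions for the new bin l
      s.m[slot_old] = dn_new;
      s.v[slot_old] = 0.0;
      s.u[slot_old] = s.u_r;
      s.lam[slot_old] = 0.0;
      s.dn[slot_old] = dn_new;
      s.h = h_new;
      s.lam_free = lam_free_new;
      A[a][l + 1] = dn_new / (s.N * dt);
      if (l >= n_warm) {
        counts(l - n_warm, a) = dn_new;
        if (record_expected) expected(l - n_warm, a) = dn_bar / (s.N * dt);
        if (record_free) {
          free_pot(l - n_warm, a) = h_new;
          free_th(l - n_warm, a) = th_free;
        }
      }
    }
  }
  List out = List::create(Named("counts") = counts);
  if (record_expected) out["expected"] = expected;
  if (record_free) {
    out["free_potential"] = free_pot;
    out["free_threshold"] = free_th;
  }
  return out;
}
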