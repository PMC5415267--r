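// Intermediate binomial survival-number process for a single population:
// the refractory distribution m(t_l, t_k) is evolved explicitly, with a
// binomial number of firings X_lk ~ B(m(t_l,t_k), P_lambda(t_l|t_k)) drawn
// for every occupied refractory state and for the free pool. Neuron
// numbers are conserved exactly (sum_k m + free = N at every step). The
// hazards use the same mean-field membrane/threshold machinery as the
// mesoscopic integrator.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double EXP_CAP_DENS = 20.0;

static inline double hzd(double u, double th, double c, double du) {
  double a = (u - th) / du;
  if (a > EXP_CAP_DENS) a = EXP_CAP_DENS;
  return c * std::exp(a);
}

// [[Rcpp::export]]
List density_run_cpp(List pp, NumericVector stim, int n_steps, double dt,
                     bool init_free) {
  int N = as<int>(pp["N"]);
  int K = as<int>(pp["K"]);
  int k_ref = as<int>(pp["k_ref"]);
  int variant = as<int>(pp["variant"]);
  double u_th = as<double>(pp["u_th"]);
  double u_r = as<double>(pp["u_r"]);
  double u_rest = as<double>(pp["u_rest"]);
  double c = as<double>(pp["c"]);
  double du = as<double>(pp["delta_u"]);
  double em = as<double>(pp["em"]);
  double coefA = as<double>(pp["coefA"]);
  std::vector<double> theta_tab = as<std::vector<double> >(pp["theta_tab"]);
  std::vector<double> qr_tab = as<std::vector<double> >(pp["qr_tab"]);
  std::vector<double> eta_tab = as<std::vector<double> >(pp["eta_tab"]);
  std::vector<double> g_decay = as<std::vector<double> >(pp["g_decay"]);
  std::vector<double> g_w = as<std::vector<double> >(pp["g_w"]);
  double Jcoup = as<std::vector<double> >(pp["Jcoup"])[0];
  double es = as<std::vector<double> >(pp["es"])[0];
  double coefY = as<std::vector<double> >(pp["coefY"])[0];
  int dstep = as<std::vector<int> >(pp["delay_steps"])[0];

  std::vector<int> m(K, 0), dn(K, 0);
  std::vector<double> u(K, u_r), lam(K, 0.0), g(g_decay.size(), 0.0);
  double h = u_rest, lam_free = hzd(h, u_th, c, du), y = 0.0;
  int freeN = 0;
  std::vector<double> A(n_steps + 1, 0.0);
  if (init_free) {
    freeN = N;
  } else {
    int slot_init = ((-1) % K + K) % K;
    m[slot_init] = N;
    dn[slot_init] = N;
    A[0] = 1.0 / dt;
  }

  NumericMatrix counts(n_steps, 1);
  IntegerVector total(n_steps);

  for (int l = 0; l < n_steps; ++l) {
    double h_tot = stim[l] * (1.0 - em);
    int idx = l - dstep + 1;
    double Ad = (idx >= 0) ? A[idx] : 0.0;
    if (Jcoup != 0.0) h_tot += Jcoup * (Ad * coefA + (y - Ad) * coefY);
    y = Ad + (y - Ad) * es;

    int slot_old = ((l - K) % K + K) % K;
    double A_old = (double)dn[slot_old] / (N * dt);
    double th_free = u_th;
    for (size_t q = 0; q < g.size(); ++q) {
      g[q] = g[q] * g_decay[q] + A_old * (1.0 - g_decay[q]);
      th_free += g_w[q] * g[q];
    }
    double h_new = u_rest + (h - u_rest) * em + h_tot;
    double lam_free_new = hzd(h_new, th_free, c, du);
    double P_free = 1.0 - std::exp(-0.5 * (lam_free + lam_free_new) * dt);

    double th_hat = th_free - qr_tab[K + 1] * dn[slot_old];
    int dn_new = 0;
    // free-pool firings
    if (freeN > 0 && P_free > 0.0) {
      int Xf = (int)R::rbinom((double)freeN, P_free);
      freeN -= Xf;
      dn_new += Xf;
    }
    for (int jj = 0; jj < K; ++jj) {
      int k = l - K + jj;
      int slot = (k % K + K) % K;
      int lag_next = K + 1 - jj;
      int elapsed = K - jj;
      double u_val;
      if (variant == 0) {
        if (elapsed >= k_ref) {
          u[slot] = u_rest + (u[slot] - u_rest) * em + h_tot;
        } else {
          u[slot] = u_r;
        }
        u_val = u[slot];
      } else {
        u_val = h_new + eta_tab[lag_next];
      }
      double lam_new = 0.0;
      if (elapsed + 1 > k_ref)
        lam_new = hzd(u_val, th_hat + theta_tab[lag_next], c, du);
      double P = 1.0 - std::exp(-0.5 * (lam[slot] + lam_new) * dt);
      lam[slot] = lam_new;
      if (m[slot] > 0 && P > 0.0) {
        int X = (int)R::rbinom((double)m[slot], P);
        m[slot] -= X;
        dn_new += X;
      }
      th_hat += qr_tab[lag_next] * dn[slot];
    }
    // oldest surviving cohort joins the free pool; its slot is recycled
    freeN += m[slot_old];
    m[slot_old] = dn_new;
    dn[slot_old] = dn_new;
    u[slot_old] = u_r;
    lam[slot_old] = 0.0;
    h = h_new;
    lam_free = lam_free_new;
    A[l + 1] = (double)dn_new / (N * dt);
    counts(l, 0) = (double)dn_new;
    // conservation check: sum of survivals plus free pool equals N
    long tot = freeN;
    for (int jj = 0; jj < K; ++jj) tot += m[jj];
    total[l] = (int)tot;
    if (tot != N)
      stop("neuron-number conservation violated at step %d (sum = %d, N = %d)",
           l + 1, (int)tot, N);
  }
  return List::create(Named("counts") = counts, Named("total") = total);
}
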