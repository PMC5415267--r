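// Microscopic GIF/GLM network simulator with fixed in-degree random
// connectivity. Each neuron carries its membrane potential (or free
// potential for the GLM variant), one exponential state per threshold
// kernel component, per-source synaptic filter states and the time since
// its last spike. Spikes are delivered to postsynaptic targets after the
// pair-specific transmission delay; the delayed afferent spike count of a
// bin is treated as a constant rate over the step and integrated with the
// same exact two-exponential update as the mesoscopic equations.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double EXP_CAP_MICRO = 20.0;

static inline double hz(double u, double th, double c, double du) {
  double a = (u - th) / du;
  if (a > EXP_CAP_MICRO) a = EXP_CAP_MICRO;
  return c * std::exp(a);
}

// [[Rcpp::export]]
List micro_run_cpp(List pops, List conn, NumericMatrix stim, int n_steps,
                   int n_warm, double dt, bool record_raster,
                   bool init_free) {
  int M = pops.size();
  int n_tot = n_steps + n_warm;

  // unpack parameters
  std::vector<int> N(M), k_ref(M), variant(M);
  std::vector<double> u_th(M), u_r(M), u_rest(M), cc(M), du(M), em(M),
      coefA(M);
  std::vector<std::vector<double> > th_jump(M), th_decay(M), eta_jump(M),
      eta_decay(M), es(M), coefY(M);
  std::vector<std::vector<int> > dstep(M);
  std::vector<std::vector<double> > w(M);
  for (int a = 0; a < M; ++a) {
    List pp = pops[a];
    N[a] = as<int>(pp["N"]);
    k_ref[a] = as<int>(pp["k_ref"]);
    variant[a] = as<int>(pp["variant"]);
    u_th[a] = as<double>(pp["u_th"]);
    u_r[a] = as<double>(pp["u_r"]);
    u_rest[a] = as<double>(pp["u_rest"]);
    cc[a] = as<double>(pp["c"]);
    du[a] = as<double>(pp["delta_u"]);
    em[a] = as<double>(pp["em"]);
    coefA[a] = as<double>(pp["coefA"]);
    th_jump[a] = as<std::vector<double> >(pp["th_jump"]);
    th_decay[a] = as<std::vector<double> >(pp["th_decay"]);
    eta_jump[a] = as<std::vector<double> >(pp["eta_jump"]);
    eta_decay[a] = as<std::vector<double> >(pp["eta_decay"]);
    es[a] = as<std::vector<double> >(pp["es"]);
    coefY[a] = as<std::vector<double> >(pp["coefY"]);
    dstep[a] = as<std::vector<int> >(pp["delay_steps"]);
    w[a] = as<std::vector<double> >(pp["w"]);
  }

  // connectivity as postsynaptic (out) lists per source population/neuron:
  // out_start[b][j] .. out_start[b][j+1]-1 index (out_pop, out_idx)
  std::vector<std::vector<int> > out_start(M), out_pop(M), out_idx(M);
  for (int b = 0; b < M; ++b) {
    List cb = conn[b];
    out_start[b] = as<std::vector<int> >(cb["start"]);
    out_pop[b] = as<std::vector<int> >(cb["pop"]);
    out_idx[b] = as<std::vector<int> >(cb["idx"]);
  }

  // future-arrival rings: ring[a][b] has L slots of per-neuron counts
  int D_max = 1;
  for (int a = 0; a < M; ++a)
    for (int b = 0; b < M; ++b)
      if (dstep[a][b] > D_max) D_max = dstep[a][b];
  int L = D_max + 1;
  std::vector<std::vector<std::vector<double> > > ring(M);
  for (int a = 0; a < M; ++a) {
    ring[a].assign(M, std::vector<double>());
    for (int b = 0; b < M; ++b) ring[a][b].assign((size_t)L * N[a], 0.0);
  }

  // neuron state
  std::vector<std::vector<double> > u(M), hfree(M), lam(M);
  std::vector<std::vector<double> > thstate(M), etastate(M), y(M);
  std::vector<std::vector<int> > elapsed(M);
  for (int a = 0; a < M; ++a) {
    u[a].assign(N[a], init_free ? u_rest[a] : u_r[a]);
    hfree[a].assign(N[a], u_rest[a]);
    lam[a].assign(N[a], 0.0);
    thstate[a].assign((size_t)th_jump[a].size() * N[a], 0.0);
    etastate[a].assign((size_t)eta_jump[a].size() * N[a], 0.0);
    y[a].assign((size_t)M * N[a], 0.0);
    if (init_free) {
      elapsed[a].assign(N[a], 1000000); // no spike history
      for (int i = 0; i < N[a]; ++i)
        lam[a][i] = hz(u[a][i], u_th[a], cc[a], du[a]);
    } else {
      elapsed[a].assign(N[a], 1); // synchronized spike at bin -1
      // threshold/after-potential states of the initial spike, valid at t_0
      for (size_t q = 0; q < th_jump[a].size(); ++q)
        for (int i = 0; i < N[a]; ++i)
          thstate[a][q * N[a] + i] = th_jump[a][q] * th_decay[a][q];
      for (size_t q = 0; q < eta_jump[a].size(); ++q)
        for (int i = 0; i < N[a]; ++i)
          etastate[a][q * N[a] + i] = eta_jump[a][q] * eta_decay[a][q];
    }
  }
  if (!init_free) {
    // deliver the synchronization spikes (bin -1) to their targets
    for (int b = 0; b < M; ++b) {
      for (int j = 0; j < N[b]; ++j) {
        for (int s = out_start[b][j]; s < out_start[b][j + 1]; ++s) {
          int a = out_pop[b][s], i = out_idx[b][s];
          int arrive = -1 + dstep[a][b];
          if (arrive >= 0 && arrive < L)
            ring[a][b][(size_t)(arrive % L) * N[a] + i] += 1.0;
        }
      }
    }
  }

  NumericMatrix counts(n_steps, M);
  std::vector<int> ras_bin, ras_pop, ras_idx;

  std::vector<std::vector<int> > spikers(M);

  for (int l = 0; l < n_tot; ++l) {
    for (int a = 0; a < M; ++a) spikers[a].clear();
    for (int a = 0; a < M; ++a) {
      double RIpart = stim(l, a) * (1.0 - em[a]);
      int nth = (int)th_jump[a].size();
      int neta = (int)eta_jump[a].size();
      for (int i = 0; i < N[a]; ++i) {
        // synaptic input: exact one-step solution per source population
        double h_tot = RIpart;
        for (int b = 0; b < M; ++b) {
          double cnt = ring[a][b][(size_t)(l % L) * N[a] + i];
          double Ad = cnt / dt;
          double y0 = y[a][(size_t)b * N[a] + i];
          if (w[a][b] != 0.0)
            h_tot += w[a][b] * (Ad * coefA[a] + (y0 - Ad) * coefY[a][b]);
          y[a][(size_t)b * N[a] + i] = Ad + (y0 - Ad) * es[a][b];
        }
        // membrane potential at t_{l+1}
        double u_new;
        if (variant[a] == 0) {
          if (elapsed[a][i] >= k_ref[a]) {
            u_new = u_rest[a] + (u[a][i] - u_rest[a]) * em[a] + h_tot;
          } else {
            u_new = u_r[a];
          }
        } else {
          hfree[a][i] = u_rest[a] + (hfree[a][i] - u_rest[a]) * em[a] + h_tot;
          double eta_sum = 0.0;
          for (int q = 0; q < neta; ++q) {
            double v = etastate[a][(size_t)q * N[a] + i] * eta_decay[a][q];
            etastate[a][(size_t)q * N[a] + i] = v;
            eta_sum += v;
          }
          u_new = hfree[a][i] + eta_sum;
        }
        // dynamic threshold at t_{l+1} (decay the component states)
        double th_new = u_th[a];
        for (int q = 0; q < nth; ++q) {
          double v = thstate[a][(size_t)q * N[a] + i] * th_decay[a][q];
          thstate[a][(size_t)q * N[a] + i] = v;
          th_new += v;
        }
        double lam_new = 0.0;
        if (elapsed[a][i] + 1 > k_ref[a])
          lam_new = hz(u_new, th_new, cc[a], du[a]);
        double P = 1.0 - std::exp(-0.5 * (lam[a][i] + lam_new) * dt);
        bool spike = false;
        if (P > 0.0) spike = (unif_rand() < P);
        if (spike) {
          spikers[a].push_back(i);
          elapsed[a][i] = 0;
          if (variant[a] == 0) u_new = u_r[a];
          for (int q = 0; q < nth; ++q)
            thstate[a][(size_t)q * N[a] + i] += th_jump[a][q] * th_decay[a][q];
          for (int q = 0; q < neta; ++q)
            etastate[a][(size_t)q * N[a] + i] +=
                eta_jump[a][q] * eta_decay[a][q];
          lam_new = 0.0;
          if (record_raster && l >= n_warm) {
            ras_bin.push_back(l - n_warm);
            ras_pop.push_back(a + 1);
            ras_idx.push_back(i + 1);
          }
        } else {
          elapsed[a][i] += 1;
        }
        u[a][i] = u_new;
        lam[a][i] = lam_new;
      }
      if (l >= n_warm) counts(l - n_warm, a) = (double)spikers[a].size();
    }
    // clear the consumed ring slot and deliver this bin's spikes
    for (int a = 0; a < M; ++a)
      for (int b = 0; b < M; ++b)
        std::fill(ring[a][b].begin() + (size_t)(l % L) * N[a],
                  ring[a][b].begin() + (size_t)(l % L + 1) * N[a], 0.0);
    for (int b = 0; b < M; ++b) {
      for (size_t sp = 0; sp < spikers[b].size(); ++sp) {
        int j = spikers[b][sp];
        for (int s = out_start[b][j]; s < out_start[b][j + 1]; ++s) {
          int a = out_pop[b][s], i = out_idx[b][s];
          int arrive = (l + dstep[a][b]) % L;
          ring[a][b][(size_t)arrive * N[a] + i] += 1.0;
        }
      }
    }
  }

  List out = List::create(Named("counts") = counts);
  if (record_raster) {
    out["raster_bin"] = wrap(ras_bin);
    out["raster_pop"] = wrap(ras_pop);
    out["raster_idx"] = wrap(ras_idx);
  }
  return out;
}
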