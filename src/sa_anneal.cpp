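#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Simulated annealing on weighted modularity by single-node reassignment.
//
// Q = sum_c [ w_in(c)/W - (s_c/(2W))^2 ], with w_in(c) the total
// intra-cluster edge weight, s_c the summed node strength of cluster c and
// W the total edge weight. Moving node u from cluster a to b changes Q by
//   dQ = (k_ub - k_ua)/W - d_u (s_b - s_a + d_u) / (2 W^2)
// where k_uc is the weight from u to cluster c and d_u its strength.
// Moves are proposed as: pick u uniformly; with probability 0.9 target the
// cluster of a uniformly chosen neighbour of u, otherwise a uniform cluster
// id (keeps empty clusters reachable, i.e. splits). Metropolis acceptance
// exp(dQ/T). Uses R's RNG, so runs are reproducible under set.seed().
//
// [[Rcpp::export]]
List sa_anneal_cpp(int n, IntegerVector from, IntegerVector to,
                   NumericVector w, IntegerVector init, int k_max,
                   double t0, double cooling, int moves_per_temp,
                   double t_min, int patience) {
  int m = from.size();
  std::vector<std::vector<int> > adj(n);
  std::vector<std::vector<double> > adjw(n);
  std::vector<double> strength(n, 0.0);
  double W = 0.0;
  for (int e = 0; e < m; ++e) {
    int a = from[e], b = to[e];
    double we = w[e];
    adj[a].push_back(b);  adjw[a].push_back(we);
    adj[b].push_back(a);  adjw[b].push_back(we);
    strength[a] += we;    strength[b] += we;
    W += we;
  }

  std::vector<int> z(init.begin(), init.end());
  std::vector<double> s(k_max, 0.0);
  for (int i = 0; i < n; ++i) s[z[i]] += strength[i];

  // initial Q
  double win_tot = 0.0;
  for (int e = 0; e < m; ++e)
    if (z[from[e]] == z[to[e]]) win_tot += w[e];
  double Q = 0.0;
  if (W > 0) {
    Q = win_tot / W;
    for (int c = 0; c < k_max; ++c) Q -= (s[c] / (2.0 * W)) * (s[c] / (2.0 * W));
  }

  std::vector<int> best = z;
  double bestQ = Q;
  std::vector<double> trace;
  std::vector<double> temps;

  if (W <= 0 || n < 2) {
    return List::create(_["assignment"] = IntegerVector(best.begin(), best.end()),
                        _["best_q"] = bestQ,
                        _["trace_q"] = NumericVector(trace.begin(), trace.end()),
                        _["trace_t"] = NumericVector(temps.begin(), temps.end()));
  }

  double T = t0;
  int stale = 0;
  std::vector<double> kto(k_max, 0.0);  // scratch: weight from u to clusters
  while (T >= t_min && stale < patience) {
    bool improved = false;
    for (int mv = 0; mv < moves_per_temp; ++mv) {
      int u = (int)(unif_rand() * n);
      if (u >= n) u = n - 1;
      int a = z[u];
      int b;
      if (!adj[u].empty() && unif_rand() < 0.9) {
        int j = (int)(unif_rand() * adj[u].size());
        if (j >= (int)adj[u].size()) j = adj[u].size() - 1;
        b = z[adj[u][j]];
      } else {
        b = (int)(unif_rand() * k_max);
        if (b >= k_max) b = k_max - 1;
      }
      if (b == a) continue;
      double kua = 0.0, kub = 0.0;
      for (size_t j = 0; j < adj[u].size(); ++j) {
        int zc = z[adj[u][j]];
        if (zc == a) kua += adjw[u][j];
        else if (zc == b) kub += adjw[u][j];
      }
      double du = strength[u];
      double dQ = (kub - kua) / W - du * (s[b] - s[a] + du) / (2.0 * W * W);
      if (dQ > 0 || unif_rand() < std::exp(dQ / T)) {
        z[u] = b;
        s[a] -= du;
        s[b] += du;
        Q += dQ;
        if (Q > bestQ + 1e-12) {
          bestQ = Q;
          best = z;
          improved = true;
        }
      }
    }
    trace.push_back(bestQ);
    temps.push_back(T);
    stale = improved ? 0 : stale + 1;
    T *= cooling;
  }

  // zero-temperature polish: from the best partition seen, sweep nodes into
  // their best neighbouring cluster until no single move improves Q
  z = best;
  std::fill(s.begin(), s.end(), 0.0);
  for (int i = 0; i < n; ++i) s[z[i]] += strength[i];
  {
    double Qb = bestQ;
    bool moved = true;
    while (moved) {
      moved = false;
      for (int u = 0; u < n; ++u) {
        int a = z[u];
        double kua = 0.0;
        for (size_t j = 0; j < adj[u].size(); ++j)
          if (z[adj[u][j]] == a) kua += adjw[u][j];
        double du = strength[u];
        int bBest = a;
        double dQBest = 0.0;
        for (size_t j = 0; j < adj[u].size(); ++j) {
          int b = z[adj[u][j]];
          if (b == a || b == bBest) continue;
          double kub = 0.0;
          for (size_t j2 = 0; j2 < adj[u].size(); ++j2)
            if (z[adj[u][j2]] == b) kub += adjw[u][j2];
          double dQ = (kub - kua) / W - du * (s[b] - s[a] + du) / (2.0 * W * W);
          if (dQ > dQBest + 1e-12) { dQBest = dQ; bBest = b; }
        }
        if (bBest != a) {
          z[u] = bBest;
          s[a] -= du;
          s[bBest] += du;
          Qb += dQBest;
          moved = true;
        }
      }
    }
    if (Qb > bestQ) { bestQ = Qb; best = z; }
  }

  return List::create(_["assignment"] = IntegerVector(best.begin(), best.end()),
                      _["best_q"] = bestQ,
                      _["trace_q"] = NumericVector(trace.begin(), trace.end()),
                      _["trace_t"] = NumericVector(temps.begin(), temps.end()));
}
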