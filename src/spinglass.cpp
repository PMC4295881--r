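#include <Rcpp.h>
#include <random>
#include <vector>

// Simulated annealing on the spin-glass (Potts) Hamiltonian
//   H(c) = - sum_{i != j} (A_ij - gamma * k_i k_j / 2m) delta(c_i, c_j)
// (ordered pairs), whose ground state at gamma = 1 is the maximal-modularity
// partition: for any single-node move, dH = -2m * dQ.
//
// One annealing stage proposes |V| single-node spin changes accepted by the
// Metropolis rule, then multiplies the temperature by `cool` until `t_stop`;
// a zero-temperature sweep polishes the final configuration. The RNG is a
// private mt19937 seeded from `seed` so results do not depend on R's RNG
// state.
//
// edges: m x 2 integer matrix, 0-based, simple undirected graph.
// [[Rcpp::export]]
Rcpp::List anneal_potts_cpp(int n, const Rcpp::IntegerMatrix& edges, int spins,
                            double gamma, double t_start, double t_stop,
                            double cool, int seed) {
  const int m = edges.nrow();
  std::vector<std::vector<int>> adj(n);
  std::vector<double> k(n, 0.0);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    adj[a].push_back(b);
    adj[b].push_back(a);
    k[a] += 1.0;
    k[b] += 1.0;
  }
  const double two_m = 2.0 * m;

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_int_distribution<int> pick_node(0, n - 1);
  std::uniform_int_distribution<int> pick_spin(0, spins - 1);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> c(n);
  std::vector<double> K(spins, 0.0); // total degree per spin state
  for (int v = 0; v < n; ++v) {
    c[v] = pick_spin(rng);
    K[c[v]] += k[v];
  }

  // dH for moving v from its spin a to spin b (ordered-pair Hamiltonian)
  std::vector<double> links(spins, 0.0);
  auto delta_h = [&](int v, int b) {
    int a = c[v];
    double l_a = 0.0, l_b = 0.0;
    for (int u : adj[v]) {
      if (c[u] == a) l_a += 1.0;
      else if (c[u] == b) l_b += 1.0;
    }
    double gain = l_b - gamma * k[v] * K[b] / two_m;
    double loss = l_a - gamma * k[v] * (K[a] - k[v]) / two_m;
    return -2.0 * (gain - loss);
  };
  auto apply_move = [&](int v, int b) {
    K[c[v]] -= k[v];
    K[b] += k[v];
    c[v] = b;
  };

  int n_temps = 0;
  std::vector<double> trace_t, trace_h;
  double H = 0.0; // track Hamiltonian incrementally from an arbitrary origin
  if (m > 0) {
    for (double t = t_start; t > t_stop; t *= cool) {
      for (int s = 0; s < n; ++s) {
        int v = pick_node(rng);
        int b = pick_spin(rng);
        if (b == c[v]) continue;
        double dh = delta_h(v, b);
        if (dh <= 0.0 || unif(rng) < std::exp(-dh / t)) {
          apply_move(v, b);
          H += dh;
        }
      }
      ++n_temps;
      trace_t.push_back(t);
      trace_h.push_back(H);
    }
    // zero-temperature polish: greedy single-node moves, then cluster
    // merges (a community split across two spin states is a local optimum
    // for single-node moves; a merge move escapes it), until stable
    for (int outer = 0; outer < 100; ++outer) {
      bool changed = false;
      for (int pass = 0; pass < 200; ++pass) {
        bool moved = false;
        for (int v = 0; v < n; ++v) {
          int best_b = c[v];
          double best_dh = -1e-12;
          for (int b = 0; b < spins; ++b) {
            if (b == c[v]) continue;
            double dh = delta_h(v, b);
            if (dh < best_dh) {
              best_dh = dh;
              best_b = b;
            }
          }
          if (best_b != c[v]) {
            apply_move(v, best_b);
            H += best_dh;
            moved = true;
            changed = true;
          }
        }
        if (!moved) break;
      }
      // best merge of two spin groups: dH = -2 (e_AB - gamma K_A K_B / 2m)
      std::vector<double> e_ab(spins * spins, 0.0);
      for (int e = 0; e < m; ++e) {
        int a = c[edges(e, 0)], b = c[edges(e, 1)];
        if (a != b) {
          e_ab[a * spins + b] += 1.0;
          e_ab[b * spins + a] += 1.0;
        }
      }
      int ma = -1, mb = -1;
      double best_dh = -1e-12;
      for (int a = 0; a < spins; ++a) {
        if (K[a] <= 0.0) continue;
        for (int b = a + 1; b < spins; ++b) {
          if (K[b] <= 0.0) continue;
          double dh = -2.0 * (e_ab[a * spins + b] -
                              gamma * K[a] * K[b] / two_m);
          if (dh < best_dh) {
            best_dh = dh;
            ma = a;
            mb = b;
          }
        }
      }
      if (ma >= 0) {
        for (int v = 0; v < n; ++v) {
          if (c[v] == mb) c[v] = ma;
        }
        K[ma] += K[mb];
        K[mb] = 0.0;
        H += best_dh;
        changed = true;
      }
      if (!changed) break;
    }
  }

  return Rcpp::List::create(Rcpp::Named("membership") = Rcpp::wrap(c),
                            Rcpp::Named("n_temperatures") = n_temps,
                            Rcpp::Named("trace_t") = Rcpp::wrap(trace_t),
                            Rcpp::Named("trace_h") = Rcpp::wrap(trace_h));
}
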