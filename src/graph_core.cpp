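#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All-pairs shortest path distances on a non-negative length matrix.
// L: symmetric, zero diagonal, R_PosInf marks absent edges.
// Dijkstra from every source with O(N^2) selection; N stays small
// (atlas-scale, <= a few hundred nodes) so a heap buys nothing.
// [[Rcpp::export]]
NumericMatrix cpp_shortest_paths(NumericMatrix L) {
  const int n = L.nrow();
  NumericMatrix D(n, n);
  // adjacency lists (sparse thresholded graphs: relax neighbours only)
  std::vector<int> adj_start(n + 1, 0);
  std::vector<int> adj_to;
  std::vector<double> adj_len;
  adj_to.reserve((size_t)n * 8);
  adj_len.reserve((size_t)n * 8);
  for (int u = 0; u < n; ++u) {
    const double* Lu = &L(0, u);  // column u == row u (symmetric)
    for (int v = 0; v < n; ++v) {
      double l = Lu[v];
      if (v != u && R_FINITE(l) && l > 0.0) {
        adj_to.push_back(v);
        adj_len.push_back(l);
      }
    }
    adj_start[u + 1] = (int)adj_to.size();
  }
  std::vector<double> dist(n);
  std::vector<bool> done(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(done.begin(), done.end(), false);
    dist[s] = 0.0;
    for (int it = 0; it < n; ++it) {
      int u = -1;
      double best = R_PosInf;
      for (int v = 0; v < n; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = true;
      const double du = dist[u];
      for (int e = adj_start[u]; e < adj_start[u + 1]; ++e) {
        int v = adj_to[e];
        double nd = du + adj_len[e];
        if (!done[v] && nd < dist[v]) dist[v] = nd;
      }
    }
    for (int v = 0; v < n; ++v) D(v, s) = dist[v];
    D(s, s) = 0.0;
  }
  return D;
}

// Brandes betweenness on a length matrix; returns the unordered-pair
// accumulation (each {s,t} pair counted once). Equal-length shortest
// paths share credit fractionally; ties detected with a relative
// tolerance so that floating-point sums of reciprocal weights compare
// sanely.
// [[Rcpp::export]]
NumericVector cpp_betweenness(NumericMatrix L) {
  const int n = L.nrow();
  NumericVector bc(n);
  const double rel_tol = 1e-10;
  std::vector<double> dist(n), sigma(n), delta(n);
  std::vector<bool> done(n);
  std::vector<std::vector<int>> pred(n);
  std::vector<int> order;
  order.reserve(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    std::fill(done.begin(), done.end(), false);
    for (int v = 0; v < n; ++v) pred[v].clear();
    order.clear();
    dist[s] = 0.0;
    sigma[s] = 1.0;
    for (int it = 0; it < n; ++it) {
      int u = -1;
      double best = R_PosInf;
      for (int v = 0; v < n; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = true;
      order.push_back(u);
      const double* Lu = &L(0, u);
      for (int v = 0; v < n; ++v) {
        if (done[v]) continue;
        double l = Lu[v];
        if (!R_FINITE(l) || l <= 0.0) continue;
        double nd = dist[u] + l;
        double tol = rel_tol * std::max(1.0, nd);
        if (nd < dist[v] - tol) {
          dist[v] = nd;
          sigma[v] = sigma[u];
          pred[v].assign(1, u);
        } else if (R_FINITE(dist[v]) && std::fabs(nd - dist[v]) <= tol) {
          sigma[v] += sigma[u];
          pred[v].push_back(u);
        }
      }
    }
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int w = order[i];
      for (size_t j = 0; j < pred[w].size(); ++j) {
        int u = pred[w][j];
        delta[u] += sigma[u] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;
  return bc;
}

// Weighted local efficiency, connectivity-toolbox convention:
// E_loc(u) = sum_{j!=h in N(u)} (w_uj * w_uh / d_jh(N_u))^(1/3) / (k_u (k_u - 1)),
// where d_jh(N_u) is the shortest path between neighbours j, h on the
// subgraph induced by N(u), lengths 1/w. Nodes with fewer than two
// neighbours contribute 0. Assumes W symmetric, non-negative; for
// weights max-normalized to (0,1] the result stays in [0,1].
// [[Rcpp::export]]
NumericVector cpp_local_efficiency(NumericMatrix W) {
  const int n = W.nrow();
  NumericVector eloc(n);
  std::vector<int> nb;
  for (int u = 0; u < n; ++u) {
    nb.clear();
    for (int v = 0; v < n; ++v)
      if (v != u && W(u, v) > 0.0) nb.push_back(v);
    const int k = (int)nb.size();
    if (k < 2) { eloc[u] = 0.0; continue; }
    std::vector<double> Ls((size_t)k * k);
    for (int a = 0; a < k; ++a)
      for (int b = 0; b < k; ++b) {
        double w = W(nb[a], nb[b]);
        Ls[(size_t)a * k + b] = (a == b) ? 0.0 : (w > 0.0 ? 1.0 / w : R_PosInf);
      }
    for (int c = 0; c < k; ++c)
      for (int a = 0; a < k; ++a) {
        double dac = Ls[(size_t)a * k + c];
        if (!R_FINITE(dac)) continue;
        for (int b = 0; b < k; ++b) {
          double alt = dac + Ls[(size_t)c * k + b];
          if (alt < Ls[(size_t)a * k + b]) Ls[(size_t)a * k + b] = alt;
        }
      }
    double numer = 0.0;
    for (int a = 0; a < k; ++a)
      for (int b = 0; b < k; ++b) {
        if (a == b) continue;
        double d = Ls[(size_t)a * k + b];
        if (!R_FINITE(d)) continue;
        numer += std::cbrt(W(u, nb[a]) * W(u, nb[b]) / d);
      }
    eloc[u] = numer / ((double)k * (k - 1));
  }
  return eloc;
}
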