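#include <Rcpp.h>
using namespace Rcpp;

// Dense all-pairs shortest paths by Floyd-Warshall on a length matrix
// (Inf = no edge). Suitable for the package's connectome sizes (<= a few
// hundred nodes), where the cubic dense pass beats per-source Dijkstra
// with graph-construction overhead.
// [[Rcpp::export(name = ".cppFwDistances")]]
NumericMatrix cppFwDistances(NumericMatrix lengths) {
  int n = lengths.nrow();
  NumericMatrix D(clone(lengths));
  double* p = REAL(D);
  for (int i = 0; i < n; ++i) p[i + (size_t)i * n] = 0.0;
  // column-major traversal: for fixed k and j relax the whole column j
  // against column k, keeping every access contiguous in i
  for (int k = 0; k < n; ++k) {
    const double* colk = p + (size_t)k * n;
    for (int j = 0; j < n; ++j) {
      double dkj = p[k + (size_t)j * n];
      if (!R_finite(dkj)) continue;
      double* colj = p + (size_t)j * n;
      for (int i = 0; i < n; ++i) {
        double cand = colk[i] + dkj;
        if (cand < colj[i]) colj[i] = cand;
      }
    }
  }
  return D;
}

static double subgraphEfficiency(const NumericMatrix& W,
                                 const std::vector<int>& nb) {
  int m = (int)nb.size();
  if (m < 2) return 0.0;
  std::vector<double> D((size_t)m * m);
  const double inf = R_PosInf;
  for (int a = 0; a < m; ++a) {
    for (int b = 0; b < m; ++b) {
      double w = W(nb[a], nb[b]);
      D[(size_t)a * m + b] = (a == b) ? 0.0 : (w > 0 ? 1.0 / w : inf);
    }
  }
  for (int k = 0; k < m; ++k) {
    for (int a = 0; a < m; ++a) {
      double dak = D[(size_t)a * m + k];
      if (!R_finite(dak)) continue;
      for (int b = 0; b < m; ++b) {
        double cand = dak + D[(size_t)k * m + b];
        if (cand < D[(size_t)a * m + b]) D[(size_t)a * m + b] = cand;
      }
    }
  }
  double s = 0.0;
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < m; ++b)
      if (a != b && R_finite(D[(size_t)a * m + b]) &&
          D[(size_t)a * m + b] > 0)
        s += 1.0 / D[(size_t)a * m + b];
  return s / ((double)m * (m - 1));
}

// Mean over nodes of the efficiency of the neighbour-induced subgraph
// (weights as strengths, path lengths 1/w); nodes with < 2 neighbours
// contribute zero.
// [[Rcpp::export(name = ".cppLocalEfficiency")]]
double cppLocalEfficiency(NumericMatrix W) {
  int n = W.nrow();
  if (n == 0) return 0.0;
  double total = 0.0;
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (W(i, j) > 0) nb.push_back(j);
    total += subgraphEfficiency(W, nb);
  }
  return total / n;
}

// Maslov-Sneppen degree-preserving rewiring: attempts `niter` random edge
// swaps on the upper-triangular edge list of a simple undirected graph,
// rejecting self-loops and duplicate edges. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export(name = ".cppRewireEdges")]]
IntegerMatrix cppRewireEdges(IntegerMatrix edges, int nNodes, int niter) {
  int ne = edges.nrow();
  if (ne < 2) return edges;
  std::vector<int> u(ne), v(ne);
  std::vector<char> adj((size_t)nNodes * nNodes, 0);
  for (int e = 0; e < ne; ++e) {
    u[e] = edges(e, 0) - 1;
    v[e] = edges(e, 1) - 1;
    adj[(size_t)u[e] * nNodes + v[e]] = 1;
    adj[(size_t)v[e] * nNodes + u[e]] = 1;
  }
  for (int it = 0; it < niter; ++it) {
    int e1 = (int)(unif_rand() * ne);
    int e2 = (int)(unif_rand() * ne);
    if (e1 == e2) continue;
    int a = u[e1], b = v[e1], c = u[e2], d = v[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    // propose (a,d) and (c,b)
    if (a == d || c == b) continue;
    if (a == c || b == d) continue;
    if (adj[(size_t)a * nNodes + d] || adj[(size_t)c * nNodes + b]) continue;
    adj[(size_t)a * nNodes + b] = adj[(size_t)b * nNodes + a] = 0;
    adj[(size_t)c * nNodes + d] = adj[(size_t)d * nNodes + c] = 0;
    adj[(size_t)a * nNodes + d] = adj[(size_t)d * nNodes + a] = 1;
    adj[(size_t)c * nNodes + b] = adj[(size_t)b * nNodes + c] = 1;
    v[e1] = d;
    u[e2] = c;
    v[e2] = b;
  }
  IntegerMatrix out(ne, 2);
  for (int e = 0; e < ne; ++e) {
    out(e, 0) = u[e] + 1;
    out(e, 1) = v[e] + 1;
  }
  return out;
}
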