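#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Breadth-first search over a subset of the edge list; returns hop distance
// from s to t, or -1 when disconnected. Edges are 1-based node indices.
static int bfs_dist(const std::vector<std::vector<std::pair<int, int>>> &adj,
                    const std::vector<char> &present, int s, int t, int nv,
                    std::vector<int> &dist, std::vector<int> &queue) {
  std::fill(dist.begin(), dist.end(), -1);
  int head = 0, tail = 0;
  queue[tail++] = s;
  dist[s] = 0;
  while (head < tail) {
    int x = queue[head++];
    if (x == t) return dist[t];
    for (const auto &nb : adj[x]) {
      if (!present[nb.second]) continue;
      if (dist[nb.first] < 0) {
        dist[nb.first] = dist[x] + 1;
        queue[tail++] = nb.first;
      }
    }
  }
  return dist[t];
}

static std::vector<std::vector<std::pair<int, int>>>
build_adj(const IntegerVector &from, const IntegerVector &to, int nv) {
  std::vector<std::vector<std::pair<int, int>>> adj(nv + 1);
  for (int e = 0; e < from.size(); ++e) {
    adj[from[e]].push_back({to[e], e});
    adj[to[e]].push_back({from[e], e});
  }
  return adj;
}

// Exact two-terminal reliability and expected reliable distance by full
// enumeration of the 2^m edge realizations (m <= 20). Returns
// c(reliability, erd) with erd = NA when the terminals are never connected.
// [[Rcpp::export]]
NumericVector cpp_exact_reliability(IntegerVector from, IntegerVector to,
                                    NumericVector w, int nv, int s, int t) {
  int m = from.size();
  if (m > 20) stop("exact enumeration supports at most 20 edges");
  auto adj = build_adj(from, to, nv);
  std::vector<int> dist(nv + 1), queue(nv + 1);
  std::vector<char> present(m, 0);
  double rel = 0.0, num = 0.0;
  unsigned long total = 1UL << m;
  for (unsigned long mask = 0; mask < total; ++mask) {
    double pr = 1.0;
    for (int e = 0; e < m; ++e) {
      bool in = (mask >> e) & 1UL;
      present[e] = in;
      pr *= in ? w[e] : 1.0 - w[e];
    }
    if (pr == 0.0) continue;
    int d = bfs_dist(adj, present, s, t, nv, dist, queue);
    if (d >= 0) {
      rel += pr;
      num += pr * d;
    }
  }
  return NumericVector::create(rel, rel > 0 ? num / rel : NA_REAL);
}

// Monte-Carlo realizations: each edge kept independently with probability
// w[e]; per sample, the s-t hop distance (-1 when disconnected). Uses R's
// RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector cpp_mc_distances(IntegerVector from, IntegerVector to,
                               NumericVector w, int nv, int s, int t,
                               int nsamples) {
  int m = from.size();
  auto adj = build_adj(from, to, nv);
  std::vector<int> dist(nv + 1), queue(nv + 1);
  std::vector<char> present(m, 0);
  IntegerVector out(nsamples);
  for (int k = 0; k < nsamples; ++k) {
    for (int e = 0; e < m; ++e) present[e] = unif_rand() < w[e];
    out[k] = bfs_dist(adj, present, s, t, nv, dist, queue);
  }
  return out;
}

// Random walk with restart, simulated. Adjacency in CSR form: node i's
// neighbours are nbr[ptr[i] .. ptr[i+1]-1] (0-based into nbr), cumw holds
// the cumulative edge weights per neighbourhood. Every step counts as a
// visit (a restart counts as a visit to the start node). A node without
// neighbours forces a restart. Returns visit counts per node.
// [[Rcpp::export]]
NumericVector cpp_rw_visits(IntegerVector ptr, IntegerVector nbr,
                            NumericVector cumw, double beta, int start,
                            double iters, int nv) {
  NumericVector visits(nv + 1);
  int cur = start;
  long long n = (long long)iters;
  for (long long it = 0; it < n; ++it) {
    int lo = ptr[cur - 1], hi = ptr[cur];
    if (unif_rand() < beta || lo == hi) {
      cur = start;
    } else {
      double total = cumw[hi - 1];
      double r = unif_rand() * total;
      // binary search for first cumw >= r within [lo, hi)
      int a = lo, b = hi - 1;
      while (a < b) {
        int mid = (a + b) / 2;
        if (cumw[mid] >= r)
          b = mid;
        else
          a = mid + 1;
      }
      cur = nbr[a];
    }
    visits[cur] += 1.0;
  }
  return visits;
}
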