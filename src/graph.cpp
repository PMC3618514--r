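// Binary-graph topology kernels: all-pairs shortest path lengths (BFS),
// nodal/global efficiency, and local efficiency (global efficiency of each
// node's neighbour-induced subgraph). These run inside the Monte-Carlo
// cost-integration loop, hence the bitset representation: rows of the
// adjacency matrix are packed into 64-bit words and BFS expands whole
// frontiers with word-wise OR/AND.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct BitGraph {
  int n;
  int words;
  std::vector<uint64_t> rows; // n * words

  explicit BitGraph(const IntegerMatrix &a) {
    n = a.nrow();
    words = (n + 63) / 64;
    rows.assign(static_cast<size_t>(n) * words, 0ULL);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        if (a(i, j) != 0 && i != j) {
          rows[static_cast<size_t>(i) * words + j / 64] |= (1ULL << (j % 64));
        }
      }
    }
  }

  const uint64_t *row(int i) const {
    return rows.data() + static_cast<size_t>(i) * words;
  }
};

// Single-source BFS restricted to the vertex set `mask` (mask == nullptr
// means all vertices). Writes hop counts into dist (-1 = unreachable).
void bfs_bitset(const BitGraph &g, int source, const uint64_t *mask,
                std::vector<int> &dist, std::vector<uint64_t> &visited,
                std::vector<uint64_t> &frontier, std::vector<uint64_t> &next) {
  const int W = g.words;
  std::fill(dist.begin(), dist.end(), -1);
  std::fill(visited.begin(), visited.end(), 0ULL);
  std::fill(frontier.begin(), frontier.end(), 0ULL);
  frontier[source / 64] = 1ULL << (source % 64);
  visited[source / 64] = frontier[source / 64];
  dist[source] = 0;
  int d = 0;
  bool any = true;
  while (any) {
    ++d;
    std::fill(next.begin(), next.end(), 0ULL);
    for (int v = 0; v < g.n; ++v) {
      if (frontier[v / 64] & (1ULL << (v % 64))) {
        const uint64_t *r = g.row(v);
        for (int w = 0; w < W; ++w) next[w] |= r[w];
      }
    }
    any = false;
    for (int w = 0; w < W; ++w) {
      uint64_t nw = next[w] & ~visited[w];
      if (mask) nw &= mask[w];
      next[w] = nw;
      visited[w] |= nw;
      if (nw) {
        any = true;
        uint64_t bits = nw;
        while (bits) {
          int b = __builtin_ctzll(bits);
          dist[w * 64 + b] = d;
          bits &= bits - 1;
        }
      }
    }
    frontier.swap(next);
  }
}

} // namespace

// [[Rcpp::export(name = ".all_pairs_distances_cpp")]]
NumericMatrix all_pairs_distances_cpp(IntegerMatrix a) {
  BitGraph g(a);
  const int n = g.n;
  NumericMatrix out(n, n);
  std::vector<int> dist(n);
  std::vector<uint64_t> visited(g.words), frontier(g.words), next(g.words);
  for (int s = 0; s < n; ++s) {
    bfs_bitset(g, s, nullptr, dist, visited, frontier, next);
    for (int j = 0; j < n; ++j) {
      out(s, j) = dist[j] < 0 ? R_PosInf : dist[j];
    }
  }
  return out;
}

// Degree, nodal efficiency, global efficiency, and (optionally) local
// efficiency of a binary undirected graph in a single pass.
// [[Rcpp::export(name = ".binary_metrics_cpp")]]
List binary_metrics_cpp(IntegerMatrix a, bool need_local) {
  BitGraph g(a);
  const int n = g.n;
  const int W = g.words;
  std::vector<int> dist(n);
  std::vector<uint64_t> visited(W), frontier(W), next(W);

  IntegerVector degree(n);
  NumericVector eff(n);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    const uint64_t *r = g.row(i);
    for (int w = 0; w < W; ++w) k += __builtin_popcountll(r[w]);
    degree[i] = k;
  }

  for (int s = 0; s < n; ++s) {
    bfs_bitset(g, s, nullptr, dist, visited, frontier, next);
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j != s && dist[j] > 0) acc += 1.0 / dist[j];
    }
    eff[s] = (n > 1) ? acc / (n - 1) : 0.0;
  }
  double eg = n > 0 ? std::accumulate(eff.begin(), eff.end(), 0.0) / n : 0.0;

  double el = NA_REAL;
  if (need_local) {
    // Local efficiency of node i is the global efficiency of the
    // subgraph induced by i's neighbours. Within that subgraph a pair
    // (u, v) is at distance 1 if adjacent, 2 if it has a common
    // neighbour inside the subgraph (bitset AND); only the remaining
    // pairs need a masked BFS.
    double el_sum = 0.0;
    std::vector<int> members, far_v;
    members.reserve(n);
    for (int i = 0; i < n; ++i) {
      const uint64_t *mask = g.row(i); // neighbour set of i excludes i itself
      int k = degree[i];
      if (k < 2) continue; // contributes 0
      members.clear();
      for (int w = 0; w < W; ++w) {
        uint64_t bits = mask[w];
        while (bits) {
          int b = __builtin_ctzll(bits);
          members.push_back(w * 64 + b);
          bits &= bits - 1;
        }
      }
      double acc = 0.0;
      for (size_t ui = 0; ui < members.size(); ++ui) {
        int u = members[ui];
        const uint64_t *ru = g.row(u);
        far_v.clear();
        for (size_t vi = ui + 1; vi < members.size(); ++vi) {
          int v = members[vi];
          if (ru[v / 64] & (1ULL << (v % 64))) {
            acc += 1.0; // distance 1, counted once per unordered pair
            continue;
          }
          const uint64_t *rv = g.row(v);
          uint64_t common = 0ULL;
          for (int w = 0; w < W && !common; ++w) {
            common = ru[w] & rv[w] & mask[w];
          }
          if (common) {
            acc += 0.5; // distance 2
          } else {
            far_v.push_back(v);
          }
        }
        if (!far_v.empty()) {
          bfs_bitset(g, u, mask, dist, visited, frontier, next);
          for (int v : far_v) {
            if (dist[v] > 0) acc += 1.0 / dist[v];
          }
        }
      }
      // acc sums unordered pairs; Eq. over ordered pairs doubles it.
      el_sum += 2.0 * acc / (static_cast<double>(k) * (k - 1));
    }
    el = n > 0 ? el_sum / n : 0.0;
  }

  return List::create(
    _["degree"] = degree,
    _["efficiency"] = eff,
    _["global_efficiency"] = eg,
    _["local_efficiency"] = el
  );
}
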