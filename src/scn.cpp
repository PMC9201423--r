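// Binary-graph metric core for structural covariance networks.
//
// Graphs are small (tens to ~100 nodes) but the permutation engine evaluates
// every metric on tens of thousands of thresholded graphs plus their random
// null networks, so adjacency is kept as packed 64-bit rows and all
// single-graph routines are allocation-light.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline int popcnt(uint64_t x) { return __builtin_popcountll(x); }

// xoshiro256++ with splitmix64 seeding: deterministic across platforms,
// independent of R's RNG stream (R supplies the integer seed).
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline uint32_t below(uint32_t n) {
    return (uint32_t)(((__uint128_t)next() * n) >> 64);
  }
};

struct BitGraph {
  int N, W;
  std::vector<uint64_t> row;   // N * W words
  std::vector<int> deg;
  BitGraph(int n) : N(n), W((n + 63) / 64), row((size_t)n * ((n + 63) / 64), 0), deg(n, 0) {}
  inline uint64_t* r(int i) { return &row[(size_t)i * W]; }
  inline const uint64_t* r(int i) const { return &row[(size_t)i * W]; }
  inline bool has(int i, int j) const { return (r(i)[j >> 6] >> (j & 63)) & 1ULL; }
  inline void add(int i, int j) {
    r(i)[j >> 6] |= 1ULL << (j & 63);
    r(j)[i >> 6] |= 1ULL << (i & 63);
    ++deg[i]; ++deg[j];
  }
  inline void rem(int i, int j) {
    r(i)[j >> 6] &= ~(1ULL << (j & 63));
    r(j)[i >> 6] &= ~(1ULL << (i & 63));
    --deg[i]; --deg[j];
  }
  int n_edges() const {
    long s = 0;
    for (int i = 0; i < N; ++i) s += deg[i];
    return (int)(s / 2);
  }
};

static BitGraph from_matrix(const IntegerMatrix& adj) {
  int n = adj.nrow();
  BitGraph g(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (adj(i, j) != 0) g.add(i, j);
  return g;
}

// Single-source reachability (for connectivity checks).
static bool is_connected(const BitGraph& g, std::vector<uint64_t>& vis, std::vector<uint64_t>& frontier) {
  const int W = g.W, N = g.N;
  if (N == 0) return true;
  vis.assign(W, 0); frontier.assign(W, 0);
  vis[0] = 1ULL; frontier[0] = 1ULL;
  int reached = 1;
  std::vector<uint64_t> nxt(W);
  while (true) {
    std::fill(nxt.begin(), nxt.end(), 0);
    for (int w = 0; w < W; ++w) {
      uint64_t f = frontier[w];
      while (f) {
        int b = __builtin_ctzll(f);
        f &= f - 1;
        const uint64_t* rr = g.r(w * 64 + b);
        for (int k = 0; k < W; ++k) nxt[k] |= rr[k];
      }
    }
    int newc = 0;
    for (int k = 0; k < W; ++k) {
      nxt[k] &= ~vis[k];
      newc += popcnt(nxt[k]);
      vis[k] |= nxt[k];
    }
    if (newc == 0) break;
    reached += newc;
    frontier = nxt;
  }
  return reached == N;
}

// All-pairs BFS: accumulates sum of distances and of inverse distances over
// ordered reachable pairs; sets connected=false if any pair is unreachable.
static void dist_sums(const BitGraph& g, double& sumd, double& suminv, bool& connected) {
  const int N = g.N, W = g.W;
  sumd = 0.0; suminv = 0.0; connected = true;
  std::vector<uint64_t> vis(W), frontier(W), nxt(W);
  for (int s = 0; s < N; ++s) {
    std::fill(vis.begin(), vis.end(), 0);
    std::fill(frontier.begin(), frontier.end(), 0);
    vis[s >> 6] |= 1ULL << (s & 63);
    frontier[s >> 6] |= 1ULL << (s & 63);
    int reached = 1, d = 0;
    while (true) {
      std::fill(nxt.begin(), nxt.end(), 0);
      for (int w = 0; w < W; ++w) {
        uint64_t f = frontier[w];
        while (f) {
          int b = __builtin_ctzll(f);
          f &= f - 1;
          const uint64_t* rr = g.r(w * 64 + b);
          for (int k = 0; k < W; ++k) nxt[k] |= rr[k];
        }
      }
      int newc = 0;
      for (int k = 0; k < W; ++k) {
        nxt[k] &= ~vis[k];
        newc += popcnt(nxt[k]);
        vis[k] |= nxt[k];
      }
      if (newc == 0) break;
      ++d;
      sumd += (double)d * newc;
      suminv += (double)newc / d;
      reached += newc;
      frontier.swap(nxt);
    }
    if (reached < N) connected = false;
  }
}

// Mean local clustering (degree<2 contributes 0) and transitivity.
static void clustering(const BitGraph& g, double& cp, double& trans) {
  const int N = g.N, W = g.W;
  double cps = 0.0, tri2 = 0.0, triples = 0.0;
  for (int i = 0; i < N; ++i) {
    int k = g.deg[i];
    if (k < 2) continue;
    const uint64_t* ri = g.r(i);
    long t = 0;
    for (int w = 0; w < W; ++w) {
      uint64_t f = ri[w];
      while (f) {
        int b = __builtin_ctzll(f);
        f &= f - 1;
        const uint64_t* rj = g.r(w * 64 + b);
        for (int kk = 0; kk < W; ++kk) t += popcnt(ri[kk] & rj[kk]);
      }
    }
    // t = sum over neighbors j of |N(i) & N(j)| = 2 * (edges among N(i))
    cps += (double)t / ((double)k * (k - 1));
    tri2 += (double)t;
    triples += (double)k * (k - 1) / 2.0;
  }
  cp = (N > 0) ? cps / N : 0.0;
  trans = (triples > 0) ? (tri2 / 2.0) / triples : 0.0;
}

// Local efficiency: mean over nodes of global efficiency of the subgraph
// induced by each node's neighborhood (degree<2 contributes 0).
static double local_eff(const BitGraph& g) {
  const int N = g.N, W = g.W;
  std::vector<uint64_t> vis(W), frontier(W), nxt(W);
  double tot = 0.0;
  for (int i = 0; i < N; ++i) {
    int k = g.deg[i];
    if (k < 2) continue;
    const uint64_t* mask = g.r(i);
    double suminv = 0.0;
    for (int w0 = 0; w0 < W; ++w0) {
      uint64_t fs = mask[w0];
      while (fs) {
        int b0 = __builtin_ctzll(fs);
        fs &= fs - 1;
        int s = w0 * 64 + b0;
        std::fill(vis.begin(), vis.end(), 0);
        std::fill(frontier.begin(), frontier.end(), 0);
        vis[s >> 6] |= 1ULL << (s & 63);
        frontier[s >> 6] |= 1ULL << (s & 63);
        int d = 0;
        while (true) {
          std::fill(nxt.begin(), nxt.end(), 0);
          for (int w = 0; w < W; ++w) {
            uint64_t f = frontier[w];
            while (f) {
              int b = __builtin_ctzll(f);
              f &= f - 1;
              const uint64_t* rr = g.r(w * 64 + b);
              for (int kk = 0; kk < W; ++kk) nxt[kk] |= rr[kk];
            }
          }
          int newc = 0;
          for (int kk = 0; kk < W; ++kk) {
            nxt[kk] &= mask[kk];
            nxt[kk] &= ~vis[kk];
            newc += popcnt(nxt[kk]);
            vis[kk] |= nxt[kk];
          }
          if (newc == 0) break;
          ++d;
          suminv += (double)newc / d;
          frontier.swap(nxt);
        }
      }
    }
    tot += suminv / ((double)k * (k - 1));
  }
  return (N > 0) ? tot / N : 0.0;
}

// Newman degree assortativity: Pearson correlation over edge-end degree
// pairs (both orientations). NaN when end-degree variance is zero.
static double assortativity(const BitGraph& g) {
  const int N = g.N;
  double Sx = 0, Sxx = 0, Sxy = 0;
  long M = 0;
  for (int i = 0; i < N; ++i) {
    const uint64_t* ri = g.r(i);
    for (int w = 0; w < g.W; ++w) {
      uint64_t f = ri[w];
      while (f) {
        int b = __builtin_ctzll(f);
        f &= f - 1;
        int j = w * 64 + b;
        if (j <= i) continue;
        double x = g.deg[i], y = g.deg[j];
        Sx += x + y;
        Sxx += x * x + y * y;
        Sxy += 2.0 * x * y;
        M += 2;
      }
    }
  }
  if (M < 2) return R_NaN;
  double mx = Sx / M;
  double varx = Sxx / M - mx * mx;
  double cov = Sxy / M - mx * mx;
  if (varx <= 1e-14) return R_NaN;
  return cov / varx;
}

// Brandes betweenness (endpoints excluded, unordered pairs).
static std::vector<double> brandes_bc(const BitGraph& g) {
  const int N = g.N;
  // adjacency lists
  std::vector<int> adj, off(N + 1, 0);
  for (int i = 0; i < N; ++i) off[i + 1] = off[i] + g.deg[i];
  adj.resize(off[N]);
  {
    std::vector<int> pos(off.begin(), off.end() - 1);
    for (int i = 0; i < N; ++i) {
      const uint64_t* ri = g.r(i);
      for (int w = 0; w < g.W; ++w) {
        uint64_t f = ri[w];
        while (f) {
          int b = __builtin_ctzll(f);
          f &= f - 1;
          adj[pos[i]++] = w * 64 + b;
        }
      }
    }
  }
  std::vector<double> bc(N, 0.0), sigma(N), delta(N);
  std::vector<int> dist(N), order(N), queue(N);
  // predecessor lists share the adjacency layout (pred count <= degree)
  std::vector<int> preds(off[N]), npred(N);
  for (int s = 0; s < N; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    std::fill(npred.begin(), npred.end(), 0);
    int qh = 0, qt = 0, no = 0;
    dist[s] = 0; sigma[s] = 1.0; queue[qt++] = s;
    while (qh < qt) {
      int v = queue[qh++];
      order[no++] = v;
      for (int e = off[v]; e < off[v + 1]; ++e) {
        int w = adj[e];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; queue[qt++] = w; }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          preds[off[w] + npred[w]++] = v;
        }
      }
    }
    for (int idx = no - 1; idx > 0; --idx) {
      int w = order[idx];
      double coef = (1.0 + delta[w]) / sigma[w];
      for (int e = off[w], e1 = off[w] + npred[w]; e < e1; ++e) {
        int v = preds[e];
        delta[v] += sigma[v] * coef;
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < N; ++i) bc[i] /= 2.0;
  return bc;
}

// ---------------------------------------------------------------------------
// Modularity
// ---------------------------------------------------------------------------

static double partition_q(const BitGraph& g, const std::vector<int>& memb, int ncomm, double m) {
  std::vector<double> L(ncomm, 0.0), D(ncomm, 0.0);
  const int N = g.N;
  for (int i = 0; i < N; ++i) {
    D[memb[i]] += g.deg[i];
    const uint64_t* ri = g.r(i);
    for (int w = 0; w < g.W; ++w) {
      uint64_t f = ri[w];
      while (f) {
        int b = __builtin_ctzll(f);
        f &= f - 1;
        int j = w * 64 + b;
        if (j > i && memb[j] == memb[i]) L[memb[i]] += 1.0;
      }
    }
  }
  double q = 0.0;
  for (int c = 0; c < ncomm; ++c)
    q += L[c] / m - (D[c] / (2.0 * m)) * (D[c] / (2.0 * m));
  return q;
}

static void exact_mod_rec(const BitGraph& g, std::vector<int>& memb, int i, int maxg, double m, double& best) {
  const int N = g.N;
  if (i == N) {
    double q = partition_q(g, memb, maxg + 1, m);
    if (q > best) best = q;
    return;
  }
  for (int c = 0; c <= maxg + 1; ++c) {
    memb[i] = c;
    exact_mod_rec(g, memb, i + 1, std::max(maxg, c), m, best);
  }
}

// Greedy CNM agglomeration, deterministic tie-break by smallest (i,j) pair;
// returns the maximum Q over the merge sequence.
static double cnm_modularity(const BitGraph& g) {
  const int N = g.N;
  double m = g.n_edges();
  if (m < 1) return R_NaN;
  std::vector<std::vector<double>> L(N, std::vector<double>(N, 0.0));
  std::vector<double> D(N, 0.0);
  std::vector<char> alive(N, 1);
  for (int i = 0; i < N; ++i) {
    D[i] = g.deg[i];
    const uint64_t* ri = g.r(i);
    for (int w = 0; w < g.W; ++w) {
      uint64_t f = ri[w];
      while (f) {
        int b = __builtin_ctzll(f);
        f &= f - 1;
        int j = w * 64 + b;
        if (j > i) { L[i][j] = 1.0; L[j][i] = 1.0; }
      }
    }
  }
  double q = 0.0;
  for (int i = 0; i < N; ++i) q -= (D[i] / (2.0 * m)) * (D[i] / (2.0 * m));
  double best = q;
  for (int step = 0; step < N - 1; ++step) {
    double bestdq = -1e300;
    int bi = -1, bj = -1;
    for (int i = 0; i < N; ++i) {
      if (!alive[i]) continue;
      for (int j = i + 1; j < N; ++j) {
        if (!alive[j] || L[i][j] <= 0.0) continue;
        double dq = L[i][j] / m - 2.0 * (D[i] / (2.0 * m)) * (D[j] / (2.0 * m));
        if (dq > bestdq + 1e-15) { bestdq = dq; bi = i; bj = j; }
      }
    }
    if (bi < 0) break;  // no connected community pairs left
    // merge bj into bi
    for (int k = 0; k < N; ++k) {
      if (!alive[k] || k == bi || k == bj) continue;
      L[bi][k] += L[bj][k];
      L[k][bi] = L[bi][k];
    }
    D[bi] += D[bj];
    alive[bj] = 0;
    q += bestdq;
    if (q > best) best = q;
  }
  return best;
}

static double modularity_value(const BitGraph& g, int exact_max) {
  double m = g.n_edges();
  if (m < 1) return R_NaN;
  if (g.N <= exact_max) {
    std::vector<int> memb(g.N, 0);
    double best = -1e300;
    exact_mod_rec(g, memb, 1, 0, m, best);
    return best;
  }
  return cnm_modularity(g);
}

// ---------------------------------------------------------------------------
// Null networks
// ---------------------------------------------------------------------------

// Degree-preserving randomization via double-edge swaps. Target number of
// successful swaps = swap_factor * E; swaps that would create self-loops or
// multi-edges are rejected and redrawn. A null that ends up disconnected is
// discarded and regenerated (bounded retries), so every null used is
// connected with the original degree sequence.
static bool randomize_preserve_degrees(const BitGraph& src, BitGraph& out,
                                       std::vector<std::pair<int,int>>& edges0,
                                       double swap_factor, Xoshiro& rng,
                                       std::vector<uint64_t>& vb1, std::vector<uint64_t>& vb2) {
  const int E = (int)edges0.size();
  for (int attempt = 0; attempt < 60; ++attempt) {
    out = src;
    std::vector<std::pair<int,int>> edges(edges0);
    long target = (long)std::ceil(swap_factor * E);
    long done = 0, tries = 0, cap = 100L * (target > 0 ? target : 1);
    while (done < target && tries < cap) {
      ++tries;
      // one RNG draw yields both edge indices and the orientation coin
      uint64_t rr = rng.next();
      int e1 = (int)(((uint64_t)(uint32_t)(rr >> 32) * (uint32_t)E) >> 32);
      int e2 = (int)(((uint64_t)(uint32_t)rr * (uint32_t)E) >> 32);
      if (e1 == e2) continue;
      int a = edges[e1].first, b = edges[e1].second;
      int c = edges[e2].first, d = edges[e2].second;
      if ((rr >> 31) & 1ULL) std::swap(c, d);
      if (a == c || a == d || b == c || b == d) continue;
      if (out.has(a, d) || out.has(c, b)) continue;
      out.rem(a, b); out.rem(c, d);
      out.add(a, d); out.add(c, b);
      edges[e1] = std::make_pair(a, d);
      edges[e2] = std::make_pair(c, b);
      ++done;
    }
    if (is_connected(out, vb1, vb2)) return true;
  }
  return false;
}

// Erdos-Renyi G(n, E) alternative null (same node and edge count), kept
// connected by regeneration.
static bool randomize_er(int N, int E, BitGraph& out, Xoshiro& rng,
                         std::vector<uint64_t>& vb1, std::vector<uint64_t>& vb2) {
  for (int attempt = 0; attempt < 200; ++attempt) {
    out = BitGraph(N);
    int placed = 0;
    long guard = 0;
    while (placed < E && ++guard < 100L * E + 1000) {
      int i = rng.below(N), j = rng.below(N);
      if (i == j || out.has(i, j)) continue;
      out.add(i, j);
      ++placed;
    }
    if (placed == E && is_connected(out, vb1, vb2)) return true;
  }
  return false;
}

static void edge_list(const BitGraph& g, std::vector<std::pair<int,int>>& edges) {
  edges.clear();
  for (int i = 0; i < g.N; ++i) {
    const uint64_t* ri = g.r(i);
    for (int w = 0; w < g.W; ++w) {
      uint64_t f = ri[w];
      while (f) {
        int b = __builtin_ctzll(f);
        f &= f - 1;
        int j = w * 64 + b;
        if (j > i) edges.push_back(std::make_pair(i, j));
      }
    }
  }
}

// mean Cp and Lp over n_null connected null networks
static bool null_cp_lp(const BitGraph& g, int n_null, double swap_factor,
                       Xoshiro& rng, bool er_model, double& cprand, double& lprand) {
  std::vector<std::pair<int,int>> edges;
  edge_list(g, edges);
  const int E = (int)edges.size();
  BitGraph nul(g.N);
  std::vector<uint64_t> vb1, vb2;
  double scp = 0.0, slp = 0.0;
  for (int r = 0; r < n_null; ++r) {
    bool ok = er_model
      ? randomize_er(g.N, E, nul, rng, vb1, vb2)
      : randomize_preserve_degrees(g, nul, edges, swap_factor, rng, vb1, vb2);
    if (!ok) return false;
    double cp, tr, sumd, suminv;
    bool conn;
    clustering(nul, cp, tr);
    dist_sums(nul, sumd, suminv, conn);
    scp += cp;
    slp += sumd / ((double)g.N * (g.N - 1));
  }
  cprand = scp / n_null;
  lprand = slp / n_null;
  return true;
}

// ---------------------------------------------------------------------------
// Exported interface
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_graph_metrics")]]
List cpp_graph_metrics(IntegerMatrix adj, int exact_mod_max = 8) {
  BitGraph g = from_matrix(adj);
  const int N = g.N;
  double cp, trans, sumd, suminv;
  bool connected;
  clustering(g, cp, trans);
  dist_sums(g, sumd, suminv, connected);
  double pairs = (double)N * (N - 1);
  double lp = connected && N > 1 ? sumd / pairs : R_NaN;
  double eglob = N > 1 ? suminv / pairs : 0.0;
  double eloc = local_eff(g);
  double assort = assortativity(g);
  double q = modularity_value(g, exact_mod_max);
  std::vector<double> bc = brandes_bc(g);
  return List::create(
    _["cp"] = cp, _["lp"] = lp, _["eglob"] = eglob, _["eloc"] = eloc,
    _["trans"] = trans, _["assort"] = assort, _["q"] = q,
    _["bc"] = NumericVector(bc.begin(), bc.end()),
    _["degree"] = IntegerVector(g.deg.begin(), g.deg.end()),
    _["connected"] = connected, _["n_edges"] = g.n_edges());
}

// [[Rcpp::export(name = ".cpp_null_cp_lp")]]
NumericVector cpp_null_cp_lp(IntegerMatrix adj, int n_null, double swap_factor,
                             int seed, bool er_model = false) {
  BitGraph g = from_matrix(adj);
  Xoshiro rng((uint64_t)seed);
  double cprand, lprand;
  if (!null_cp_lp(g, n_null, swap_factor, rng, er_model, cprand, lprand))
    stop("could not generate a connected null network within the retry budget");
  return NumericVector::create(_["cprand"] = cprand, _["lprand"] = lprand);
}

// Ranked edge selection shared by thresholding and the curve engine: pairs
// ordered by descending (signed or absolute) association, ties broken by
// ascending (row, column) via stable sort over row-major pair order.
static void ranked_pairs(const NumericMatrix& assoc, bool absolute,
                         std::vector<int>& ord, std::vector<std::pair<int,int>>& pairs) {
  const int N = assoc.nrow();
  pairs.clear();
  std::vector<double> val;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      pairs.push_back(std::make_pair(i, j));
      double v = assoc(i, j);
      val.push_back(absolute ? std::fabs(v) : v);
    }
  ord.resize(pairs.size());
  for (size_t t = 0; t < ord.size(); ++t) ord[t] = (int)t;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return val[a] > val[b]; });
}

// [[Rcpp::export(name = ".cpp_threshold")]]
IntegerMatrix cpp_threshold(NumericMatrix assoc, int n_edges, bool absolute = false) {
  const int N = assoc.nrow();
  std::vector<int> ord;
  std::vector<std::pair<int,int>> pairs;
  ranked_pairs(assoc, absolute, ord, pairs);
  IntegerMatrix adj(N, N);
  for (int t = 0; t < n_edges; ++t) {
    int i = pairs[ord[t]].first, j = pairs[ord[t]].second;
    adj(i, j) = 1; adj(j, i) = 1;
  }
  return adj;
}

// [[Rcpp::export(name = ".cpp_connected_at")]]
bool cpp_connected_at(NumericMatrix assoc, int n_edges, bool absolute = false) {
  const int N = assoc.nrow();
  std::vector<int> ord;
  std::vector<std::pair<int,int>> pairs;
  ranked_pairs(assoc, absolute, ord, pairs);
  BitGraph g(N);
  for (int t = 0; t < n_edges; ++t)
    g.add(pairs[ord[t]].first, pairs[ord[t]].second);
  std::vector<uint64_t> vb1, vb2;
  return is_connected(g, vb1, vb2);
}

// Metric curves over a nested density grid for one association matrix.
// Returns a row per density: cp lp eglob eloc trans assort q cprand lprand
// gamma lambda sigma, plus a bc_norm matrix (density x node) and per-density
// connectivity flags. Null-network RNG is one continuous stream from `seed`.
// [[Rcpp::export(name = ".cpp_metric_curves")]]
List cpp_metric_curves(NumericMatrix assoc, IntegerVector n_edges, int n_null,
                       double swap_factor, int seed, bool with_nulls = true,
                       bool absolute = false, bool er_model = false,
                       int exact_mod_max = 8) {
  const int N = assoc.nrow();
  const int nd = n_edges.size();
  std::vector<int> ord;
  std::vector<std::pair<int,int>> pairs;
  ranked_pairs(assoc, absolute, ord, pairs);

  BitGraph g(N);
  Xoshiro rng((uint64_t)seed);
  NumericMatrix global(nd, 12);
  NumericMatrix bcn(nd, N);
  LogicalVector conn_flags(nd);
  int placed = 0;
  double pairs_n = (double)N * (N - 1);
  for (int d = 0; d < nd; ++d) {
    int E = n_edges[d];
    if (E < placed) stop("edge counts must be non-decreasing across the density grid");
    for (; placed < E; ++placed)
      g.add(pairs[ord[placed]].first, pairs[ord[placed]].second);

    double cp, trans, sumd, suminv;
    bool connected;
    clustering(g, cp, trans);
    dist_sums(g, sumd, suminv, connected);
    conn_flags[d] = connected;
    double lp = connected ? sumd / pairs_n : R_NaN;
    global(d, 0) = cp;
    global(d, 1) = lp;
    global(d, 2) = suminv / pairs_n;
    global(d, 3) = local_eff(g);
    global(d, 4) = trans;
    global(d, 5) = assortativity(g);
    global(d, 6) = modularity_value(g, exact_mod_max);
    double cprand = R_NaN, lprand = R_NaN;
    if (with_nulls && connected) {
      if (!null_cp_lp(g, n_null, swap_factor, rng, er_model, cprand, lprand))
        stop("could not generate a connected null network within the retry budget");
    }
    global(d, 7) = cprand;
    global(d, 8) = lprand;
    global(d, 9) = cprand > 0 ? cp / cprand : R_NaN;
    global(d, 10) = lprand > 0 ? lp / lprand : R_NaN;
    global(d, 11) = (cprand > 0 && lprand > 0) ? (cp / cprand) / (lp / lprand) : R_NaN;

    std::vector<double> bc = brandes_bc(g);
    double mbc = 0.0;
    for (int i = 0; i < N; ++i) mbc += bc[i];
    mbc /= N;
    for (int i = 0; i < N; ++i) bcn(d, i) = mbc > 0 ? bc[i] / mbc : 0.0;
  }
  colnames(global) = CharacterVector::create("cp", "lp", "eglob", "eloc",
    "trans", "assort", "q", "cprand", "lprand", "gamma", "lambda", "sigma");
  return List::create(_["global"] = global, _["bc_norm"] = bcn,
                      _["connected"] = conn_flags);
}

// Relative size of the largest connected component after sequential node
// removal in the given order (0-based); element k of the result is the state
// after k removals, so the curve has N+1 points from 1 (connected input)
// down to 0.
static void removal_curve(const BitGraph& g0, const std::vector<int>& ord, std::vector<double>& out) {
  const int N = g0.N, W = g0.W;
  std::vector<uint64_t> alive(W, 0);
  for (int i = 0; i < N; ++i) alive[i >> 6] |= 1ULL << (i & 63);
  out.assign(N + 1, 0.0);
  std::vector<uint64_t> seen(W), vis(W), frontier(W), nxt(W);
  for (int k = 0; k <= N; ++k) {
    if (k > 0) {
      int v = ord[k - 1];
      alive[v >> 6] &= ~(1ULL << (v & 63));
    }
    // largest component among alive nodes
    std::copy(alive.begin(), alive.end(), seen.begin());
    int best = 0;
    for (int w0 = 0; w0 < W; ++w0) {
      while (seen[w0]) {
        int b0 = __builtin_ctzll(seen[w0]);
        int s = w0 * 64 + b0;
        std::fill(vis.begin(), vis.end(), 0);
        std::fill(frontier.begin(), frontier.end(), 0);
        vis[s >> 6] |= 1ULL << (s & 63);
        frontier[s >> 6] |= 1ULL << (s & 63);
        int size = 1;
        while (true) {
          std::fill(nxt.begin(), nxt.end(), 0);
          for (int w = 0; w < W; ++w) {
            uint64_t f = frontier[w];
            while (f) {
              int b = __builtin_ctzll(f);
              f &= f - 1;
              const uint64_t* rr = g0.r(w * 64 + b);
              for (int kk = 0; kk < W; ++kk) nxt[kk] |= rr[kk];
            }
          }
          int newc = 0;
          for (int kk = 0; kk < W; ++kk) {
            nxt[kk] &= alive[kk] & ~vis[kk];
            newc += popcnt(nxt[kk]);
            vis[kk] |= nxt[kk];
          }
          if (newc == 0) break;
          size += newc;
          frontier.swap(nxt);
        }
        if (size > best) best = size;
        for (int kk = 0; kk < W; ++kk) seen[kk] &= ~vis[kk];
      }
    }
    out[k] = (double)best / N;
  }
}

// [[Rcpp::export(name = ".cpp_removal_curve")]]
NumericVector cpp_removal_curve(IntegerMatrix adj, IntegerVector order) {
  BitGraph g = from_matrix(adj);
  if (order.size() != g.N) stop("removal order must list every node exactly once");
  std::vector<int> ord(order.begin(), order.end());
  std::vector<double> out;
  removal_curve(g, ord, out);
  return NumericVector(out.begin(), out.end());
}

// Mean relative-LCC curve over n_iter uniformly random removal orders.
// [[Rcpp::export(name = ".cpp_random_failure_curve")]]
NumericVector cpp_random_failure_curve(IntegerMatrix adj, int n_iter, int seed) {
  BitGraph g = from_matrix(adj);
  const int N = g.N;
  Xoshiro rng((uint64_t)seed);
  std::vector<int> ord(N);
  std::vector<double> acc(N + 1, 0.0), cur;
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) ord[i] = i;
    for (int i = N - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(ord[i], ord[j]);
    }
    removal_curve(g, ord, cur);
    for (int k = 0; k <= N; ++k) acc[k] += cur[k];
  }
  for (int k = 0; k <= N; ++k) acc[k] /= n_iter;
  return NumericVector(acc.begin(), acc.end());
}

// [[Rcpp::export(name = ".cpp_betweenness")]]
NumericVector cpp_betweenness(IntegerMatrix adj) {
  BitGraph g = from_matrix(adj);
  std::vector<double> bc = brandes_bc(g);
  return NumericVector(bc.begin(), bc.end());
}

// Degree sequence of one degree-preserving null realization (test hook for
// the swap invariant).
// [[Rcpp::export(name = ".cpp_null_degrees")]]
IntegerVector cpp_null_degrees(IntegerMatrix adj, double swap_factor, int seed) {
  BitGraph g = from_matrix(adj);
  std::vector<std::pair<int,int>> edges;
  edge_list(g, edges);
  BitGraph nul(g.N);
  Xoshiro rng((uint64_t)seed);
  std::vector<uint64_t> vb1, vb2;
  if (!randomize_preserve_degrees(g, nul, edges, swap_factor, rng, vb1, vb2))
    stop("could not generate a connected null network within the retry budget");
  return IntegerVector(nul.deg.begin(), nul.deg.end());
}
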