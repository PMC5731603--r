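#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Exact maximum-weight matching on a general graph by subset DP.
// w is a dense k x k symmetric weight matrix; entries <= 0 mean "no edge".
// Intended for one connected component at a time (k <= 22).
// Returns 0-based partner indices, -1 for unmatched vertices.
// [[Rcpp::export]]
IntegerVector mwm_dp_cpp(NumericMatrix w) {
  const int k = w.nrow();
  if (k != w.ncol()) stop("weight matrix must be square");
  if (k > 22) stop("matching component too large (%d vertices > 22)", k);
  const uint32_t full = (k == 32) ? 0xffffffffu : ((1u << k) - 1u);
  std::vector<double> f((size_t)full + 1, 0.0);
  for (uint32_t mask = 1; mask <= full; ++mask) {
    int v = __builtin_ctz(mask);
    double best = f[mask & ~(1u << v)]; // v unmatched
    uint32_t rest = mask & ~(1u << v);
    uint32_t mm = rest;
    while (mm) {
      int u = __builtin_ctz(mm);
      mm &= mm - 1;
      double wv = w(v, u);
      if (wv > 0) {
        double s = wv + f[rest & ~(1u << u)];
        if (s > best) best = s;
      }
    }
    f[mask] = best;
  }
  IntegerVector partner(k, -1);
  uint32_t mask = full;
  while (mask) {
    int v = __builtin_ctz(mask);
    if (f[mask] == f[mask & ~(1u << v)]) { mask &= ~(1u << v); continue; }
    uint32_t rest = mask & ~(1u << v);
    uint32_t mm = rest;
    bool found = false;
    while (mm) {
      int u = __builtin_ctz(mm);
      mm &= mm - 1;
      if (w(v, u) > 0 && f[mask] == w(v, u) + f[rest & ~(1u << u)]) {
        partner[v] = u; partner[u] = v;
        mask = rest & ~(1u << u);
        found = true;
        break;
      }
    }
    if (!found) stop("internal error: matching DP reconstruction failed");
  }
  return partner;
}

namespace {

struct BfState {
  int nv;
  std::vector<int> parent;       // DSU over vertices, dashed edges pre-merged
  const IntegerMatrix* edges;    // E x 2, 0-based vertex ids
  const NumericVector* w;
  std::vector<double> suffix;    // suffix[i] = sum of w[i..E-1]
  uint32_t used;                 // matched-vertex bitmask
  double best;
  std::vector<int> cur, bestSet;

  int find(int x) const {
    while (parent[x] != x) x = parent[x];
    return x;
  }

  void rec(int e, double cw) {
    const int E = (*edges).nrow();
    if (cw > best) { best = cw; bestSet = cur; }
    if (e >= E) return;
    if (cw + suffix[e] <= best) return; // bound
    const int a = (*edges)(e, 0), b = (*edges)(e, 1);
    // take edge e if both endpoints unmatched and no alternating cycle arises
    if (!(used & (1u << a)) && !(used & (1u << b))) {
      int ra = find(a), rb = find(b);
      if (ra != rb) {
        parent[ra] = rb;
        used |= (1u << a) | (1u << b);
        cur.push_back(e);
        rec(e + 1, cw + (*w)[e]);
        cur.pop_back();
        used &= ~((1u << a) | (1u << b));
        parent[ra] = ra;
      }
    }
    rec(e + 1, cw); // skip edge e
  }
};

} // namespace

// Exact maximum weighted alternating path cover by exhaustive search.
// A cover is equivalent to a matching M on solid edges such that M plus the
// dashed edges is acyclic; search over such matchings with DSU cycle pruning
// and a suffix-weight bound.  Vertices: 2*nseg, vertex 2i = tail(i),
// 2i+1 = head(i); dashed edges are implicit (2i, 2i+1).
// [[Rcpp::export]]
List bf_cover_cpp(int nseg, IntegerMatrix edges, NumericVector w) {
  if (nseg > 16) stop("brute-force cover limited to 16 segments");
  const int nv = 2 * nseg, E = edges.nrow();
  BfState st;
  st.nv = nv;
  st.parent.resize(nv);
  for (int i = 0; i < nseg; ++i) { st.parent[2 * i] = 2 * i; st.parent[2 * i + 1] = 2 * i; }
  st.edges = &edges;
  st.w = &w;
  st.suffix.assign(E + 1, 0.0);
  for (int i = E - 1; i >= 0; --i) st.suffix[i] = st.suffix[i + 1] + w[i];
  st.used = 0;
  st.best = 0.0;
  st.rec(0, 0.0);
  return List::create(_["weight"] = st.best,
                      _["edges"] = IntegerVector(st.bestSet.begin(), st.bestSet.end()));
}
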