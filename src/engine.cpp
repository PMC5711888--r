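// Fast engine for synchronous Boolean network analysis.
//
// Rules arrive from R as postfix bytecode, one integer vector per node:
//   token >= 10 : push variable (node index = token - 10, 0-based)
//   token 0/1   : push constant
//   token -1    : NOT, -2 : AND, -3 : OR   (binary)
// Node order defines bit order: node i <-> bit i of a 64-bit state word.
// The engine supports networks with up to 64 nodes; the R layer falls back
// to a plain-R evaluator for anything larger (none of the bundled analyses
// need it).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_map>
#include <stdexcept>
#include <algorithm>
#include <string>
#include <functional>

using namespace Rcpp;

typedef uint64_t u64;
typedef uint32_t u32;

static const int TOK_NOT = -1, TOK_AND = -2, TOK_OR = -3;

// ---------------------------------------------------------------------------
// bytecode containers
// ---------------------------------------------------------------------------

struct Program {
  int n;                              // number of nodes
  std::vector<std::vector<int> > code; // postfix per node
  std::vector<u64> support;           // bitmask of nodes referenced per rule
};

static Program unpackProgram(List prog, int n) {
  if (n > 64) stop("fast engine supports at most 64 nodes");
  Program p; p.n = n;
  p.code.resize(n); p.support.assign(n, 0);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = prog[i];
    p.code[i].assign(v.begin(), v.end());
    for (int t : p.code[i]) if (t >= 10) {
      int j = t - 10;
      if (j < 0 || j >= n) stop("bytecode references node out of range");
      p.support[i] |= (u64(1) << j);
    }
  }
  return p;
}

// scalar evaluation of one rule on a full state word
static inline int evalRule(const std::vector<int>& code, u64 state) {
  int st[128]; int sp = 0;
  for (size_t k = 0; k < code.size(); ++k) {
    int t = code[k];
    if (t >= 10) st[sp++] = (int)((state >> (t - 10)) & 1);
    else if (t >= 0) st[sp++] = t;
    else if (t == TOK_NOT) st[sp - 1] = 1 - st[sp - 1];
    else if (t == TOK_AND) { --sp; st[sp - 1] = st[sp - 1] & st[sp]; }
    else { --sp; st[sp - 1] = st[sp - 1] | st[sp]; }
  }
  return st[0];
}

static inline u64 stepState(const Program& p, u64 s) {
  u64 nxt = 0;
  for (int i = 0; i < p.n; ++i)
    if (evalRule(p.code[i], s)) nxt |= (u64(1) << i);
  return nxt;
}

// ternary evaluation: values 0, 1, 2 (unknown)
static inline int evalRuleTernary(const std::vector<int>& code,
                                  const std::vector<uint8_t>& tri) {
  int st[128]; int sp = 0;
  for (size_t k = 0; k < code.size(); ++k) {
    int t = code[k];
    if (t >= 10) st[sp++] = tri[t - 10];
    else if (t >= 0) st[sp++] = t;
    else if (t == TOK_NOT) { int a = st[sp - 1]; st[sp - 1] = (a == 2) ? 2 : 1 - a; }
    else if (t == TOK_AND) {
      --sp; int a = st[sp - 1], b = st[sp];
      st[sp - 1] = (a == 0 || b == 0) ? 0 : ((a == 1 && b == 1) ? 1 : 2);
    } else {
      --sp; int a = st[sp - 1], b = st[sp];
      st[sp - 1] = (a == 1 || b == 1) ? 1 : ((a == 0 && b == 0) ? 0 : 2);
    }
  }
  return st[0];
}

// ---------------------------------------------------------------------------
// constant propagation (sound for attractors: once a rule's ternary value is
// determined by already-fixed nodes, the node holds that value in every
// attractor state)
// ---------------------------------------------------------------------------

// tri: 0/1 clamped or propagated constant, 2 free; clamped nodes are fixed
// before the call.  Nodes listed in `clamped` keep their values; all others
// may be promoted from 2 to a constant.
static void propagate(const Program& p, std::vector<uint8_t>& tri,
                      const std::vector<uint8_t>& isClamped) {
  bool changed = true;
  while (changed) {
    changed = false;
    for (int i = 0; i < p.n; ++i) {
      if (tri[i] != 2 || isClamped[i]) continue;
      int v = evalRuleTernary(p.code[i], tri);
      if (v != 2) { tri[i] = (uint8_t)v; changed = true; }
    }
  }
}

// ---------------------------------------------------------------------------
// core concretization: substitute constants into the free rules and renumber
// variables to core bit positions; constant-fold on the fly
// ---------------------------------------------------------------------------

struct CoreProg {
  int m;                                // number of free (core) nodes
  std::vector<int> coreNodes;           // node index per core position
  std::vector<std::vector<int> > code;  // postfix over core positions
};

struct Frag { bool isConst; int cval; std::vector<int> code; };

static std::vector<int> concretizeRule(const std::vector<int>& code,
                                       const std::vector<uint8_t>& tri,
                                       const std::vector<int>& corePos) {
  std::vector<Frag> st;
  for (size_t k = 0; k < code.size(); ++k) {
    int t = code[k];
    if (t >= 10) {
      int j = t - 10;
      Frag f;
      if (tri[j] != 2) { f.isConst = true; f.cval = tri[j]; }
      else { f.isConst = false; f.cval = 0; f.code.push_back(10 + corePos[j]); }
      st.push_back(std::move(f));
    } else if (t >= 0) {
      Frag f; f.isConst = true; f.cval = t; st.push_back(std::move(f));
    } else if (t == TOK_NOT) {
      Frag& a = st.back();
      if (a.isConst) a.cval = 1 - a.cval;
      else a.code.push_back(TOK_NOT);
    } else {
      Frag b = std::move(st.back()); st.pop_back();
      Frag& a = st.back();
      bool isAnd = (t == TOK_AND);
      int absorb = isAnd ? 0 : 1; // AND absorbs on 0, OR on 1
      if (a.isConst && b.isConst) {
        a.cval = isAnd ? (a.cval & b.cval) : (a.cval | b.cval);
      } else if (a.isConst) {
        if (a.cval == absorb) { a.cval = absorb; /* stays const */ }
        else { a = std::move(b); }
      } else if (b.isConst) {
        if (b.cval == absorb) { a.isConst = true; a.cval = absorb; a.code.clear(); }
        /* else keep a unchanged */
      } else {
        a.code.insert(a.code.end(), b.code.begin(), b.code.end());
        a.code.push_back(t);
      }
    }
  }
  Frag& r = st.back();
  if (r.isConst) { std::vector<int> c; c.push_back(r.cval); return c; }
  return std::move(r.code);
}

static CoreProg buildCore(const Program& p, const std::vector<uint8_t>& tri) {
  CoreProg cp; cp.m = 0;
  std::vector<int> corePos(p.n, -1);
  for (int i = 0; i < p.n; ++i)
    if (tri[i] == 2) { corePos[i] = cp.m++; cp.coreNodes.push_back(i); }
  cp.code.resize(cp.m);
  for (int q = 0; q < cp.m; ++q)
    cp.code[q] = concretizeRule(p.code[cp.coreNodes[q]], tri, corePos);
  return cp;
}

static inline int evalCoreScalar(const std::vector<int>& code, u64 s) {
  return evalRule(code, s);
}

static inline u64 stepCore(const CoreProg& cp, u64 s) {
  u64 nxt = 0;
  for (int q = 0; q < cp.m; ++q)
    if (evalCoreScalar(cp.code[q], s)) nxt |= (u64(1) << q);
  return nxt;
}

// ---------------------------------------------------------------------------
// bitsliced successor-array construction (64 states per block)
// ---------------------------------------------------------------------------

static inline u64 evalRuleWords(const std::vector<int>& code, const u64* w) {
  u64 st[128]; int sp = 0;
  for (size_t k = 0; k < code.size(); ++k) {
    int t = code[k];
    if (t >= 10) st[sp++] = w[t - 10];
    else if (t >= 0) st[sp++] = t ? ~u64(0) : 0;
    else if (t == TOK_NOT) st[sp - 1] = ~st[sp - 1];
    else if (t == TOK_AND) { --sp; st[sp - 1] &= st[sp]; }
    else { --sp; st[sp - 1] |= st[sp]; }
  }
  return st[0];
}

static void transpose64_anti(u64 a[64]) {
  int j; u64 m = 0x00000000FFFFFFFFULL;
  for (j = 32; j != 0; j >>= 1, m ^= m << j) {
    for (int k = 0; k < 64; k = ((k | j) + 1) & ~j) {
      u64 t = (a[k] ^ (a[k | j] >> j)) & m;
      a[k] ^= t;
      a[k | j] ^= (t << j);
    }
  }
}

// main-diagonal transpose: result[c] bit r == input[r] bit c
static void transpose64(u64 a[64]) {
  for (int i = 0; i < 32; ++i) std::swap(a[i], a[63 - i]);
  transpose64_anti(a);
  for (int i = 0; i < 32; ++i) std::swap(a[i], a[63 - i]);
}

static const u64 LANEPAT[6] = {
  0xAAAAAAAAAAAAAAAAULL, 0xCCCCCCCCCCCCCCCCULL, 0xF0F0F0F0F0F0F0F0ULL,
  0xFF00FF00FF00FF00ULL, 0xFFFF0000FFFF0000ULL, 0xFFFFFFFF00000000ULL };

static void buildSuccessors(const CoreProg& cp, std::vector<u32>& succ) {
  int m = cp.m;
  size_t N = size_t(1) << m;
  succ.resize(N);
  if (m <= 6) {
    for (size_t s = 0; s < N; ++s) succ[s] = (u32)stepCore(cp, (u64)s);
    return;
  }
  u64 w[64];
  u64 out[64];
  for (size_t base = 0; base < N; base += 64) {
    for (int p = 0; p < m; ++p)
      w[p] = (p < 6) ? LANEPAT[p] : (((base >> p) & 1) ? ~u64(0) : 0);
    for (int q = 0; q < 64; ++q) out[q] = 0;
    for (int q = 0; q < m; ++q) out[q] = evalRuleWords(cp.code[q], w);
    // out[q] bit lane = node q of state base+lane; transpose to per-lane words
    transpose64(out);
    // after transpose64, out[lane] bit q = original out[q] bit lane
    for (int lane = 0; lane < 64; ++lane)
      succ[base + lane] = (u32)out[lane];
  }
}

// ---------------------------------------------------------------------------
// attractor extraction from a successor array (functional-graph cycles)
// ---------------------------------------------------------------------------

typedef std::vector<std::vector<u64> > AttractorList; // each: cycle states

static void canonicalRotate(std::vector<u64>& cyc) {
  size_t best = 0;
  for (size_t k = 1; k < cyc.size(); ++k) if (cyc[k] < cyc[best]) best = k;
  std::rotate(cyc.begin(), cyc.begin() + best, cyc.end());
}

static AttractorList attractorsFromSuccessors(const std::vector<u32>& succ,
                                              std::vector<double>* basins) {
  size_t N = succ.size();
  std::vector<int32_t> color(N, 0);     // 0 unvisited, else run id
  std::vector<int32_t> attrOf;          // per run-terminal attractor id? use map below
  AttractorList res;
  std::vector<u32> path;
  std::vector<int32_t> attrId(basins ? N : 0, -1); // per state (only if basins)
  int32_t run = 0;
  for (size_t s0 = 0; s0 < N; ++s0) {
    if (color[s0]) continue;
    ++run;
    path.clear();
    u32 s = (u32)s0;
    while (!color[s]) { color[s] = run; path.push_back(s); s = succ[s]; }
    if (color[s] == run) {
      // new cycle: find position of s in path (it is the first state of cycle)
      size_t pos = path.size();
      while (pos > 0 && path[pos - 1] != s) --pos;
      --pos;
      std::vector<u64> cyc(path.begin() + pos, path.end());
      canonicalRotate(cyc);
      if (basins) for (size_t k = 0; k < path.size(); ++k) attrId[path[k]] = (int32_t)res.size();
      res.push_back(std::move(cyc));
    } else if (basins) {
      int32_t id = attrId[s];
      for (size_t k = 0; k < path.size(); ++k) attrId[path[k]] = id;
    }
  }
  if (basins) {
    basins->assign(res.size(), 0.0);
    for (size_t s = 0; s < N; ++s) (*basins)[attrId[s]] += 1.0;
  }
  // deterministic order: sort by (length, first state)
  std::vector<size_t> ord(res.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  if (!basins) {
    std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
      if (res[a].size() != res[b].size()) return res[a].size() < res[b].size();
      return res[a][0] < res[b][0];
    });
    AttractorList r2(res.size());
    for (size_t i = 0; i < ord.size(); ++i) r2[i] = std::move(res[ord[i]]);
    return r2;
  }
  return res;
}

// ===========================================================================
// BDD engine (reduced ordered BDDs, used for clamped cores too large to
// enumerate explicitly).  Attractor states are computed as the eventual image
// of the full core state space under the synchronous map; cycles are then
// peeled off by concrete iteration.
// ===========================================================================

// open-addressing hash map (u64 -> int32); the BDD engine is hash-bound, so
// this matters far more than any node-level micro-optimization
class FlatMap {
  std::vector<u64> keys;
  std::vector<int32_t> vals;
  size_t mask, count;
  static constexpr u64 EMPTYK = ~u64(0);
  static inline size_t mix(u64 k) {
    k ^= k >> 33; k *= 0xFF51AFD7ED558CCDULL; k ^= k >> 33;
    return (size_t)k;
  }
public:
  explicit FlatMap(size_t lg = 16)
    : keys(size_t(1) << lg, EMPTYK), vals(size_t(1) << lg),
      mask((size_t(1) << lg) - 1), count(0) {}
  inline int32_t* find(u64 k) {
    size_t h = mix(k) & mask;
    while (keys[h] != EMPTYK) {
      if (keys[h] == k) return &vals[h];
      h = (h + 1) & mask;
    }
    return nullptr;
  }
  inline void insert(u64 k, int32_t v) {
    if ((count + 1) * 5 > (mask + 1) * 3) grow();
    size_t h = mix(k) & mask;
    while (keys[h] != EMPTYK) {
      if (keys[h] == k) { vals[h] = v; return; }
      h = (h + 1) & mask;
    }
    keys[h] = k; vals[h] = v; ++count;
  }
  void grow() {
    std::vector<u64> ok; ok.swap(keys);
    std::vector<int32_t> ov; ov.swap(vals);
    size_t ncap = (mask + 1) * 2;
    keys.assign(ncap, EMPTYK); vals.assign(ncap, 0);
    mask = ncap - 1; count = 0;
    for (size_t i = 0; i < ok.size(); ++i)
      if (ok[i] != EMPTYK) insert(ok[i], ov[i]);
  }
  void clear() {
    std::fill(keys.begin(), keys.end(), EMPTYK);
    count = 0;
  }
  size_t size() const { return count; }
};

class BddMgr {
public:
  struct Node { int32_t var, lo, hi; };
  std::vector<Node> nodes;
  FlatMap uniq;
  FlatMap cache;
  size_t nodeCap;

  explicit BddMgr(size_t cap) : uniq(18), cache(18), nodeCap(cap) {
    nodes.reserve(1 << 18);
    nodes.push_back({ INT32_MAX, 0, 0 });   // 0 = FALSE
    nodes.push_back({ INT32_MAX, 1, 1 });   // 1 = TRUE
  }
  inline int var(int a) const { return nodes[a].var; }

  int mk(int v, int lo, int hi) {
    if (lo == hi) return lo;
    u64 key = (u64(v) << 56) | (u64(lo) << 28) | u64(hi);
    int32_t* hit = uniq.find(key);
    if (hit) return *hit;
    if (nodes.size() >= nodeCap)
      throw std::runtime_error("BDD node budget exceeded");
    int id = (int)nodes.size();
    nodes.push_back({ v, lo, hi });
    uniq.insert(key, id);
    return id;
  }

  enum Op { AND = 1, OR = 2, NOT = 3, RELP = 4, RENAME = 6 };

  static inline u64 ckey(int op, int a, int b) {
    return (u64(op) << 58) | (u64(a) << 29) | u64(b);
  }

  int and_(int a, int b) {
    if (a == 0 || b == 0) return 0;
    if (a == 1) return b;
    if (b == 1 || a == b) return a;
    if (a > b) std::swap(a, b);
    u64 key = ckey(AND, a, b);
    int32_t* hit = cache.find(key);
    if (hit) return *hit;
    int va = var(a), vb = var(b), v = std::min(va, vb);
    int a0 = (va == v) ? nodes[a].lo : a, a1 = (va == v) ? nodes[a].hi : a;
    int b0 = (vb == v) ? nodes[b].lo : b, b1 = (vb == v) ? nodes[b].hi : b;
    int r = mk(v, and_(a0, b0), and_(a1, b1));
    cache.insert(key, r);
    return r;
  }

  int or_(int a, int b) {
    if (a == 1 || b == 1) return 1;
    if (a == 0) return b;
    if (b == 0 || a == b) return a;
    if (a > b) std::swap(a, b);
    u64 key = ckey(OR, a, b);
    int32_t* hit = cache.find(key);
    if (hit) return *hit;
    int va = var(a), vb = var(b), v = std::min(va, vb);
    int a0 = (va == v) ? nodes[a].lo : a, a1 = (va == v) ? nodes[a].hi : a;
    int b0 = (vb == v) ? nodes[b].lo : b, b1 = (vb == v) ? nodes[b].hi : b;
    int r = mk(v, or_(a0, b0), or_(a1, b1));
    cache.insert(key, r);
    return r;
  }

  int not_(int a) {
    if (a == 0) return 1;
    if (a == 1) return 0;
    u64 key = ckey(NOT, a, 0);
    int32_t* hit = cache.find(key);
    if (hit) return *hit;
    int r = mk(var(a), not_(nodes[a].lo), not_(nodes[a].hi));
    cache.insert(key, r);
    return r;
  }

  // exists over variables marked in ex[] of (a AND b); exId tags the mask in
  // the cache key (masks are fixed per cluster position within one image run)
  int relprod(int a, int b, const std::vector<uint8_t>& ex, int exId) {
    if (a == 0 || b == 0) return 0;
    if (a == 1 && b == 1) return 1;
    int a_ = std::min(a, b), b_ = std::max(a, b);
    u64 key = (u64(RELP) << 58) | (u64(exId) << 52) | (u64(a_) << 26) | u64(b_);
    int32_t* hit = cache.find(key);
    if (hit) return *hit;
    int va = var(a), vb = var(b), v = std::min(va, vb);
    int a0 = (va == v) ? nodes[a].lo : a, a1 = (va == v) ? nodes[a].hi : a;
    int b0 = (vb == v) ? nodes[b].lo : b, b1 = (vb == v) ? nodes[b].hi : b;
    int r0 = relprod(a0, b0, ex, exId);
    int r;
    if (v < (int)ex.size() && ex[v]) {
      if (r0 == 1) r = 1;
      else { int r1 = relprod(a1, b1, ex, exId); r = or_(r0, r1); }
    } else {
      int r1 = relprod(a1, b1, ex, exId);
      r = mk(v, r0, r1);
    }
    cache.insert(key, r);
    return r;
  }

  // shift every variable down by one level (primed -> present); valid only
  // when all remaining variables are odd (primed)
  int rename_down(int a) {
    if (a <= 1) return a;
    u64 key = ckey(RENAME, a, 0);
    int32_t* hit = cache.find(key);
    if (hit) return *hit;
    int r = mk(var(a) - 1, rename_down(nodes[a].lo), rename_down(nodes[a].hi));
    cache.insert(key, r);
    return r;
  }

  void maybeTrimCache() {
    if (cache.size() > 8000000) cache.clear();
  }
};

// Variable order for the core: start from a DFS postorder (regulators early)
// and refine with a FORCE-style barycenter pass, which keeps tightly coupled
// nodes at nearby levels and shrinks the intermediate image BDDs
static std::vector<int> coreVarOrder(const CoreProg& cp) {
  int m = cp.m;
  std::vector<std::vector<int> > dep(m);   // q depends on dep[q]
  std::vector<std::vector<int> > nb(m);    // undirected adjacency
  for (int q = 0; q < m; ++q) {
    std::vector<char> seen(m, 0);
    for (int t : cp.code[q]) if (t >= 10 && !seen[t - 10]) {
      seen[t - 10] = 1; dep[q].push_back(t - 10);
      if (t - 10 != q) { nb[q].push_back(t - 10); nb[t - 10].push_back(q); }
    }
  }
  std::vector<int> order; order.reserve(m);
  std::vector<char> state(m, 0);
  for (int start = 0; start < m; ++start) {
    if (state[start]) continue;
    std::vector<std::pair<int, size_t> > stack;
    stack.push_back(std::make_pair(start, (size_t)0));
    state[start] = 1;
    while (!stack.empty()) {
      std::pair<int, size_t>& top = stack.back();
      if (top.second < dep[top.first].size()) {
        int nx = dep[top.first][top.second++];
        if (!state[nx]) { state[nx] = 1; stack.push_back(std::make_pair(nx, (size_t)0)); }
      } else {
        order.push_back(top.first);
        stack.pop_back();
      }
    }
  }
  std::vector<double> pos(m);
  for (int k = 0; k < m; ++k) pos[order[k]] = k;
  for (int round = 0; round < 60; ++round) {
    std::vector<double> np(m);
    for (int q = 0; q < m; ++q) {
      if (nb[q].empty()) { np[q] = pos[q]; continue; }
      double s = pos[q];
      for (int u : nb[q]) s += pos[u];
      np[q] = s / (double)(nb[q].size() + 1);
    }
    std::vector<int> ix(m);
    for (int q = 0; q < m; ++q) ix[q] = q;
    std::stable_sort(ix.begin(), ix.end(), [&](int a, int b) {
      return np[a] < np[b];
    });
    for (int k = 0; k < m; ++k) pos[ix[k]] = k;
  }
  std::vector<int> ord(m);
  for (int q = 0; q < m; ++q) ord[q] = (int)pos[q];
  return ord;
}

// build a rule BDD over present-variable levels 2*ord[q]
static int buildRuleBdd(BddMgr& B, const std::vector<int>& code,
                        const std::vector<int>& ord) {
  std::vector<int> st; st.reserve(code.size());
  for (size_t k = 0; k < code.size(); ++k) {
    int t = code[k];
    if (t >= 10) st.push_back(B.mk(2 * ord[t - 10], 0, 1));
    else if (t >= 0) st.push_back(t);
    else if (t == TOK_NOT) st.back() = B.not_(st.back());
    else if (t == TOK_AND) { int b = st.back(); st.pop_back(); st.back() = B.and_(st.back(), b); }
    else { int b = st.back(); st.pop_back(); st.back() = B.or_(st.back(), b); }
  }
  return st.back();
}

// Enumerate attractors of a concretized core with BDDs: the set of states on
// attractors is the eventual image of the full core space under the
// synchronous map (the decreasing chain f^t(full space) stabilizes after the
// longest transient); its cycles are then peeled off by concrete iteration.
// Exact by construction; an exceeded node budget raises rather than
// returning a partial result.
static AttractorList attractorsBdd(const CoreProg& cp, size_t nodeCap,
                                   bool verbose = false) {
  int m = cp.m;
  BddMgr B(nodeCap);
  std::vector<int> ord = coreVarOrder(cp);

  // transition clusters T_q = (y_q <-> f_q(x)); y_q sits at level 2*ord[q]+1
  std::vector<int> F(m), T(m);
  for (int q = 0; q < m; ++q) F[q] = buildRuleBdd(B, cp.code[q], ord);
  for (int q = 0; q < m; ++q) {
    int y = B.mk(2 * ord[q] + 1, 0, 1);
    T[q] = B.or_(B.and_(y, F[q]), B.and_(B.not_(y), B.not_(F[q])));
  }

  // cluster order: by deepest referenced present level, ascending
  std::vector<int> clOrder(m);
  for (int q = 0; q < m; ++q) clOrder[q] = q;
  std::vector<int> deepest(m, -1);
  for (int q = 0; q < m; ++q)
    for (int t : cp.code[q]) if (t >= 10) deepest[q] = std::max(deepest[q], 2 * ord[t - 10]);
  std::sort(clOrder.begin(), clOrder.end(), [&](int a, int b) {
    if (deepest[a] != deepest[b]) return deepest[a] < deepest[b];
    return a < b;
  });

  // quantification schedule: present var level 2*k is quantified in the last
  // cluster (by processing position) that references it
  std::vector<int> lastUse(2 * m, -1);
  for (int pos = 0; pos < m; ++pos) {
    int q = clOrder[pos];
    for (int t : cp.code[q]) if (t >= 10) {
      int lvl = 2 * ord[t - 10];
      lastUse[lvl] = std::max(lastUse[lvl], pos);
    }
  }
  std::vector<std::vector<uint8_t> > exSets(m, std::vector<uint8_t>(2 * m, 0));
  std::vector<uint8_t> unused(2 * m, 0);
  bool anyUnused = false;
  for (int q = 0; q < m; ++q) {
    int lvl = 2 * ord[q];
    if (lastUse[lvl] < 0) { unused[lvl] = 1; anyUnused = true; }
    else exSets[lastUse[lvl]][lvl] = 1;
  }

  // eventual image iteration from the full space
  int S = 1;
  int iter = 0;
  for (;;) {
    int cur = S;
    if (anyUnused) cur = B.relprod(cur, 1, unused, 63);
    for (int pos = 0; pos < m; ++pos)
      cur = B.relprod(cur, T[clOrder[pos]], exSets[pos], pos);
    cur = B.rename_down(cur);
    B.maybeTrimCache();
    if (verbose)
      Rprintf("  iter %d: arena %d nodes, cache %d\n", iter,
              (int)B.nodes.size(), (int)B.cache.size());
    if (cur == S) break;
    S = cur;
    if (++iter > 100000) throw std::runtime_error("image iteration failed to converge");
  }

  // peel cycles: pick a state in S, walk its cycle concretely, subtract
  AttractorList res;
  while (S != 0) {
    u64 st = 0;
    int a = S;
    while (a > 1) {      // any satisfying path; don't-care levels default 0
      const BddMgr::Node& nd = B.nodes[a];
      if (nd.hi != 0) { st |= (u64(1) << (nd.var / 2)); a = nd.hi; }
      else a = nd.lo;
    }
    u64 state = 0;       // st is indexed by level/2 = ord[q]; map back
    for (int q = 0; q < m; ++q)
      if ((st >> ord[q]) & 1) state |= (u64(1) << q);
    std::vector<u64> cyc;
    u64 s = state;
    do { cyc.push_back(s); s = stepCore(cp, s); } while (s != state);
    canonicalRotate(cyc);
    for (u64 c : cyc) {
      std::vector<std::pair<int, int> > bits; // (level, value)
      for (int q = 0; q < m; ++q)
        bits.push_back(std::make_pair(2 * ord[q], (int)((c >> q) & 1)));
      std::sort(bits.begin(), bits.end());
      int cube = 1;
      for (int k = (int)bits.size() - 1; k >= 0; --k) {
        if (bits[k].second) cube = B.mk(bits[k].first, 0, cube);
        else cube = B.mk(bits[k].first, cube, 0);
      }
      S = B.and_(S, B.not_(cube));
    }
    res.push_back(std::move(cyc));
    if (res.size() > 2000000) throw std::runtime_error("attractor count exploded");
  }
  std::sort(res.begin(), res.end(), [](const std::vector<u64>& a, const std::vector<u64>& b) {
    if (a.size() != b.size()) return a.size() < b.size();
    return a[0] < b[0];
  });
  return res;
}

// ---------------------------------------------------------------------------
// shared enumeration entry: clamp -> propagate -> core -> enumerate
// ---------------------------------------------------------------------------

struct EnumResult {
  std::vector<uint8_t> tri;   // propagated values (0/1/2)
  CoreProg core;
  AttractorList attractors;   // over core bits
  std::string backend;
};

static EnumResult enumerateClamped(const Program& p,
                                   const std::vector<int>& clampIdx,
                                   const std::vector<int>& clampVal,
                                   int bruteCap, size_t bddNodeCap,
                                   const std::string& backend) {
  EnumResult r;
  r.tri.assign(p.n, 2);
  std::vector<uint8_t> isClamped(p.n, 0);
  for (size_t k = 0; k < clampIdx.size(); ++k) {
    r.tri[clampIdx[k]] = (uint8_t)clampVal[k];
    isClamped[clampIdx[k]] = 1;
  }
  propagate(p, r.tri, isClamped);
  r.core = buildCore(p, r.tri);
  int m = r.core.m;
  if (backend == "propagate_only") {
    r.backend = "propagation";
    return r;
  }
  if (m == 0) {
    r.attractors.push_back(std::vector<u64>(1, 0));
    r.backend = "propagation";
    return r;
  }
  bool useBrute;
  if (backend == "brute") {
    if (m > 28) throw std::runtime_error("core too large for brute-force backend");
    useBrute = true;
  } else if (backend == "bdd" || backend == "bdd_verbose") useBrute = false;
  else useBrute = (m <= bruteCap);
  if (useBrute) {
    std::vector<u32> succ;
    buildSuccessors(r.core, succ);
    r.attractors = attractorsFromSuccessors(succ, nullptr);
    r.backend = "brute";
  } else {
    r.attractors = attractorsBdd(r.core, bddNodeCap, backend == "bdd_verbose");
    r.backend = "bdd";
  }
  return r;
}

// expand a core state to a full 64-bit state
static inline u64 expandState(const std::vector<uint8_t>& tri,
                              const CoreProg& cp, u64 coreState) {
  u64 s = 0;
  int n = (int)tri.size();
  for (int i = 0; i < n; ++i) if (tri[i] == 1) s |= (u64(1) << i);
  for (int q = 0; q < cp.m; ++q)
    if ((coreState >> q) & 1) s |= (u64(1) << cp.coreNodes[q]);
  return s;
}

static IntegerMatrix statesMatrix(const std::vector<u64>& fullStates, int n) {
  IntegerMatrix mat((int)fullStates.size(), n);
  for (size_t r = 0; r < fullStates.size(); ++r)
    for (int i = 0; i < n; ++i)
      mat((int)r, i) = (int)((fullStates[r] >> i) & 1);
  return mat;
}

// ---------------------------------------------------------------------------
// exported: single-trajectory iteration
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_iterate")]]
List cpp_iterate(List prog, int n, IntegerVector state, bool keepTrajectory) {
  Program p = unpackProgram(prog, n);
  u64 s = 0;
  for (int i = 0; i < n; ++i) if (state[i]) s |= (u64(1) << i);
  std::unordered_map<u64, int> seen;
  std::vector<u64> traj;
  int t = 0;
  for (;;) {
    auto it = seen.find(s);
    if (it != seen.end()) {
      int cycStart = it->second;
      std::vector<u64> cyc(traj.begin() + cycStart, traj.end());
      canonicalRotate(cyc);
      List out = List::create(
        _["states"] = statesMatrix(cyc, n),
        _["transient"] = cycStart,
        _["trajectory"] = keepTrajectory ? statesMatrix(traj, n) : IntegerMatrix(0, n));
      return out;
    }
    seen.emplace(s, t);
    traj.push_back(s);
    s = stepState(p, s);
    ++t;
  }
}

// [[Rcpp::export(name = ".cpp_step")]]
IntegerVector cpp_step(List prog, int n, IntegerVector state) {
  Program p = unpackProgram(prog, n);
  u64 s = 0;
  for (int i = 0; i < n; ++i) if (state[i]) s |= (u64(1) << i);
  u64 nx = stepState(p, s);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (int)((nx >> i) & 1);
  return out;
}

// ---------------------------------------------------------------------------
// exported: brute-force enumeration over the whole state space (toys)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_enumerate_bruteforce")]]
List cpp_enumerate_bruteforce(List prog, int n, bool basins) {
  if (n > 28) stop("brute-force enumeration capped at 28 nodes");
  Program p = unpackProgram(prog, n);
  std::vector<uint8_t> tri(n, 2);
  CoreProg cp = buildCore(p, tri);
  std::vector<u32> succ;
  buildSuccessors(cp, succ);
  std::vector<double> basinSizes;
  AttractorList al = attractorsFromSuccessors(succ, basins ? &basinSizes : nullptr);
  List atts(al.size());
  for (size_t k = 0; k < al.size(); ++k) {
    std::vector<u64> full(al[k].size());
    for (size_t j = 0; j < al[k].size(); ++j) full[j] = expandState(tri, cp, al[k][j]);
    atts[k] = statesMatrix(full, n);
  }
  List out = List::create(_["attractors"] = atts);
  if (basins) out["basins"] = NumericVector(basinSizes.begin(), basinSizes.end());
  return out;
}

// ---------------------------------------------------------------------------
// exported: exact enumeration for a clamped network
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_enumerate_clamped")]]
List cpp_enumerate_clamped(List prog, int n, IntegerVector clampIdx,
                           IntegerVector clampVal, int bruteCap,
                           double bddNodeCap, std::string backend) {
  Program p = unpackProgram(prog, n);
  std::vector<int> ci(clampIdx.begin(), clampIdx.end());
  std::vector<int> cv(clampVal.begin(), clampVal.end());
  EnumResult r;
  try {
    r = enumerateClamped(p, ci, cv, bruteCap, (size_t)bddNodeCap, backend);
  } catch (std::exception& e) {
    stop(std::string("exact enumeration failed: ") + e.what());
  }
  List atts(r.attractors.size());
  for (size_t k = 0; k < r.attractors.size(); ++k) {
    std::vector<u64> full(r.attractors[k].size());
    for (size_t j = 0; j < r.attractors[k].size(); ++j)
      full[j] = expandState(r.tri, r.core, r.attractors[k][j]);
    atts[k] = statesMatrix(full, n);
  }
  IntegerVector triOut(n);
  for (int i = 0; i < n; ++i) triOut[i] = r.tri[i] == 2 ? NA_INTEGER : (int)r.tri[i];
  return List::create(_["attractors"] = atts,
                      _["constants"] = triOut,
                      _["core_size"] = r.core.m,
                      _["backend"] = r.backend);
}

// ---------------------------------------------------------------------------
// exported: full micro-environment sweep
// ---------------------------------------------------------------------------

struct KeyHash {
  size_t operator()(const std::pair<u64, u64>& k) const {
    u64 h = k.first * 0x9E3779B97F4A7C15ULL ^ (k.second + 0x517CC1B727220A95ULL);
    h ^= h >> 31; h *= 0xBF58476D1CE4E5B9ULL; h ^= h >> 29;
    return (size_t)h;
  }
};

// labels: 1 Phalanx, 2 Stalk, 3 Tip, 4 Other (state) / Atypical (attractor, env)
static inline int labelState(u64 s, int iNRP1, int iDLL4a, int iAKT, int iJAGa) {
  int nrp1 = (int)((s >> iNRP1) & 1), dll4a = (int)((s >> iDLL4a) & 1);
  int akt = (int)((s >> iAKT) & 1), jaga = (int)((s >> iJAGa) & 1);
  if (nrp1 == 1 && dll4a == 1 && akt == 0) return 3;
  if (jaga == 1 && nrp1 == 0) return 2;
  if (akt == 1 && jaga == 0 && nrp1 == 0) return 1;
  return 4;
}

// [[Rcpp::export(name = ".cpp_sweep")]]
List cpp_sweep(List prog, int n, IntegerVector inputIdx,
               IntegerVector markerIdx, IntegerVector mutIdx,
               IntegerVector mutVal, int bruteCap, double bddNodeCap,
               bool progress) {
  Program p = unpackProgram(prog, n);
  int nin = inputIdx.size();
  if (nin > 30) stop("too many inputs for an exhaustive sweep");
  size_t NE = size_t(1) << nin;
  int iNRP1 = markerIdx[0], iDLL4a = markerIdx[1], iAKT = markerIdx[2],
      iJAGa = markerIdx[3], iBcat = markerIdx[4], iLEF1 = markerIdx[5];

  // support masks for the refined memo key
  std::vector<u64> support = p.support;

  std::vector<uint8_t> isMut(n, 0);
  for (int k = 0; k < mutIdx.size(); ++k) isMut[mutIdx[k]] = 1;

  typedef std::pair<u64, u64> Key;
  std::unordered_map<Key, int, KeyHash> memo;
  std::vector<std::pair<CoreProg, AttractorList> > stash; // per distinct key

  IntegerVector envBehavior(NE), envNAtt(NE), envProlif(NE);
  LogicalVector hasTip(NE), hasStalk(NE), hasPhal(NE);

  std::vector<int> clampIdx, clampVal;
  std::vector<uint8_t> tri(n), isClamped(n);

  for (size_t env = 0; env < NE; ++env) {
    if (progress && (env & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    // clamp: mutations override environment bits
    std::fill(tri.begin(), tri.end(), (uint8_t)2);
    std::fill(isClamped.begin(), isClamped.end(), (uint8_t)0);
    for (int k = 0; k < nin; ++k) {
      int node = inputIdx[k];
      int bit = (int)((env >> (nin - 1 - k)) & 1); // first input = MSB
      tri[node] = (uint8_t)bit; isClamped[node] = 1;
    }
    for (int k = 0; k < mutIdx.size(); ++k) {
      tri[mutIdx[k]] = (uint8_t)mutVal[k]; isClamped[mutIdx[k]] = 1;
    }
    propagate(p, tri, isClamped);

    u64 freeMask = 0, constVals = 0, refMask = 0;
    for (int i = 0; i < n; ++i) {
      if (tri[i] == 2) { freeMask |= (u64(1) << i); refMask |= support[i]; }
    }
    // marker constants always matter for classification; fold them into the key
    for (int k = 0; k < 6; ++k) refMask |= (u64(1) << markerIdx[k]);
    for (int i = 0; i < n; ++i)
      if (tri[i] == 1) constVals |= (u64(1) << i);
    Key key(freeMask, constVals & refMask & ~freeMask);

    int slot;
    auto it = memo.find(key);
    if (it != memo.end()) slot = it->second;
    else {
      CoreProg cp = buildCore(p, tri);
      AttractorList al;
      try {
        if (cp.m == 0) al.push_back(std::vector<u64>(1, 0));
        else if (cp.m <= bruteCap) {
          std::vector<u32> succ;
          buildSuccessors(cp, succ);
          al = attractorsFromSuccessors(succ, nullptr);
        } else {
          al = attractorsBdd(cp, (size_t)bddNodeCap);
        }
      } catch (std::exception& e) {
        stop("exact enumeration failed for environment " +
             std::to_string(env) + ": " + e.what());
      }
      slot = (int)stash.size();
      stash.push_back(std::make_pair(std::move(cp), std::move(al)));
      memo.emplace(key, slot);
    }

    const CoreProg& cp = stash[slot].first;
    const AttractorList& al = stash[slot].second;
    // per-attractor behavior and proliferation labels for this environment
    int envLab = 0;           // 0 unset; 1..3 behavior; 4 atypical
    bool anyDiv = false, allDiv = true;
    bool tipA = false, stalkA = false, phalA = false;
    for (size_t a = 0; a < al.size(); ++a) {
      int attLab = 0; bool div = true;
      for (size_t j = 0; j < al[a].size(); ++j) {
        u64 full = expandState(tri, cp, al[a][j]);
        int sl = labelState(full, iNRP1, iDLL4a, iAKT, iJAGa);
        if (attLab == 0) attLab = sl;
        else if (attLab != sl) attLab = 4;
        if (!(((full >> iBcat) & 1) && ((full >> iLEF1) & 1))) div = false;
      }
      if (attLab == 3) tipA = true;
      else if (attLab == 2) stalkA = true;
      else if (attLab == 1) phalA = true;
      if (div) anyDiv = true; else allDiv = false;
      if (envLab == 0) envLab = attLab;
      else if (envLab != attLab) envLab = 4;
    }
    envBehavior[env] = envLab;
    envNAtt[env] = (int)al.size();
    envProlif[env] = allDiv ? 1 : (anyDiv ? 2 : 3); // all / some / none
    hasTip[env] = tipA; hasStalk[env] = stalkA; hasPhal[env] = phalA;
  }

  return List::create(_["behavior"] = envBehavior,
                      _["n_attractors"] = envNAtt,
                      _["proliferation"] = envProlif,
                      _["has_tip"] = hasTip,
                      _["has_stalk"] = hasStalk,
                      _["has_phalanx"] = hasPhal,
                      _["n_cores"] = (int)stash.size());
}

// ---------------------------------------------------------------------------
// Monte-Carlo engines: robustness to single-bit activation noise
// ---------------------------------------------------------------------------

struct SplitMix {
  u64 x;
  explicit SplitMix(u64 seed) : x(seed) {}
  u64 next() {
    u64 z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
};

// flat open-addressing hash table mapping state -> attractor id
class StateCache {
  std::vector<u64> keys;
  std::vector<int32_t> vals;
  size_t mask, count, cap;
  static constexpr u64 EMPTY = ~u64(0);
public:
  explicit StateCache(size_t logSize, size_t maxEntries)
    : keys(size_t(1) << logSize, EMPTY), vals(size_t(1) << logSize, -1),
      mask((size_t(1) << logSize) - 1), count(0), cap(maxEntries) {}
  inline int32_t find(u64 k) const {
    size_t h = (size_t)(k * 0x9E3779B97F4A7C15ULL) & mask;
    while (keys[h] != EMPTY) {
      if (keys[h] == k) return vals[h];
      h = (h + 1) & mask;
    }
    return -1;
  }
  inline bool insert(u64 k, int32_t v) {
    if (count >= cap || count * 10 >= keys.size() * 7) return false;
    size_t h = (size_t)(k * 0x9E3779B97F4A7C15ULL) & mask;
    while (keys[h] != EMPTY) {
      if (keys[h] == k) return true;
      h = (h + 1) & mask;
    }
    keys[h] = k; vals[h] = v; ++count;
    return true;
  }
  size_t size() const { return count; }
};

// iterate a state to its attractor; returns attractor id, registering new
// attractors in the cache and the label table
static int32_t toAttractor(const Program& p, u64 s, StateCache& cache,
                           std::vector<int>& attrLabel,
                           std::vector<u64>& attrMin,
                           int iNRP1, int iDLL4a, int iAKT, int iJAGa,
                           std::vector<u64>& path) {
  path.clear();
  std::unordered_map<u64, int> local;
  for (;;) {
    int32_t id = cache.find(s);
    if (id >= 0) {
      for (u64 q : path) cache.insert(q, id);
      return id;
    }
    auto it = local.find(s);
    if (it != local.end()) {
      // new cycle discovered starting at position it->second
      int32_t nid = (int32_t)attrLabel.size();
      int lab = 0; u64 mn = ~u64(0);
      for (size_t k = it->second; k < path.size(); ++k) {
        int sl = labelState(path[k], iNRP1, iDLL4a, iAKT, iJAGa);
        if (lab == 0) lab = sl; else if (lab != sl) lab = 4;
        if (path[k] < mn) mn = path[k];
      }
      if (lab == 4) lab = 5; // attractor-level: mixed/Other => atypical (5)
      attrLabel.push_back(lab);
      attrMin.push_back(mn);
      for (u64 q : path) cache.insert(q, nid);
      return nid;
    }
    local.emplace(s, (int)path.size());
    path.push_back(s);
    s = stepState(p, s);
  }
}

// [[Rcpp::export(name = ".cpp_robustness")]]
List cpp_robustness(List prog, int n, IntegerVector markerIdx,
                    double nRep, double seed, double cacheLog) {
  Program p = unpackProgram(prog, n);
  int iNRP1 = markerIdx[0], iDLL4a = markerIdx[1], iAKT = markerIdx[2],
      iJAGa = markerIdx[3];
  size_t N = (size_t)nRep;
  SplitMix rng((u64)seed * 0x2545F4914F6CDD1DULL + 0x9E3779B97F4A7C15ULL);
  size_t lg = (size_t)cacheLog;
  StateCache cache(lg, (size_t(1) << lg) * 7 / 10);
  std::vector<int> attrLabel;   // 1 Phalanx 2 Stalk 3 Tip 5 atypical
  std::vector<u64> attrMin;
  std::vector<u64> path;

  u64 mask = (n == 64) ? ~u64(0) : ((u64(1) << n) - 1);
  double sameAttr = 0, sameBeh = 0;
  double denom[4] = { 0, 0, 0, 0 }, match[4] = { 0, 0, 0, 0 }; // 1..3 used

  for (size_t r = 0; r < N; ++r) {
    if ((r & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    u64 s = rng.next() & mask;
    int flip = (int)(rng.next() % (u64)n);
    u64 s2 = s ^ (u64(1) << flip);
    int32_t a1 = toAttractor(p, s, cache, attrLabel, attrMin,
                             iNRP1, iDLL4a, iAKT, iJAGa, path);
    int32_t a2 = toAttractor(p, s2, cache, attrLabel, attrMin,
                             iNRP1, iDLL4a, iAKT, iJAGa, path);
    // canonical min state identifies the attractor even if the cache filled
    // up and the same cycle was registered twice
    if (attrMin[a1] == attrMin[a2]) sameAttr += 1;
    int l1 = attrLabel[a1], l2 = attrLabel[a2];
    if (l1 == l2) sameBeh += 1;
    if (l1 >= 1 && l1 <= 3) {
      denom[l1] += 1;
      if (l1 == l2) match[l1] += 1;
    }
  }
  return List::create(
    _["n"] = (double)N,
    _["same_attractor"] = sameAttr,
    _["same_behavior"] = sameBeh,
    _["denom_phalanx"] = denom[1], _["match_phalanx"] = match[1],
    _["denom_stalk"] = denom[2], _["match_stalk"] = match[2],
    _["denom_tip"] = denom[3], _["match_tip"] = match[3],
    _["n_attractors_seen"] = (int)attrLabel.size(),
    _["cache_entries"] = (double)cache.size());
}

// ---------------------------------------------------------------------------
// per-rule sensitivity: Monte-Carlo estimate and exact influence sum
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_sensitivity")]]
List cpp_sensitivity(List prog, int n, double nRep, double seed,
                     int analyticCap) {
  Program p = unpackProgram(prog, n);
  size_t N = (size_t)nRep;
  NumericVector est(n), analytic(n);
  u64 mask = (n == 64) ? ~u64(0) : ((u64(1) << n) - 1);
  for (int i = 0; i < n; ++i) {
    // Monte Carlo (fresh deterministic stream per rule)
    SplitMix rng(((u64)seed * 0x2545F4914F6CDD1DULL) ^ (u64(i) * 0xDA942042E4DD58B5ULL)
                 ^ 0x9E3779B97F4A7C15ULL);
    size_t diff = 0;
    const std::vector<int>& code = p.code[i];
    for (size_t r = 0; r < N; ++r) {
      u64 s = rng.next() & mask;
      int flip = (int)(rng.next() % (u64)n);
      if (!((p.support[i] >> flip) & 1)) continue; // output cannot change
      if (evalRule(code, s) != evalRule(code, s ^ (u64(1) << flip))) ++diff;
    }
    est[i] = (double)diff / (double)N;
    // analytic: sum of Boolean influences over support / n
    std::vector<int> sup;
    for (int j = 0; j < n; ++j) if ((p.support[i] >> j) & 1) sup.push_back(j);
    if ((int)sup.size() <= analyticCap) {
      int k = (int)sup.size();
      double infl = 0;
      size_t K = size_t(1) << k;
      for (int jj = 0; jj < k; ++jj) {
        size_t cnt = 0;
        for (size_t a = 0; a < K; ++a) {
          u64 s = 0;
          for (int b = 0; b < k; ++b) if ((a >> b) & 1) s |= (u64(1) << sup[b]);
          if (evalRule(code, s) != evalRule(code, s ^ (u64(1) << sup[jj]))) ++cnt;
        }
        infl += (double)cnt / (double)K;
      }
      analytic[i] = infl / (double)n;
    } else analytic[i] = NA_REAL;
  }
  return List::create(_["estimate"] = est, _["analytic"] = analytic);
}
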