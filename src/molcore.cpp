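// Core numeric kernels: FNV-1a hashing, Morgan environment keys, the
// chemical-dictionary store, familiarity scoring with the key-dependency
// cascade, fingerprints and single-edit perturbation application.
// Everything here is index-hot; the user-facing API lives in R/.

#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <string>
#include <vector>
#include <array>
#include <map>
#include <unordered_map>
#include <algorithm>
#include <queue>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// FNV-1a 64-bit hashing (platform-independent; scheme id "fnv1a64/v1")
// ---------------------------------------------------------------------------

static const uint64_t FNV_OFFSET = 1469598103934665603ULL;
static const uint64_t FNV_PRIME  = 1099511628211ULL;

static inline uint64_t fnv1a_u64(uint64_t x, uint64_t h) {
  for (int i = 0; i < 8; ++i) {
    h ^= (x & 0xffULL);
    h *= FNV_PRIME;
    x >>= 8;
  }
  return h;
}

static inline uint64_t fnv1a_ints(const std::vector<int64_t>& v) {
  uint64_t h = FNV_OFFSET;
  for (int64_t x : v) h = fnv1a_u64((uint64_t)x, h);
  return h;
}

static std::string hash_hex(uint64_t h) {
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}

// ---------------------------------------------------------------------------
// Molecule representation
// ---------------------------------------------------------------------------

struct Mol {
  std::vector<int> Z, Q, H;
  std::vector<std::array<int, 3>> bonds;              // a, b (0-based), order
  std::vector<std::vector<std::pair<int, int>>> adj;  // neighbour, order
  int n() const { return (int)Z.size(); }
  int m() const { return (int)bonds.size(); }
  void build_adj() {
    adj.assign(Z.size(), {});
    for (auto& b : bonds) {
      adj[b[0]].push_back({b[1], b[2]});
      adj[b[1]].push_back({b[0], b[2]});
    }
  }
};

static Mol mol_from_R(const List& mol) {
  Mol m;
  IntegerVector Z = mol["Z"], Q = mol["Q"], H = mol["H"];
  IntegerMatrix B = mol["bonds"];
  int n = Z.size();
  m.Z.assign(Z.begin(), Z.end());
  m.Q.assign(Q.begin(), Q.end());
  m.H.assign(H.begin(), H.end());
  for (int i = 0; i < B.nrow(); ++i) {
    int a = B(i, 0) - 1, b = B(i, 1) - 1, o = B(i, 2);
    if (a < 0 || b < 0 || a >= n || b >= n)
      stop("bond references an atom index out of range");
    m.bonds.push_back({a, b, o});
  }
  m.build_adj();
  return m;
}

static List mol_to_R(const Mol& m) {
  int n = m.n(), nb = m.m();
  IntegerVector Z(n), Q(n), H(n);
  for (int i = 0; i < n; ++i) { Z[i] = m.Z[i]; Q[i] = m.Q[i]; H[i] = m.H[i]; }
  IntegerMatrix B(nb, 3);
  for (int i = 0; i < nb; ++i) {
    B(i, 0) = m.bonds[i][0] + 1;
    B(i, 1) = m.bonds[i][1] + 1;
    B(i, 2) = m.bonds[i][2];
  }
  colnames(B) = CharacterVector::create("a", "b", "order");
  List out = List::create(_["Z"] = Z, _["Q"] = Q, _["H"] = H, _["bonds"] = B);
  out.attr("class") = "molgraph";
  return out;
}

// ---------------------------------------------------------------------------
// Keys
// ---------------------------------------------------------------------------

typedef std::array<int, 5> AtomKey;  // D, V, Z, Q, H

static std::vector<AtomKey> atom_keys(const Mol& m) {
  std::vector<AtomKey> ak(m.n());
  for (int i = 0; i < m.n(); ++i) {
    int D = (int)m.adj[i].size(), V = 0;
    for (auto& nb : m.adj[i]) V += nb.second;
    ak[i] = {D, V, m.Z[i], m.Q[i], m.H[i]};
  }
  return ak;
}

static std::string key_prefix_str(const AtomKey& k, int j) {
  std::string s;
  char buf[16];
  for (int i = 0; i < j; ++i) {
    if (i) s.push_back(',');
    std::snprintf(buf, sizeof(buf), "%d", k[i]);
    s += buf;
  }
  return s;
}

static inline std::string atom_key_str(const AtomKey& k) { return key_prefix_str(k, 5); }

// canonical: endpoint keys sorted ascending component-wise
static void canon_bond(const AtomKey& k1, const AtomKey& k2, int order,
                       std::string& bond_str, std::string& pbond_str) {
  const AtomKey *a = &k1, *b = &k2;
  if (k2 < k1) { a = &k2; b = &k1; }
  pbond_str = atom_key_str(*a) + ";" + atom_key_str(*b);
  char buf[16];
  std::snprintf(buf, sizeof(buf), "%d", order);
  bond_str = pbond_str + ";" + buf;
}

static uint64_t atom_key_hash(const AtomKey& k) {
  std::vector<int64_t> v(k.begin(), k.end());
  return fnv1a_ints(v);
}

// Morgan rounds: invariants per radius 0..rounds
static std::vector<std::vector<uint64_t>> morgan_rounds(const Mol& m, int rounds) {
  int n = m.n();
  std::vector<std::vector<uint64_t>> inv(rounds + 1, std::vector<uint64_t>(n));
  std::vector<AtomKey> ak = atom_keys(m);
  for (int i = 0; i < n; ++i) inv[0][i] = atom_key_hash(ak[i]);
  for (int r = 1; r <= rounds; ++r) {
    for (int i = 0; i < n; ++i) {
      std::vector<std::pair<int, uint64_t>> nb;
      for (auto& p : m.adj[i]) nb.push_back({p.second, inv[r - 1][p.first]});
      std::sort(nb.begin(), nb.end());
      uint64_t h = FNV_OFFSET;
      h = fnv1a_u64(inv[r - 1][i], h);
      for (auto& p : nb) {
        h = fnv1a_u64((uint64_t)p.first, h);
        h = fnv1a_u64(p.second, h);
      }
      inv[r][i] = h;
    }
  }
  return inv;
}

// atoms within topological distance r of center (center included)
static std::vector<int> env_members(const Mol& m, int center, int radius) {
  std::vector<int> dist(m.n(), -1);
  std::queue<int> q;
  dist[center] = 0;
  q.push(center);
  std::vector<int> out;
  while (!q.empty()) {
    int v = q.front(); q.pop();
    out.push_back(v);
    if (dist[v] == radius) continue;
    for (auto& p : m.adj[v])
      if (dist[p.first] < 0) { dist[p.first] = dist[v] + 1; q.push(p.first); }
  }
  std::sort(out.begin(), out.end());
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_atom_keys(List mol) {
  Mol m = mol_from_R(mol);
  std::vector<AtomKey> ak = atom_keys(m);
  IntegerMatrix out(m.n(), 5);
  for (int i = 0; i < m.n(); ++i)
    for (int j = 0; j < 5; ++j) out(i, j) = ak[i][j];
  colnames(out) = CharacterVector::create("D", "V", "Z", "Q", "H");
  return out;
}

// [[Rcpp::export]]
List cpp_env_keys(List mol, int radius) {
  Mol m = mol_from_R(mol);
  int n = m.n();
  std::vector<std::vector<uint64_t>> inv = morgan_rounds(m, radius);
  CharacterVector keys(n);
  List members(n);
  for (int i = 0; i < n; ++i) {
    keys[i] = hash_hex(inv[radius][i]);
    std::vector<int> mem = env_members(m, i, radius);
    IntegerVector mv(mem.size());
    for (size_t k = 0; k < mem.size(); ++k) mv[k] = mem[k] + 1;
    members[i] = mv;
  }
  return List::create(_["keys"] = keys, _["members"] = members);
}

// circular-substructure fingerprint: radii 0..radius, folded to nbits
static std::vector<int> fingerprint_bits(const Mol& m, int radius, int nbits) {
  std::vector<std::vector<uint64_t>> inv = morgan_rounds(m, radius);
  std::vector<int> bits;
  for (int r = 0; r <= radius; ++r)
    for (int i = 0; i < m.n(); ++i)
      bits.push_back((int)(inv[r][i] % (uint64_t)nbits));
  std::sort(bits.begin(), bits.end());
  bits.erase(std::unique(bits.begin(), bits.end()), bits.end());
  return bits;
}

// [[Rcpp::export]]
IntegerVector cpp_fingerprint(List mol, int radius = 2, int nbits = 2048) {
  Mol m = mol_from_R(mol);
  std::vector<int> bits = fingerprint_bits(m, radius, nbits);
  return IntegerVector(bits.begin(), bits.end());
}

// one Morgan round
static void morgan_step(const Mol& m, const std::vector<uint64_t>& prev,
                        std::vector<uint64_t>& next) {
  int n = m.n();
  next.resize(n);
  for (int i = 0; i < n; ++i) {
    std::vector<std::pair<int, uint64_t>> nb;
    for (auto& p : m.adj[i]) nb.push_back({p.second, prev[p.first]});
    std::sort(nb.begin(), nb.end());
    uint64_t h = FNV_OFFSET;
    h = fnv1a_u64(prev[i], h);
    for (auto& p : nb) {
      h = fnv1a_u64((uint64_t)p.first, h);
      h = fnv1a_u64(p.second, h);
    }
    next[i] = h;
  }
}

static int distinct_count(std::vector<uint64_t> v) {
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  return (int)v.size();
}

// refine invariants until the partition stabilizes (plus one extra round)
static std::vector<uint64_t> refined_invariants(const Mol& m,
                                               const std::vector<uint64_t>& init) {
  std::vector<uint64_t> cur = init, next;
  int prev_distinct = distinct_count(cur);
  for (int r = 0; r < m.n(); ++r) {
    morgan_step(m, cur, next);
    int d = distinct_count(next);
    cur.swap(next);
    if (d == prev_distinct) break;
    prev_distinct = d;
  }
  return cur;
}

static std::string graph_hash_core(const Mol& m) {
  int n = m.n();
  if (n == 0) return hash_hex(FNV_OFFSET);
  std::vector<AtomKey> ak = atom_keys(m);
  std::vector<uint64_t> init(n);
  for (int i = 0; i < n; ++i) init[i] = atom_key_hash(ak[i]);
  std::vector<uint64_t> fin = refined_invariants(m, init);
  std::vector<uint64_t> sorted_inv(fin);
  std::sort(sorted_inv.begin(), sorted_inv.end());
  std::vector<std::array<uint64_t, 3>> edges;
  for (auto& b : m.bonds) {
    uint64_t x = fin[b[0]], y = fin[b[1]];
    if (y < x) std::swap(x, y);
    edges.push_back({x, y, (uint64_t)b[2]});
  }
  std::sort(edges.begin(), edges.end());
  uint64_t h = FNV_OFFSET;
  h = fnv1a_u64((uint64_t)n, h);
  h = fnv1a_u64((uint64_t)m.m(), h);
  for (uint64_t x : sorted_inv) h = fnv1a_u64(x, h);
  for (auto& e : edges)
    for (uint64_t x : e) h = fnv1a_u64(x, h);
  return hash_hex(h);
}

// [[Rcpp::export]]
std::string cpp_graph_hash(List mol) {
  Mol m = mol_from_R(mol);
  return graph_hash_core(m);
}

// [[Rcpp::export]]
IntegerMatrix cpp_dist_matrix(List mol) {
  Mol m = mol_from_R(mol);
  int n = m.n();
  const int INF = 1000000;
  IntegerMatrix D(n, n);
  for (int s = 0; s < n; ++s) {
    std::vector<int> dist(n, INF);
    std::queue<int> q;
    dist[s] = 0; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (auto& p : m.adj[v])
        if (dist[p.first] == INF) { dist[p.first] = dist[v] + 1; q.push(p.first); }
    }
    for (int i = 0; i < n; ++i) D(s, i) = dist[i];
  }
  return D;
}

// ---------------------------------------------------------------------------
// Standard-valence table (organic subset, charge-adjusted)
// ---------------------------------------------------------------------------

static std::vector<int> default_valences(int Z, int Q) {
  switch (Z) {
    case 5:  if (Q == 0) return {3}; if (Q == -1) return {4}; break;
    case 6:  if (Q == 0) return {4}; if (Q == 1 || Q == -1) return {3}; break;
    case 7:  if (Q == 0) return {3}; if (Q == 1) return {4}; if (Q == -1) return {2}; break;
    case 8:  if (Q == 0) return {2}; if (Q == 1) return {3}; if (Q == -1) return {1}; break;
    case 15: if (Q == 0) return {3, 5}; if (Q == 1) return {4}; break;
    case 16: if (Q == 0) return {2, 4, 6}; if (Q == 1) return {3, 5}; if (Q == -1) return {1}; break;
    case 9: case 17: case 35: case 53:
      if (Q == 0) return {1}; break;
    default: break;
  }
  return {};
}

// [[Rcpp::export]]
IntegerVector cpp_default_valences(int Z, int Q) {
  std::vector<int> v = default_valences(Z, Q);
  return IntegerVector(v.begin(), v.end());
}

// set H toward the smallest standard valence >= V; no table entry or V over
// the maximum leaves the atom untouched
static void sanitize_atoms(Mol& m, const std::vector<int>& touched) {
  for (int i : touched) {
    if (i < 0 || i >= m.n()) continue;
    std::vector<int> dv = default_valences(m.Z[i], m.Q[i]);
    if (dv.empty()) continue;
    int V = 0;
    for (auto& p : m.adj[i]) V += p.second;
    int target = -1;
    for (int d : dv) if (d >= V) { target = d; break; }
    if (target < 0) continue;
    m.H[i] = target - V;
  }
}

// [[Rcpp::export]]
List cpp_sanitize(List mol, IntegerVector touched) {
  Mol m = mol_from_R(mol);
  std::vector<int> t;
  for (int i : touched) t.push_back(i - 1);
  sanitize_atoms(m, t);
  return mol_to_R(m);
}

// ---------------------------------------------------------------------------
// Perturbation application
// cand encoding (7 ints): kind, i, j, a1, a2, a3, a4
//   1 set_hydrogens(i, a1)        2 set_charge(i, a1)
//   3 set_element(i, a1)          4 set_bond_type(i, j, a1)
//   5 delete_bond(i, j)           6 delete_atom(i)
//   7 insert_bond(i, j, a1)       8 insert_atom(i, Z=a1, Q=a2, H=a3, order=a4)
//   (insert_atom H = -1 derives H from the valence table)
// ---------------------------------------------------------------------------

static int find_bond(const Mol& m, int a, int b) {
  for (int i = 0; i < m.m(); ++i) {
    if ((m.bonds[i][0] == a && m.bonds[i][1] == b) ||
        (m.bonds[i][0] == b && m.bonds[i][1] == a)) return i;
  }
  return -1;
}

// keep the largest connected component (ties: the one holding the lowest
// atom index); returns old->new mapping (-1 dropped)
static std::vector<int> keep_largest_component(Mol& m) {
  int n = m.n();
  std::vector<int> comp(n, -1);
  int nc = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    std::queue<int> q;
    comp[s] = nc; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (auto& p : m.adj[v])
        if (comp[p.first] < 0) { comp[p.first] = nc; q.push(p.first); }
    }
    ++nc;
  }
  if (nc <= 1) {
    std::vector<int> id(n);
    for (int i = 0; i < n; ++i) id[i] = i;
    return id;
  }
  std::vector<int> size(nc, 0);
  for (int i = 0; i < n; ++i) ++size[comp[i]];
  int best = 0;
  for (int c = 1; c < nc; ++c) if (size[c] > size[best]) best = c;
  // components are discovered in order of their lowest atom index, so the
  // first component of maximal size also holds the lowest index
  std::vector<int> map(n, -1);
  int k = 0;
  for (int i = 0; i < n; ++i) if (comp[i] == best) map[i] = k++;
  Mol out;
  for (int i = 0; i < n; ++i) {
    if (map[i] < 0) continue;
    out.Z.push_back(m.Z[i]); out.Q.push_back(m.Q[i]); out.H.push_back(m.H[i]);
  }
  for (auto& b : m.bonds)
    if (map[b[0]] >= 0 && map[b[1]] >= 0)
      out.bonds.push_back({map[b[0]], map[b[1]], b[2]});
  out.build_adj();
  m = out;
  return map;
}

static Mol apply_cand(const Mol& in, const int* c, bool sanitize) {
  Mol m = in;
  int kind = c[0], i = c[1] - 1, j = c[2] - 1;
  std::vector<int> touched;
  switch (kind) {
    case 1: m.H[i] = c[3]; break;
    case 2: m.Q[i] = c[3]; break;
    case 3: m.Z[i] = c[3]; break;
    case 4: {
      int bi = find_bond(m, i, j);
      if (bi < 0) stop("no such bond");
      m.bonds[bi][2] = c[3];
      m.build_adj();
      touched = {i, j};
      break;
    }
    case 5: {
      int bi = find_bond(m, i, j);
      if (bi < 0) stop("no such bond");
      m.bonds.erase(m.bonds.begin() + bi);
      m.build_adj();
      std::vector<int> map = keep_largest_component(m);
      touched.clear();
      if (map[i] >= 0) touched.push_back(map[i]);
      if (map[j] >= 0) touched.push_back(map[j]);
      break;
    }
    case 6: {
      std::vector<int> nbrs;
      for (auto& p : m.adj[i]) nbrs.push_back(p.first);
      Mol out;
      std::vector<int> map0(m.n(), -1);
      int k = 0;
      for (int a = 0; a < m.n(); ++a) {
        if (a == i) continue;
        map0[a] = k++;
        out.Z.push_back(m.Z[a]); out.Q.push_back(m.Q[a]); out.H.push_back(m.H[a]);
      }
      for (auto& b : m.bonds)
        if (b[0] != i && b[1] != i)
          out.bonds.push_back({map0[b[0]], map0[b[1]], b[2]});
      out.build_adj();
      m = out;
      std::vector<int> map = keep_largest_component(m);
      for (int a : nbrs)
        if (map0[a] >= 0 && map[map0[a]] >= 0) touched.push_back(map[map0[a]]);
      break;
    }
    case 7: {
      if (find_bond(m, i, j) >= 0) stop("bond already exists");
      m.bonds.push_back({i, j, c[3]});
      m.build_adj();
      touched = {i, j};
      break;
    }
    case 8: {
      int z = c[3], q = c[4], h = c[5], o = c[6];
      m.Z.push_back(z); m.Q.push_back(q);
      m.H.push_back(h < 0 ? 0 : h);
      int newi = m.n() - 1;
      m.bonds.push_back({i, newi, o});
      m.build_adj();
      if (h < 0) {
        std::vector<int> dv = default_valences(z, q);
        int hh = 0;
        for (int d : dv) if (d >= o) { hh = d - o; break; }
        m.H[newi] = hh;
      }
      touched = {i};  // the inserted atom's invariants are part of the edit
      break;
    }
    default: stop("unknown perturbation kind");
  }
  if (sanitize && !touched.empty()) sanitize_atoms(m, touched);
  return m;
}

// [[Rcpp::export]]
List cpp_apply_cand(List mol, IntegerVector cand, bool sanitize) {
  Mol m = mol_from_R(mol);
  std::vector<int> c(cand.begin(), cand.end());
  if (c.size() != 7) stop("candidate must have 7 fields");
  Mol out = apply_cand(m, c.data(), sanitize);
  return mol_to_R(out);
}

// ---------------------------------------------------------------------------
// Chemical dictionary
// ---------------------------------------------------------------------------

struct ChemDict {
  int radius;
  long long threshold;
  long long n_molecules;
  // 0 atom, 1 partial atom, 2 bond, 3 partial bond, 4 environment
  std::unordered_map<std::string, long long> tab[5];
  std::unordered_map<std::string, std::map<int, long long>> atom_succ;  // prefix -> value -> count
  std::unordered_map<std::string, std::map<int, long long>> bond_succ;  // pbond -> order -> count
};

static void dict_add(ChemDict& d, const Mol& m) {
  std::vector<AtomKey> ak = atom_keys(m);
  for (int i = 0; i < m.n(); ++i) {
    d.tab[0][atom_key_str(ak[i])] += 1;
    for (int j = 1; j <= 4; ++j) d.tab[1][key_prefix_str(ak[i], j)] += 1;
    for (int j = 1; j <= 5; ++j)
      d.atom_succ[key_prefix_str(ak[i], j - 1)][ak[i][j - 1]] += 1;
  }
  for (auto& b : m.bonds) {
    std::string bs, pbs;
    canon_bond(ak[b[0]], ak[b[1]], b[2], bs, pbs);
    d.tab[2][bs] += 1;
    d.tab[3][pbs] += 1;
    d.bond_succ[pbs][b[2]] += 1;
  }
  std::vector<std::vector<uint64_t>> inv = morgan_rounds(m, d.radius);
  for (int i = 0; i < m.n(); ++i) d.tab[4][hash_hex(inv[d.radius][i])] += 1;
  d.n_molecules += 1;
}

// [[Rcpp::export]]
SEXP cpp_dict_new(int radius, double threshold) {
  ChemDict* d = new ChemDict();
  d->radius = radius;
  d->threshold = (long long)threshold;
  d->n_molecules = 0;
  XPtr<ChemDict> p(d, true);
  return p;
}

static ChemDict* get_dict(SEXP xp) {
  XPtr<ChemDict> p(xp);
  if (!p) stop("invalid dictionary pointer (rebuild or reload the dictionary)");
  return p.get();
}

// [[Rcpp::export]]
void cpp_dict_add_molecule(SEXP xp, List mol) {
  ChemDict* d = get_dict(xp);
  Mol m = mol_from_R(mol);
  dict_add(*d, m);
}

// [[Rcpp::export]]
List cpp_dict_info(SEXP xp) {
  ChemDict* d = get_dict(xp);
  IntegerVector sizes(5);
  for (int i = 0; i < 5; ++i) sizes[i] = (int)d->tab[i].size();
  sizes.names() = CharacterVector::create("atom", "partial_atom", "bond",
                                          "partial_bond", "environment");
  return List::create(_["radius"] = d->radius,
                      _["threshold"] = (double)d->threshold,
                      _["n_molecules"] = (double)d->n_molecules,
                      _["n_keys"] = sizes);
}

// [[Rcpp::export]]
NumericVector cpp_dict_counts(SEXP xp, int category, CharacterVector keys) {
  ChemDict* d = get_dict(xp);
  if (category < 0 || category > 4) stop("bad category");
  NumericVector out(keys.size());
  for (int i = 0; i < keys.size(); ++i) {
    auto it = d->tab[category].find(std::string(keys[i]));
    out[i] = (it == d->tab[category].end()) ? 0.0 : (double)it->second;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dict_successors(SEXP xp, int type, std::string prefix) {
  ChemDict* d = get_dict(xp);
  const std::unordered_map<std::string, std::map<int, long long>>& tabs =
      (type == 0) ? d->atom_succ : d->bond_succ;
  auto it = tabs.find(prefix);
  if (it == tabs.end())
    return List::create(_["value"] = IntegerVector(0), _["count"] = NumericVector(0));
  std::vector<std::pair<long long, int>> v;  // (-count, value) for sort
  for (auto& p : it->second) v.push_back({-p.second, p.first});
  std::sort(v.begin(), v.end());
  IntegerVector vals(v.size());
  NumericVector cnts(v.size());
  for (size_t i = 0; i < v.size(); ++i) { vals[i] = v[i].second; cnts[i] = (double)(-v[i].first); }
  return List::create(_["value"] = vals, _["count"] = cnts);
}

// [[Rcpp::export]]
List cpp_dict_export(SEXP xp) {
  ChemDict* d = get_dict(xp);
  List out(5);
  for (int c = 0; c < 5; ++c) {
    std::vector<std::string> keys;
    keys.reserve(d->tab[c].size());
    for (auto& p : d->tab[c]) keys.push_back(p.first);
    std::sort(keys.begin(), keys.end());
    CharacterVector kv(keys.size());
    NumericVector cv(keys.size());
    for (size_t i = 0; i < keys.size(); ++i) {
      kv[i] = keys[i];
      cv[i] = (double)d->tab[c].at(keys[i]);
    }
    out[c] = List::create(_["key"] = kv, _["count"] = cv);
  }
  out.names() = CharacterVector::create("atom", "partial_atom", "bond",
                                        "partial_bond", "environment");
  return out;
}

static int parse_int(const std::string& s) {
  int v = 0, sign = 1;
  size_t i = 0;
  if (i < s.size() && (s[i] == '-' || s[i] == '+')) {
    if (s[i] == '-') sign = -1;
    ++i;
  }
  for (; i < s.size(); ++i) {
    if (s[i] < '0' || s[i] > '9') break;
    v = v * 10 + (s[i] - '0');
  }
  return sign * v;
}

static std::vector<int> parse_int_csv(const std::string& s) {
  std::vector<int> out;
  size_t p = 0;
  while (p < s.size()) {
    size_t q = s.find(',', p);
    if (q == std::string::npos) q = s.size();
    out.push_back(parse_int(s.substr(p, q - p)));
    p = q + 1;
  }
  return out;
}

// rebuild successor tables from full atom/bond key tables
static void rebuild_successors(ChemDict& d) {
  d.atom_succ.clear();
  d.bond_succ.clear();
  for (auto& p : d.tab[0]) {
    std::vector<int> k = parse_int_csv(p.first);
    if (k.size() != 5) continue;
    AtomKey ak = {k[0], k[1], k[2], k[3], k[4]};
    for (int j = 1; j <= 5; ++j)
      d.atom_succ[key_prefix_str(ak, j - 1)][ak[j - 1]] += p.second;
  }
  for (auto& p : d.tab[2]) {
    size_t pos = p.first.rfind(';');
    if (pos == std::string::npos) continue;
    std::string pb = p.first.substr(0, pos);
    int order = parse_int(p.first.substr(pos + 1));
    d.bond_succ[pb][order] += p.second;
  }
}

// [[Rcpp::export]]
SEXP cpp_dict_import(int radius, double threshold, double n_molecules, List tables) {
  ChemDict* d = new ChemDict();
  d->radius = radius;
  d->threshold = (long long)threshold;
  d->n_molecules = (long long)n_molecules;
  for (int c = 0; c < 5; ++c) {
    List t = tables[c];
    CharacterVector kv = t["key"];
    NumericVector cv = t["count"];
    for (int i = 0; i < kv.size(); ++i)
      d->tab[c][std::string(kv[i])] = (long long)cv[i];
  }
  rebuild_successors(*d);
  XPtr<ChemDict> p(d, true);
  return p;
}

// distinct atom-key property values and degree-1 keys, used to define the
// single-edit universe
// [[Rcpp::export]]
List cpp_dict_value_sets(SEXP xp) {
  ChemDict* d = get_dict(xp);
  std::vector<int> zs, qs, hs;
  std::vector<std::array<long long, 5>> deg1;  // V,Z,Q,H,count
  for (auto& p : d->tab[0]) {
    std::vector<int> k = parse_int_csv(p.first);
    if (k.size() != 5) continue;
    zs.push_back(k[2]); qs.push_back(k[3]); hs.push_back(k[4]);
    if (k[0] == 1 && k[1] >= 1 && k[1] <= 3)
      deg1.push_back({k[1], k[2], k[3], k[4], p.second});
  }
  auto uniq = [](std::vector<int>& v) {
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  };
  uniq(zs); uniq(qs); uniq(hs);
  std::sort(deg1.begin(), deg1.end(),
            [](const std::array<long long, 5>& a, const std::array<long long, 5>& b) {
              if (a[4] != b[4]) return a[4] > b[4];  // count desc
              return std::lexicographical_compare(a.begin(), a.begin() + 4,
                                                  b.begin(), b.begin() + 4);
            });
  IntegerMatrix dm(deg1.size(), 5);
  for (size_t i = 0; i < deg1.size(); ++i)
    for (int j = 0; j < 5; ++j) dm(i, j) = (int)deg1[i][j];
  colnames(dm) = CharacterVector::create("order", "Z", "Q", "H", "count");
  return List::create(_["Z"] = IntegerVector(zs.begin(), zs.end()),
                      _["Q"] = IntegerVector(qs.begin(), qs.end()),
                      _["H"] = IntegerVector(hs.begin(), hs.end()),
                      _["deg1_keys"] = dm);
}

// ---------------------------------------------------------------------------
// Familiarity with the key-dependency cascade
// ---------------------------------------------------------------------------

struct FamResult {
  int n_a, n_b, n_e, nf_a, nf_b, nf_e;
  std::vector<int> atom_level;            // 0 familiar, else most significant foreign j
  std::vector<char> bond_familiar, env_familiar;
  std::vector<double> pb_count, b_count, env_count;
  std::vector<std::string> atom_key_strs, bond_strs, pbond_strs, env_strs;
  NumericMatrix prefix_counts;
  std::vector<std::vector<int>> members;
};

static void familiarity_core(const ChemDict& d, const Mol& m, bool details, FamResult& r,
                             const std::vector<uint64_t>* env_inv = nullptr) {
  int n = m.n(), nb = m.m();
  long long t = d.threshold;
  std::vector<AtomKey> ak = atom_keys(m);
  r.n_a = n; r.n_b = nb; r.n_e = n;
  r.atom_level.assign(n, 0);
  if (details) r.prefix_counts = NumericMatrix(n, 5);
  r.atom_key_strs.resize(n);
  for (int i = 0; i < n; ++i) {
    r.atom_key_strs[i] = atom_key_str(ak[i]);
    int level = 0;
    for (int j = 1; j <= 5; ++j) {
      std::string ks = (j == 5) ? r.atom_key_strs[i] : key_prefix_str(ak[i], j);
      auto it = (j == 5) ? d.tab[0].find(ks) : d.tab[1].find(ks);
      long long cnt = (j == 5)
        ? ((it == d.tab[0].end()) ? 0 : it->second)
        : ((it == d.tab[1].end()) ? 0 : it->second);
      if (details) r.prefix_counts(i, j - 1) = (double)cnt;
      if (level == 0 && cnt <= t) level = j;
      if (level != 0 && !details) break;
    }
    r.atom_level[i] = level;
  }
  r.nf_a = 0;
  for (int i = 0; i < n; ++i) if (r.atom_level[i] == 0) ++r.nf_a;

  r.bond_familiar.assign(nb, 0);
  r.bond_strs.resize(nb); r.pbond_strs.resize(nb);
  r.pb_count.assign(nb, 0); r.b_count.assign(nb, 0);
  r.nf_b = 0;
  for (int i = 0; i < nb; ++i) {
    int a = m.bonds[i][0], b = m.bonds[i][1];
    canon_bond(ak[a], ak[b], m.bonds[i][2], r.bond_strs[i], r.pbond_strs[i]);
    auto itp = d.tab[3].find(r.pbond_strs[i]);
    auto itb = d.tab[2].find(r.bond_strs[i]);
    r.pb_count[i] = (itp == d.tab[3].end()) ? 0 : (double)itp->second;
    r.b_count[i] = (itb == d.tab[2].end()) ? 0 : (double)itb->second;
    bool fam = (r.atom_level[a] == 0) && (r.atom_level[b] == 0) &&
               (r.pb_count[i] > t) && (r.b_count[i] > t);
    r.bond_familiar[i] = fam ? 1 : 0;
    if (fam) ++r.nf_b;
  }

  std::vector<uint64_t> env_hash;
  if (env_inv != nullptr) {
    env_hash = *env_inv;
  } else {
    std::vector<std::vector<uint64_t>> inv = morgan_rounds(m, d.radius);
    env_hash = inv[d.radius];
  }
  r.env_familiar.assign(n, 0);
  r.env_strs.resize(n);
  r.env_count.assign(n, 0);
  r.members.resize(n);
  r.nf_e = 0;
  for (int i = 0; i < n; ++i) {
    r.env_strs[i] = hash_hex(env_hash[i]);
    auto it = d.tab[4].find(r.env_strs[i]);
    r.env_count[i] = (it == d.tab[4].end()) ? 0 : (double)it->second;
    std::vector<int> mem = env_members(m, i, d.radius);
    r.members[i] = mem;
    bool fam = r.env_count[i] > t;
    if (fam) {
      std::vector<char> in_env(n, 0);
      for (int a : mem) in_env[a] = 1;
      for (int a : mem) if (r.atom_level[a] != 0) { fam = false; break; }
      if (fam) {
        for (int bi = 0; bi < nb; ++bi) {
          if (in_env[m.bonds[bi][0]] && in_env[m.bonds[bi][1]] && !r.bond_familiar[bi]) {
            fam = false; break;
          }
        }
      }
    }
    r.env_familiar[i] = fam ? 1 : 0;
    if (fam) ++r.nf_e;
  }
}

static List fam_to_R(const FamResult& r, bool details) {
  int n = r.n_a + r.n_b + r.n_e;
  int nf = r.nf_a + r.nf_b + r.nf_e;
  double f1 = (n > 0) ? (double)nf / n : NA_REAL;
  double f2 = (n > 0) ? 1.0 / (n - nf + 1) : NA_REAL;
  List out = List::create(
      _["n_a"] = r.n_a, _["n_b"] = r.n_b, _["n_e"] = r.n_e,
      _["nf_a"] = r.nf_a, _["nf_b"] = r.nf_b, _["nf_e"] = r.nf_e,
      _["n"] = n, _["nf"] = nf, _["f1"] = f1, _["f2"] = f2);
  if (!details) return out;
  int na = r.n_a, nb = r.n_b;
  CharacterVector aks(na), bks(nb), pbks(nb), eks(na);
  LogicalVector afam(na), bfam(nb), efam(na);
  IntegerVector alev(na);
  NumericVector pbc(nb), bc(nb), ec(na);
  List mem(na);
  for (int i = 0; i < na; ++i) {
    aks[i] = r.atom_key_strs[i];
    alev[i] = r.atom_level[i];
    afam[i] = (r.atom_level[i] == 0);
    eks[i] = r.env_strs[i];
    efam[i] = (bool)r.env_familiar[i];
    ec[i] = r.env_count[i];
    IntegerVector mv(r.members[i].size());
    for (size_t k = 0; k < r.members[i].size(); ++k) mv[k] = r.members[i][k] + 1;
    mem[i] = mv;
  }
  for (int i = 0; i < nb; ++i) {
    bks[i] = r.bond_strs[i];
    pbks[i] = r.pbond_strs[i];
    bfam[i] = (bool)r.bond_familiar[i];
    pbc[i] = r.pb_count[i];
    bc[i] = r.b_count[i];
  }
  out["atom_keys"] = aks;
  out["atom_foreign_level"] = alev;
  out["atom_familiar"] = afam;
  out["atom_prefix_counts"] = r.prefix_counts;
  out["bond_keys"] = bks;
  out["pbond_keys"] = pbks;
  out["bond_familiar"] = bfam;
  out["bond_count"] = bc;
  out["pbond_count"] = pbc;
  out["env_keys"] = eks;
  out["env_familiar"] = efam;
  out["env_count"] = ec;
  out["env_members"] = mem;
  return out;
}

// [[Rcpp::export]]
List cpp_familiarity(SEXP xp, List mol, bool details = false) {
  ChemDict* d = get_dict(xp);
  Mol m = mol_from_R(mol);
  FamResult r;
  familiarity_core(*d, m, details, r);
  return fam_to_R(r, details);
}

static double tanimoto_dist(const std::vector<int>& fp, const IntegerVector& root_fp) {
  size_t i = 0, j = 0, inter = 0;
  while (i < fp.size() && j < (size_t)root_fp.size()) {
    if (fp[i] == root_fp[j]) { ++inter; ++i; ++j; }
    else if (fp[i] < root_fp[j]) ++i;
    else ++j;
  }
  size_t uni = fp.size() + root_fp.size() - inter;
  return (uni == 0) ? 0.0 : 1.0 - (double)inter / (double)uni;
}

// ---------------------------------------------------------------------------
// In-place helpers for the search-tree bookkeeping. R's copy-on-modify would
// duplicate whole per-vertex arrays on every insert; these write through.
// The vectors are package-internal and never shared.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
void cpp_set_real(NumericVector v, int i, double x) { v[i - 1] = x; }

// [[Rcpp::export]]
void cpp_set_int(IntegerVector v, int i, int x) { v[i - 1] = x; }

// [[Rcpp::export]]
void cpp_set_lgl(LogicalVector v, int i, bool x) { v[i - 1] = x; }

// [[Rcpp::export]]
void cpp_add_real(NumericVector v, int i, double x) { v[i - 1] += x; }

// [[Rcpp::export]]
void cpp_add_int(IntegerVector v, int i, int x) { v[i - 1] += x; }

// write all per-vertex scalars of a new tree vertex in one call
// [[Rcpp::export]]
void cpp_vertex_init(IntegerVector parent, IntegerVector depth,
                     NumericVector f1, NumericVector f2, NumericVector droot,
                     IntegerVector nv, LogicalVector fully,
                     LogicalVector subtree_elig,
                     NumericVector child_sum, IntegerVector child_cnt,
                     int id, int par, int dep, double f1v, double f2v,
                     double droot_v, bool elig) {
  int i = id - 1;
  parent[i] = par;
  depth[i] = dep;
  f1[i] = f1v;
  f2[i] = f2v;
  droot[i] = droot_v;
  nv[i] = 0;
  fully[i] = false;
  subtree_elig[i] = elig;
  child_sum[i] = 0.0;
  child_cnt[i] = 0;
  if (par > 0) {
    child_sum[par - 1] += f1v;
    child_cnt[par - 1] += 1;
  }
}

// push (key, id) onto the heap (arrays must have capacity >= n) and sift up
// [[Rcpp::export]]
void cpp_heap_insert(NumericVector k, IntegerVector id, int n, double key, int vid) {
  k[n - 1] = key;
  id[n - 1] = vid;
  int i = n;
  while (i > 1) {
    int p = i / 2;
    bool less = k[i - 1] < k[p - 1] ||
      (k[i - 1] == k[p - 1] && id[i - 1] < id[p - 1]);
    if (!less) break;
    std::swap(k[i - 1], k[p - 1]);
    std::swap(id[i - 1], id[p - 1]);
    i = p;
  }
}

// canonical bond-key strings for batches of (possibly modified) endpoint
// keys; endpoint order is normalized here
// [[Rcpp::export]]
CharacterVector cpp_bond_key_strs(IntegerMatrix k1, IntegerMatrix k2,
                                  IntegerVector order) {
  int n = k1.nrow();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    AtomKey a, b;
    for (int j = 0; j < 5; ++j) { a[j] = k1(i, j); b[j] = k2(i, j); }
    std::string bs, pbs;
    canon_bond(a, b, order[i], bs, pbs);
    out[i] = bs;
  }
  return out;
}

// UCB1-guided descent from the root: walk toward the child maximizing
// children-mean f1 + c*sqrt(ln N_v / n_v) (unexpanded children first)
// until an eligible vertex is reached; marks dead subtrees on the way.
// Returns 0 when the whole tree is exhausted.
// [[Rcpp::export]]
int cpp_uct_select(Environment children, LogicalVector subtree_elig,
                   IntegerVector parent, IntegerVector depth,
                   NumericVector f1, IntegerVector nv, LogicalVector fully,
                   NumericVector child_sum, IntegerVector child_cnt,
                   int depth_limit, double uct_c) {
  int v = 1;
  for (;;) {
    int i = v - 1;
    if (!fully[i] && f1[i] < 1.0 && depth[i] < depth_limit) return v;
    std::string key = std::to_string(v);
    IntegerVector kids;
    if (children.exists(key)) kids = children.get(key);
    int best = 0;
    double best_ucb = -1e300;
    bool best_inf = false;
    double logN = (nv[i] > 0) ? std::log((double)nv[i]) : 0.0;
    for (int k = 0; k < kids.size(); ++k) {
      int c = kids[k];
      if (!subtree_elig[c - 1]) continue;
      if (nv[c - 1] == 0) {
        if (!best_inf) { best = c; best_inf = true; }
        continue;
      }
      if (best_inf) continue;
      double mean = (child_cnt[c - 1] > 0)
        ? child_sum[c - 1] / child_cnt[c - 1] : f1[c - 1];
      double ucb = mean + uct_c * std::sqrt(logN / nv[c - 1]);
      if (best == 0 || ucb > best_ucb) { best = c; best_ucb = ucb; }
    }
    if (best == 0) {
      subtree_elig[i] = false;
      v = parent[i];
      if (v == 0) return 0;
      continue;
    }
    v = best;
  }
}

// sift entry i up in a binary min-heap on (key, id)
// [[Rcpp::export]]
void cpp_heap_up(NumericVector k, IntegerVector id, int i) {
  while (i > 1) {
    int p = i / 2;
    bool less = k[i - 1] < k[p - 1] ||
      (k[i - 1] == k[p - 1] && id[i - 1] < id[p - 1]);
    if (!less) break;
    std::swap(k[i - 1], k[p - 1]);
    std::swap(id[i - 1], id[p - 1]);
    i = p;
  }
}

// sift the root down in a heap of size n
// [[Rcpp::export]]
void cpp_heap_down(NumericVector k, IntegerVector id, int n) {
  int i = 1;
  for (;;) {
    int l = 2 * i, r = l + 1, s = i;
    if (l <= n && (k[l - 1] < k[s - 1] ||
                   (k[l - 1] == k[s - 1] && id[l - 1] < id[s - 1]))) s = l;
    if (r <= n && (k[r - 1] < k[s - 1] ||
                   (k[r - 1] == k[s - 1] && id[r - 1] < id[s - 1]))) s = r;
    if (s == i) break;
    std::swap(k[i - 1], k[s - 1]);
    std::swap(id[i - 1], id[s - 1]);
    i = s;
  }
}

// Diagnose the most significant foreign key of a molecule.
// culprit codes: 1 D, 2 V, 3 Z, 4 Q, 5 H, 6 AK-pair, 7 B, 8 environment.
// [[Rcpp::export]]
List cpp_diagnose(SEXP xp, List mol) {
  ChemDict* d = get_dict(xp);
  Mol m = mol_from_R(mol);
  long long t = d->threshold;
  FamResult r;
  familiarity_core(*d, m, true, r);
  int n = m.n(), nb = m.m();

  // atom ladder: smallest foreign level wins; ties by rarest foreign
  // prefix, then lowest index
  int best_lev = 99, best_atom = -1;
  double best_freq = 0;
  for (int i = 0; i < n; ++i) {
    int lev = r.atom_level[i];
    if (lev == 0) continue;
    double freq = r.prefix_counts(i, lev - 1);
    if (lev < best_lev || (lev == best_lev && freq < best_freq)) {
      best_lev = lev; best_atom = i; best_freq = freq;
    }
  }
  // bond ladder (only when both endpoint atom keys are familiar)
  int best_blev = 99, best_bond = -1;
  double best_bfreq = 0;
  for (int k = 0; k < nb; ++k) {
    if (r.atom_level[m.bonds[k][0]] != 0 || r.atom_level[m.bonds[k][1]] != 0)
      continue;
    int lev = 0;
    double freq = 0;
    if (r.pb_count[k] <= t) { lev = 6; freq = r.pb_count[k]; }
    else if (r.b_count[k] <= t) { lev = 7; freq = r.b_count[k]; }
    else continue;
    if (lev < best_blev || (lev == best_blev && freq < best_bfreq)) {
      best_blev = lev; best_bond = k; best_bfreq = freq;
    }
  }
  auto prefix_of = [&](int atom, int len) {
    std::vector<AtomKey> ak = atom_keys(m);
    return key_prefix_str(ak[atom], len);
  };
  if (best_lev <= 5 || best_blev <= 7) {
    if (best_lev <= 5 && best_lev <= best_blev) {
      return List::create(_["type"] = 1, _["a"] = best_atom + 1, _["b"] = 0,
                          _["culprit"] = best_lev,
                          _["foreign"] = prefix_of(best_atom, best_lev),
                          _["predecessor"] = (best_lev > 1)
                            ? prefix_of(best_atom, best_lev - 1) : std::string(""));
    }
    int a = m.bonds[best_bond][0] + 1, b = m.bonds[best_bond][1] + 1;
    if (best_blev == 6)
      return List::create(_["type"] = 2, _["a"] = a, _["b"] = b,
                          _["culprit"] = 6,
                          _["foreign"] = r.pbond_strs[best_bond],
                          _["predecessor"] = std::string(""));
    return List::create(_["type"] = 2, _["a"] = a, _["b"] = b,
                        _["culprit"] = 7,
                        _["foreign"] = r.bond_strs[best_bond],
                        _["predecessor"] = r.pbond_strs[best_bond]);
  }

  // environment-only defects: maximal foreign-environment membership,
  // ties by rarest key, atoms before bonds, then lowest index
  std::vector<int> amemb(n, 0), bmemb(nb, 0);
  for (int e = 0; e < n; ++e) {
    if (r.env_familiar[e]) continue;
    std::vector<char> in_env(n, 0);
    for (int a : r.members[e]) { amemb[a] += 1; in_env[a] = 1; }
    for (int k = 0; k < nb; ++k)
      if (in_env[m.bonds[k][0]] && in_env[m.bonds[k][1]]) bmemb[k] += 1;
  }
  int pick = -1, pick_type = 0, pick_memb = -1;
  double pick_freq = 0;
  for (int i = 0; i < n; ++i) {
    if (amemb[i] == 0) continue;
    auto it = d->tab[0].find(r.atom_key_strs[i]);
    double freq = (it == d->tab[0].end()) ? 0.0 : (double)it->second;
    if (amemb[i] > pick_memb || (amemb[i] == pick_memb && freq < pick_freq)) {
      pick = i; pick_type = 1; pick_memb = amemb[i]; pick_freq = freq;
    }
  }
  for (int k = 0; k < nb; ++k) {
    if (bmemb[k] == 0) continue;
    double freq = r.b_count[k];
    if (bmemb[k] > pick_memb || (bmemb[k] == pick_memb && freq < pick_freq)) {
      pick = k; pick_type = 2; pick_memb = bmemb[k]; pick_freq = freq;
    }
  }
  if (pick < 0) stop("molecule is fully familiar; nothing to diagnose");
  if (pick_type == 1)
    return List::create(_["type"] = 1, _["a"] = pick + 1, _["b"] = 0,
                        _["culprit"] = 8, _["foreign"] = r.env_strs[pick],
                        _["predecessor"] = R_NilValue);
  return List::create(_["type"] = 2, _["a"] = m.bonds[pick][0] + 1,
                      _["b"] = m.bonds[pick][1] + 1,
                      _["culprit"] = 8, _["foreign"] = R_NilValue,
                      _["predecessor"] = R_NilValue);
}

// fused scoring for the search hot path: familiarity + fingerprint + distance
// [[Rcpp::export]]
List cpp_score_mol(SEXP xp, List mol, IntegerVector root_fp) {
  ChemDict* d = get_dict(xp);
  Mol m = mol_from_R(mol);
  FamResult r;
  familiarity_core(*d, m, false, r);
  std::vector<int> fp = fingerprint_bits(m, 2, 2048);
  List out = fam_to_R(r, false);
  out["fp"] = IntegerVector(fp.begin(), fp.end());
  out["d_root"] = tanimoto_dist(fp, root_fp);
  return out;
}

// fused expansion step: apply the candidate edit (+ optional sanitization),
// then compute graph hash, familiarity, fingerprint and distance to the
// root in one pass over a shared set of Morgan invariants
// [[Rcpp::export]]
List cpp_child_eval(List mol, IntegerVector cand, bool sanitize, SEXP xp,
                    IntegerVector root_fp) {
  ChemDict* d = get_dict(xp);
  Mol parent = mol_from_R(mol);
  std::vector<int> c(cand.begin(), cand.end());
  if (c.size() != 7) stop("candidate must have 7 fields");
  Mol m = apply_cand(parent, c.data(), sanitize);
  int n = m.n();
  int R = std::max(2, d->radius);
  std::vector<std::vector<uint64_t>> inv = morgan_rounds(m, R);
  FamResult r;
  familiarity_core(*d, m, false, r, &inv[d->radius]);
  std::vector<int> fp;
  for (int rad = 0; rad <= 2; ++rad)
    for (int i = 0; i < n; ++i)
      fp.push_back((int)(inv[rad][i] % 2048ULL));
  std::sort(fp.begin(), fp.end());
  fp.erase(std::unique(fp.begin(), fp.end()), fp.end());
  List out = fam_to_R(r, false);
  out["mol"] = mol_to_R(m);
  out["ghash"] = graph_hash_core(m);
  out["fp"] = IntegerVector(fp.begin(), fp.end());
  out["d_root"] = tanimoto_dist(fp, root_fp);
  return out;
}
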