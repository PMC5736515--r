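// Core molecular-graph engine: canonical labelling, subgraph matching and
// bond-rearrangement rule application. Molecules are small vertex-labelled
// multigraphs (atomic number, formal charge, integer bond orders 1..3) held
// in dense adjacency form; all graphs handled here are far below the n = 250
// guard, so exact (backtracking) canonicalization is affordable.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <map>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct Graph {
  int n = 0;
  std::vector<int> elem;          // atomic number (1 = H)
  std::vector<int> chg;           // formal charge
  std::vector<uint8_t> B;         // n x n bond orders

  uint8_t get(int i, int j) const { return B[(size_t)i * n + j]; }
  void set(int i, int j, uint8_t v) {
    B[(size_t)i * n + j] = v;
    B[(size_t)j * n + i] = v;
  }
  int valence(int i) const {
    int s = 0;
    for (int j = 0; j < n; ++j) s += get(i, j);
    return s;
  }
};

Graph graph_from_r(const IntegerVector& elem, const IntegerVector& chg,
                   const IntegerMatrix& bond) {
  Graph g;
  g.n = elem.size();
  if (g.n > 250) stop("graph engine supports at most 250 atoms");
  g.elem.assign(elem.begin(), elem.end());
  g.chg.assign(chg.begin(), chg.end());
  g.B.assign((size_t)g.n * g.n, 0);
  for (int r = 0; r < bond.nrow(); ++r) {
    int i = bond(r, 0) - 1, j = bond(r, 1) - 1, o = bond(r, 2);
    if (i < 0 || j < 0 || i >= g.n || j >= g.n || i == j)
      stop("bond table refers to invalid atom index");
    if (o < 1 || o > 3) stop("bond order must be in 1..3");
    g.set(i, j, (uint8_t)o);
  }
  return g;
}

List graph_to_r(const Graph& g) {
  IntegerVector elem(g.n), chg(g.n);
  std::vector<int> bi, bj, bo;
  for (int i = 0; i < g.n; ++i) {
    elem[i] = g.elem[i];
    chg[i] = g.chg[i];
    for (int j = i + 1; j < g.n; ++j)
      if (g.get(i, j)) {
        bi.push_back(i + 1);
        bj.push_back(j + 1);
        bo.push_back(g.get(i, j));
      }
  }
  IntegerMatrix bond(bi.size(), 3);
  for (size_t r = 0; r < bi.size(); ++r) {
    bond(r, 0) = bi[r];
    bond(r, 1) = bj[r];
    bond(r, 2) = bo[r];
  }
  return List::create(_["elem"] = elem, _["charge"] = chg, _["bond"] = bond);
}

// Default valences used when saturating free sites with implicit hydrogens.
int default_valence(int z) {
  switch (z) {
    case 1: return 1;   // H
    case 5: return 3;   // B
    case 6: return 4;   // C
    case 7: return 3;   // N
    case 8: return 2;   // O
    case 9: return 1;   // F
    case 14: return 4;  // Si
    case 15: return 3;  // P
    case 16: return 2;  // S
    case 17: return 1;  // Cl
    case 35: return 1;  // Br
    case 53: return 1;  // I
    default: return 0;
  }
}

int implicit_h_count(const Graph& g, int i) {
  int dv = default_valence(g.elem[i]);
  if (dv == 0) return 0;
  int z = g.elem[i], c = g.chg[i];
  // standard SMILES implicit-valence adjustments
  if (z == 7 || z == 8 || z == 15 || z == 16) dv += c;        // N,O,P,S
  else if (z == 6) dv -= (c < 0 ? -c : c);                    // C
  else if (z == 5) dv -= c;                                   // B
  else if (c != 0) return 0;                                  // charged halogen etc.
  int h = dv - g.valence(i);
  return h > 0 ? h : 0;
}

Graph with_implicit_h(const Graph& g) {
  std::vector<int> hcount(g.n);
  int extra = 0;
  for (int i = 0; i < g.n; ++i) {
    hcount[i] = implicit_h_count(g, i);
    extra += hcount[i];
  }
  if (extra == 0) return g;
  Graph h;
  h.n = g.n + extra;
  h.elem = g.elem;
  h.chg = g.chg;
  h.elem.resize(h.n, 1);
  h.chg.resize(h.n, 0);
  h.B.assign((size_t)h.n * h.n, 0);
  for (int i = 0; i < g.n; ++i)
    for (int j = i + 1; j < g.n; ++j)
      if (g.get(i, j)) h.set(i, j, g.get(i, j));
  int k = g.n;
  for (int i = 0; i < g.n; ++i)
    for (int c = 0; c < hcount[i]; ++c) h.set(i, k++, 1);
  return h;
}

// ---- connectivity -------------------------------------------------------

std::vector<int> components(const Graph& g) {
  std::vector<int> comp(g.n, -1);
  int c = 0;
  std::vector<int> stack;
  for (int s = 0; s < g.n; ++s) {
    if (comp[s] >= 0) continue;
    stack.push_back(s);
    comp[s] = c;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      for (int u = 0; u < g.n; ++u)
        if (g.get(v, u) && comp[u] < 0) {
          comp[u] = c;
          stack.push_back(u);
        }
    }
    ++c;
  }
  return comp;
}

int n_components(const Graph& g) {
  if (g.n == 0) return 0;
  std::vector<int> comp = components(g);
  return *std::max_element(comp.begin(), comp.end()) + 1;
}

// ---- structural filters -------------------------------------------------

// max_valence > 0: uniform cap on per-atom total bond order.
// max_valence == 0: element-default cap (charge adjusted), unknown elements free.
bool valence_ok(const Graph& g, int max_valence) {
  for (int i = 0; i < g.n; ++i) {
    int v = g.valence(i);
    if (max_valence > 0) {
      if (v > max_valence) return false;
    } else if (max_valence == 0) {
      int dv = default_valence(g.elem[i]);
      if (dv > 0 && g.chg[i] == 0 && v > dv + 2) return false;  // generous cap
    }
  }
  return true;
}

// No atom may carry two double bonds while sitting in a 3- or 4-membered ring.
bool ring_double_ok(const Graph& g) {
  for (int v = 0; v < g.n; ++v) {
    int ndouble = 0;
    for (int u = 0; u < g.n; ++u)
      if (g.get(v, u) == 2) ++ndouble;
    if (ndouble < 2) continue;
    // is v in a ring of size 3 or 4?
    std::vector<int> nb;
    for (int u = 0; u < g.n; ++u)
      if (g.get(v, u)) nb.push_back(u);
    for (size_t a = 0; a < nb.size(); ++a)
      for (size_t b = a + 1; b < nb.size(); ++b) {
        if (g.get(nb[a], nb[b])) return false;  // 3-ring
        for (int x = 0; x < g.n; ++x)
          if (x != v && g.get(nb[a], x) && g.get(nb[b], x)) return false;  // 4-ring
      }
  }
  return true;
}

// ---- canonical labelling ------------------------------------------------
// Colour refinement plus full individualization backtracking; the returned
// byte string is identical for isomorphic graphs and distinct otherwise.

int count_classes(const std::vector<int>& col) {
  std::set<int> s(col.begin(), col.end());
  return (int)s.size();
}

void refine(const Graph& g, std::vector<int>& col) {
  int n = g.n;
  int classes = count_classes(col);
  while (classes < n) {
    std::vector<std::pair<std::vector<long long>, int>> sig(n);
    for (int v = 0; v < n; ++v) {
      std::vector<long long> x;
      x.push_back(col[v]);
      std::vector<long long> nb;
      for (int u = 0; u < n; ++u) {
        int o = g.get(v, u);
        if (o) nb.push_back((long long)o * 1000000 + col[u]);
      }
      std::sort(nb.begin(), nb.end());
      x.insert(x.end(), nb.begin(), nb.end());
      sig[v] = {std::move(x), v};
    }
    std::vector<std::pair<std::vector<long long>, int>> srt = sig;
    std::sort(srt.begin(), srt.end());
    std::vector<int> ncol(n);
    int rank = 0;
    for (int k = 0; k < n; ++k) {
      if (k > 0 && srt[k].first != srt[k - 1].first) ++rank;
      ncol[srt[k].second] = rank;
    }
    int nclasses = rank + 1;
    col.swap(ncol);
    if (nclasses == classes) break;  // stable partition
    classes = nclasses;
  }
}

std::string code_from_discrete(const Graph& g, const std::vector<int>& col,
                               const std::vector<int>& aux) {
  int n = g.n;
  // colours are distinct but not necessarily 0..n-1: order vertices by colour
  std::vector<std::pair<int, int>> byc(n);
  for (int v = 0; v < n; ++v) byc[v] = {col[v], v};
  std::sort(byc.begin(), byc.end());
  std::vector<int> pos(n);  // canonical position -> vertex
  for (int p = 0; p < n; ++p) pos[p] = byc[p].second;
  std::string code;
  code.reserve(3 * n + 8);
  code.push_back((char)(unsigned char)n);
  for (int p = 0; p < n; ++p) {
    int v = pos[p];
    code.push_back((char)(unsigned char)g.elem[v]);
    code.push_back((char)(unsigned char)(g.chg[v] + 64));
    code.push_back((char)(unsigned char)aux[v]);
  }
  for (int p = 0; p < n; ++p)
    for (int q = p + 1; q < n; ++q) {
      int o = g.get(pos[p], pos[q]);
      if (o) {
        code.push_back((char)(unsigned char)p);
        code.push_back((char)(unsigned char)q);
        code.push_back((char)(unsigned char)o);
      }
    }
  return code;
}

std::string canon_search(const Graph& g, std::vector<int> col,
                         const std::vector<int>& aux) {
  refine(g, col);
  int n = g.n;
  // locate smallest non-singleton colour class (ties: smallest colour id)
  std::map<int, int> size;
  for (int v = 0; v < n; ++v) size[col[v]]++;
  int target = -1, tsize = n + 1;
  for (auto& kv : size)
    if (kv.second > 1 && kv.second < tsize) {
      target = kv.first;
      tsize = kv.second;
    }
  if (target < 0) return code_from_discrete(g, col, aux);
  std::string best;
  for (int v = 0; v < n; ++v) {
    if (col[v] != target) continue;
    std::vector<int> col2(n);
    for (int w = 0; w < n; ++w) col2[w] = 2 * col[w] + (w == v ? 1 : 0);
    std::string s = canon_search(g, std::move(col2), aux);
    if (best.empty() || s < best) best = s;
  }
  return best;
}

// aux: extra per-vertex invariant (e.g. folded hydrogen count) included in
// both the initial colouring and the emitted code.
std::string canon_code(const Graph& g, const std::vector<int>& aux) {
  if (g.n == 0) return std::string();
  typedef std::pair<std::pair<int, int>, std::pair<int, int>> Init;
  std::vector<Init> srt(g.n);
  for (int v = 0; v < g.n; ++v)
    srt[v] = {{g.elem[v], g.chg[v]}, {aux[v], v}};
  std::sort(srt.begin(), srt.end());
  std::vector<int> col(g.n);
  int rank = 0;
  for (int k = 0; k < g.n; ++k) {
    if (k > 0 && (srt[k].first != srt[k - 1].first ||
                  srt[k].second.first != srt[k - 1].second.first))
      ++rank;
    col[srt[k].second.second] = rank;
  }
  return canon_search(g, col, aux);
}

std::string hex_encode(const std::string& raw) {
  static const char* d = "0123456789abcdef";
  std::string out;
  out.reserve(raw.size() * 2);
  for (unsigned char c : raw) {
    out.push_back(d[c >> 4]);
    out.push_back(d[c & 15]);
  }
  return out;
}

// Connectivity-level key. Terminal hydrogens (neutral, one single bond to a
// heavy atom) are folded into their neighbour's colour, implicit hydrogens
// are added to the same count (charge-aware), and the formal-charge layer is
// then dropped: the key depends on atoms, bonds and hydrogen counts only --
// no stereo, no charge layer. Folding keeps the canonical search off the
// large symmetric hydrogen cells of saturated molecules.
std::string molecule_key(const Graph& g, bool fill_h) {
  std::vector<char> fold(g.n, 0);
  std::vector<int> hcnt(g.n, 0);
  for (int v = 0; v < g.n; ++v) {
    if (g.elem[v] != 1 || g.chg[v] != 0) continue;
    int nb = -1, deg = 0, osum = 0;
    for (int u = 0; u < g.n; ++u)
      if (g.get(v, u)) {
        ++deg;
        osum += g.get(v, u);
        nb = u;
      }
    if (deg == 1 && osum == 1 && g.elem[nb] != 1) {
      fold[v] = 1;
      hcnt[nb] += 1;
    }
  }
  std::vector<int> keep;
  for (int v = 0; v < g.n; ++v)
    if (!fold[v]) keep.push_back(v);
  Graph h;
  h.n = (int)keep.size();
  h.B.assign((size_t)h.n * h.n, 0);
  std::vector<int> aux(h.n, 0);
  for (int a = 0; a < h.n; ++a) {
    h.elem.push_back(g.elem[keep[a]]);
    h.chg.push_back(0);
    aux[a] = hcnt[keep[a]];
  }
  for (int a = 0; a < h.n; ++a)
    for (int b = a + 1; b < h.n; ++b)
      if (g.get(keep[a], keep[b])) h.set(a, b, g.get(keep[a], keep[b]));
  if (fill_h)
    for (int a = 0; a < h.n; ++a) aux[a] += implicit_h_count(g, keep[a]);
  return hex_encode(canon_code(h, aux));
}

// ---- pattern matching ---------------------------------------------------

struct Pattern {
  int p = 0;
  std::vector<int> elem;              // 0 = wildcard
  std::vector<int> chg;               // charge constraint
  std::vector<uint8_t> chg_fixed;     // 1 if charge constrained
  std::vector<int> bond;              // p x p: -1 any, 0 must be absent, 1..3 order
  int b(int i, int j) const { return bond[(size_t)i * p + j]; }
};

struct MatchContext {
  const Graph* g;
  const Pattern* pat;
  const std::vector<int>* mol_id;  // per molecule-slot ids (1-based), or null
  const std::vector<int>* req_mol = nullptr;  // required molecule per pattern atom (0 = free)
  int n_mols = 1;
  bool span_all = false;
  std::vector<int> order;          // pattern-atom visit order
  std::vector<int> anchor;         // for each order position, earlier pattern
                                   // atom bonded (order>=1) to it, or -1
  std::vector<int> assign;         // pattern atom -> graph atom
  std::vector<char> used;
  std::vector<std::vector<int>> embeddings;
  size_t max_embeddings = 2000000;
};

bool atom_compatible(const MatchContext& C, int pa, int v) {
  const Pattern& P = *C.pat;
  const Graph& G = *C.g;
  if (P.elem[pa] != 0 && P.elem[pa] != G.elem[v]) return false;
  if (P.chg_fixed[pa] && P.chg[pa] != G.chg[v]) return false;
  if (C.req_mol && (*C.req_mol)[pa] > 0 && C.mol_id &&
      (*C.mol_id)[v] != (*C.req_mol)[pa])
    return false;
  return true;
}

bool bonds_compatible(const MatchContext& C, int pa, int v) {
  const Pattern& P = *C.pat;
  const Graph& G = *C.g;
  for (int q = 0; q < P.p; ++q) {
    if (C.assign[q] < 0 || q == pa) continue;
    int want = P.b(pa, q);
    if (want < 0) continue;
    if ((int)G.get(v, C.assign[q]) != want) return false;
  }
  return true;
}

void backtrack(MatchContext& C, size_t pos) {
  if (C.embeddings.size() >= C.max_embeddings)
    stop("embedding enumeration exceeded limit");
  const Pattern& P = *C.pat;
  const Graph& G = *C.g;
  if (pos == C.order.size()) {
    if (C.span_all && C.mol_id) {
      std::vector<char> seen(C.n_mols + 1, 0);
      for (int q = 0; q < P.p; ++q) seen[(*C.mol_id)[C.assign[q]]] = 1;
      for (int m = 1; m <= C.n_mols; ++m)
        if (!seen[m]) return;
    }
    C.embeddings.push_back(C.assign);
    return;
  }
  int pa = C.order[pos];
  int anc = C.anchor[pos];
  if (anc >= 0) {
    int av = C.assign[anc];
    int want = P.b(pa, anc);
    for (int v = 0; v < G.n; ++v) {
      if (C.used[v] || (int)G.get(av, v) != want) continue;
      if (!atom_compatible(C, pa, v) || !bonds_compatible(C, pa, v)) continue;
      C.assign[pa] = v;
      C.used[v] = 1;
      backtrack(C, pos + 1);
      C.used[v] = 0;
      C.assign[pa] = -1;
    }
  } else {
    for (int v = 0; v < G.n; ++v) {
      if (C.used[v]) continue;
      if (!atom_compatible(C, pa, v) || !bonds_compatible(C, pa, v)) continue;
      C.assign[pa] = v;
      C.used[v] = 1;
      backtrack(C, pos + 1);
      C.used[v] = 0;
      C.assign[pa] = -1;
    }
  }
}

void plan_order(const Pattern& P, std::vector<int>& order, std::vector<int>& anchor) {
  int p = P.p;
  std::vector<char> placed(p, 0);
  order.clear();
  anchor.clear();
  for (int step = 0; step < p; ++step) {
    int best = -1, best_anchor = -1, best_score = -1;
    for (int a = 0; a < p; ++a) {
      if (placed[a]) continue;
      int anc = -1, score = 0;
      for (int q = 0; q < p; ++q) {
        if (!placed[q]) continue;
        int o = P.b(a, q);
        if (o >= 1 && anc < 0) anc = q;
        if (o >= 0) ++score;  // any fixed constraint helps pruning
      }
      if (anc >= 0) score += 100;
      if (P.elem[a] != 0) score += 1;
      if (score > best_score) {
        best_score = score;
        best = a;
        best_anchor = anc;
      }
    }
    order.push_back(best);
    anchor.push_back(best_anchor);
    placed[best] = 1;
  }
}

Pattern pattern_from_r(const IntegerVector& pelem, const IntegerVector& pchg,
                       const LogicalVector& pchg_fixed, const IntegerMatrix& pbond) {
  Pattern P;
  P.p = pelem.size();
  P.elem.assign(pelem.begin(), pelem.end());
  P.chg.assign(pchg.begin(), pchg.end());
  P.chg_fixed.resize(P.p);
  for (int i = 0; i < P.p; ++i) P.chg_fixed[i] = pchg_fixed[i] ? 1 : 0;
  P.bond.assign((size_t)P.p * P.p, -1);
  for (int i = 0; i < P.p; ++i)
    for (int j = 0; j < P.p; ++j) P.bond[(size_t)i * P.p + j] = pbond(i, j);
  return P;
}

}  // namespace

// [[Rcpp::export]]
std::string rxr_canon_key(IntegerVector elem, IntegerVector chg, IntegerMatrix bond,
                          bool fill_h = true) {
  Graph g = graph_from_r(elem, chg, bond);
  return molecule_key(g, fill_h);
}

// [[Rcpp::export]]
IntegerVector rxr_components(IntegerVector elem, IntegerVector chg, IntegerMatrix bond) {
  Graph g = graph_from_r(elem, chg, bond);
  std::vector<int> comp = components(g);
  IntegerVector out(g.n);
  for (int i = 0; i < g.n; ++i) out[i] = comp[i] + 1;
  return out;
}

// [[Rcpp::export]]
IntegerVector rxr_implicit_h(IntegerVector elem, IntegerVector chg, IntegerMatrix bond) {
  Graph g = graph_from_r(elem, chg, bond);
  IntegerVector out(g.n);
  for (int i = 0; i < g.n; ++i) out[i] = implicit_h_count(g, i);
  return out;
}

// [[Rcpp::export]]
List rxr_sanitize_flags(IntegerVector elem, IntegerVector chg, IntegerMatrix bond,
                        int max_valence = 4) {
  Graph g = graph_from_r(elem, chg, bond);
  return List::create(_["connected"] = n_components(g) <= 1,
                      _["valence_ok"] = valence_ok(g, max_valence),
                      _["ring_ok"] = ring_double_ok(g));
}

// [[Rcpp::export]]
IntegerMatrix rxr_distances(IntegerVector elem, IntegerVector chg, IntegerMatrix bond) {
  Graph g = graph_from_r(elem, chg, bond);
  int n = g.n;
  IntegerMatrix D(n, n);
  std::fill(D.begin(), D.end(), NA_INTEGER);
  std::vector<int> q;
  for (int s = 0; s < n; ++s) {
    std::vector<int> dist(n, -1);
    dist[s] = 0;
    q.clear();
    q.push_back(s);
    for (size_t h = 0; h < q.size(); ++h) {
      int v = q[h];
      for (int u = 0; u < n; ++u)
        if (g.get(v, u) && dist[u] < 0) {
          dist[u] = dist[v] + 1;
          q.push_back(u);
        }
    }
    for (int t = 0; t < n; ++t)
      if (dist[t] >= 0) D(s, t) = dist[t];
  }
  return D;
}

// Apply a compiled rule to the (possibly multi-molecule) reactant graph.
//
// elem/chg/bond:   union reactant graph; mol_id marks which input molecule
//                  each atom belongs to (1-based).
// pattern:         pelem (0 = wildcard), pchg/pchg_fixed, pbond constraints.
// edits:           rows (pi, pj, new_order): bond orders rewritten between
//                  mapped pattern atoms (1-based pattern indices).
// pdelete:         pattern atoms removed from the product.
// new_elem/...:    atoms created by the product side; new_bond rows
//                  (a, b, order) index pattern atoms 1..p and new atoms p+1..
// split_components: FALSE = the edited graph is a single product structure
//                  (unimolecular transformation semantics; disconnected
//                  products are rejected when connected_only). TRUE = each
//                  connected component of the edited graph becomes one
//                  product molecule of the tuple.
// max_valence:     >0 uniform cap, 0 element defaults, -1 skip check.
// [[Rcpp::export]]
List rxr_apply(IntegerVector elem, IntegerVector chg, IntegerMatrix bond,
               IntegerVector mol_id, int n_mols, bool span_all,
               IntegerVector req_mol,
               IntegerVector pelem, IntegerVector pchg, LogicalVector pchg_fixed,
               IntegerMatrix pbond, IntegerMatrix edits, LogicalVector pdelete,
               IntegerVector new_elem, IntegerVector new_chg, IntegerMatrix new_bond,
               bool split_components, bool connected_only, int max_valence,
               bool ring_rule, bool fill_h_key, bool count_only = false) {
  Graph g = graph_from_r(elem, chg, bond);
  Pattern P = pattern_from_r(pelem, pchg, pchg_fixed, pbond);
  std::vector<int> molid(mol_id.begin(), mol_id.end());
  std::vector<int> reqm(req_mol.begin(), req_mol.end());

  MatchContext C;
  C.g = &g;
  C.pat = &P;
  C.mol_id = molid.empty() ? nullptr : &molid;
  C.req_mol = reqm.empty() ? nullptr : &reqm;
  C.n_mols = n_mols;
  C.span_all = span_all && n_mols > 1;
  plan_order(P, C.order, C.anchor);
  C.assign.assign(P.p, -1);
  C.used.assign(g.n, 0);
  if (P.p <= g.n) backtrack(C, 0);

  int n_embed = (int)C.embeddings.size();
  if (count_only)
    return List::create(_["n_embeddings"] = n_embed);

  // deduplicate embeddings by the labelled set of bond changes
  int nq = new_elem.size();
  std::set<std::vector<int>> edit_sigs;
  std::map<std::string, List> tuples;
  int rej_disc = 0, rej_val = 0, rej_ring = 0, degenerate = 0;

  for (const std::vector<int>& emb : C.embeddings) {
    std::vector<int> sig;
    for (int r = 0; r < edits.nrow(); ++r) {
      int i = emb[edits(r, 0) - 1], j = emb[edits(r, 1) - 1], o = edits(r, 2);
      if ((int)g.get(i, j) == o) continue;  // no-op on this embedding
      int a = std::min(i, j), b = std::max(i, j);
      sig.push_back(a * 100000 + b * 100 + o);
    }
    bool any_delete = false;
    for (int q = 0; q < P.p; ++q)
      if (pdelete[q]) {
        any_delete = true;
        sig.push_back(-(emb[q] + 1));
      }
    // attachment points of created atoms are part of the labelled signature
    for (int r = 0; r < new_bond.nrow(); ++r)
      if (new_bond(r, 0) <= P.p)
        sig.push_back(1000000000 + emb[new_bond(r, 0) - 1] * 1000 +
                      new_bond(r, 1) * 10 + new_bond(r, 2));
    if (sig.empty() && nq == 0) {
      ++degenerate;  // embedding changes nothing
      continue;
    }
    std::sort(sig.begin(), sig.end());
    if (!edit_sigs.insert(sig).second) continue;

    // build edited graph
    Graph h;
    h.n = g.n + nq;
    h.elem = g.elem;
    h.chg = g.chg;
    h.elem.resize(h.n);
    h.chg.resize(h.n);
    for (int q = 0; q < nq; ++q) {
      h.elem[g.n + q] = new_elem[q];
      h.chg[g.n + q] = new_chg[q];
    }
    h.B.assign((size_t)h.n * h.n, 0);
    for (int i = 0; i < g.n; ++i)
      for (int j = i + 1; j < g.n; ++j)
        if (g.get(i, j)) h.set(i, j, g.get(i, j));
    for (int r = 0; r < edits.nrow(); ++r)
      h.set(emb[edits(r, 0) - 1], emb[edits(r, 1) - 1], (uint8_t)edits(r, 2));
    for (int r = 0; r < new_bond.nrow(); ++r) {
      int a = new_bond(r, 0), b = new_bond(r, 1), o = new_bond(r, 2);
      int va = (a <= P.p) ? emb[a - 1] : g.n + (a - P.p - 1);
      int vb = (b <= P.p) ? emb[b - 1] : g.n + (b - P.p - 1);
      h.set(va, vb, (uint8_t)o);
    }
    // drop deleted pattern atoms
    std::vector<int> keep;
    if (any_delete) {
      std::vector<char> del(h.n, 0);
      for (int q = 0; q < P.p; ++q)
        if (pdelete[q]) del[emb[q]] = 1;
      for (int v = 0; v < h.n; ++v)
        if (!del[v]) keep.push_back(v);
      Graph h2;
      h2.n = (int)keep.size();
      h2.B.assign((size_t)h2.n * h2.n, 0);
      for (int a2 = 0; a2 < h2.n; ++a2) {
        h2.elem.push_back(h.elem[keep[a2]]);
        h2.chg.push_back(h.chg[keep[a2]]);
      }
      for (int a2 = 0; a2 < h2.n; ++a2)
        for (int b2 = a2 + 1; b2 < h2.n; ++b2)
          if (h.get(keep[a2], keep[b2])) h2.set(a2, b2, h.get(keep[a2], keep[b2]));
      h = h2;
    }

    // split into product molecules
    std::vector<Graph> prods;
    if (!split_components) {
      if (connected_only && n_components(h) > 1) {
        ++rej_disc;
        continue;
      }
      prods.push_back(h);
    } else {
      std::vector<int> comp = components(h);
      int nc = h.n ? *std::max_element(comp.begin(), comp.end()) + 1 : 0;
      for (int c = 0; c < nc; ++c) {
        std::vector<int> idx;
        for (int v = 0; v < h.n; ++v)
          if (comp[v] == c) idx.push_back(v);
        Graph m;
        m.n = (int)idx.size();
        m.B.assign((size_t)m.n * m.n, 0);
        for (int a2 = 0; a2 < m.n; ++a2) {
          m.elem.push_back(h.elem[idx[a2]]);
          m.chg.push_back(h.chg[idx[a2]]);
        }
        for (int a2 = 0; a2 < m.n; ++a2)
          for (int b2 = a2 + 1; b2 < m.n; ++b2)
            if (h.get(idx[a2], idx[b2])) m.set(a2, b2, h.get(idx[a2], idx[b2]));
        prods.push_back(m);
      }
    }

    bool ok = true;
    for (const Graph& m : prods) {
      if (max_valence >= 0 && !valence_ok(m, max_valence)) {
        ++rej_val;
        ok = false;
        break;
      }
      if (ring_rule && !ring_double_ok(m)) {
        ++rej_ring;
        ok = false;
        break;
      }
    }
    if (!ok) continue;

    std::vector<std::string> keys;
    for (const Graph& m : prods) keys.push_back(molecule_key(m, fill_h_key));
    std::vector<size_t> ord(keys.size());
    for (size_t k = 0; k < ord.size(); ++k) ord[k] = k;
    std::sort(ord.begin(), ord.end(),
              [&](size_t a, size_t b) { return keys[a] < keys[b]; });
    std::string tkey;
    for (size_t k : ord) tkey += keys[k] + "|";
    if (tuples.count(tkey)) continue;

    List mols(prods.size());
    CharacterVector kv(prods.size());
    for (size_t k = 0; k < ord.size(); ++k) {
      mols[k] = graph_to_r(prods[ord[k]]);
      kv[k] = keys[ord[k]];
    }
    tuples[tkey] = List::create(_["molecules"] = mols, _["keys"] = kv);
    if ((int)tuples.size() > 500000) stop("product explosion: >500000 tuples");
  }

  List out(tuples.size());
  int k = 0;
  for (auto& kv : tuples) out[k++] = kv.second;
  return List::create(
      _["tuples"] = out,
      _["counts"] = IntegerVector::create(
          _["embeddings"] = n_embed, _["degenerate"] = degenerate,
          _["rejected_disconnected"] = rej_disc, _["rejected_valence"] = rej_val,
          _["rejected_ring"] = rej_ring, _["tuples"] = (int)tuples.size()));
}
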