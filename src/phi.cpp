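// Integrated information (IIT 3.0) for binary systems of 2-3 nodes.
//
// Conventions (fixed package-wide):
//  * states are little-endian bitmasks: node 1 is the least significant bit;
//  * the TPM is state-by-node: row s (0-based mask) gives p(node j on at the
//    next step | system state s), assuming conditional independence;
//  * repertoire distances use the earth mover's distance with Hamming ground
//    metric, solved exactly (effect repertoires are product distributions,
//    for which the EMD equals the L1 distance between node marginals);
//  * ties in MIP/purview searches break to the first candidate in a fixed
//    enumeration order (subsets ordered by size, then by mask).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <memory>
#include <string>

using namespace Rcpp;

namespace {

constexpr double EPS_PHI = 1e-10;  // phi at or below this counts as zero
constexpr double CMP_EPS = 1e-13;  // strict-improvement margin in searches

inline int popcnt(unsigned x) { return __builtin_popcount(x); }

// Index of full state s restricted to the nodes in mask (little-endian over
// the masked nodes in ascending order).
inline int compress_state(int s, int mask) {
  int r = 0, b = 0;
  for (int k = 0; mask >> k; ++k)
    if (mask & (1 << k)) { r |= ((s >> k) & 1) << b; ++b; }
  return r;
}

// Inverse of compress_state: place purview-index bits onto the mask's nodes.
inline int expand_state(int u, int mask) {
  int s = 0, b = 0;
  for (int k = 0; mask >> k; ++k)
    if (mask & (1 << k)) { s |= ((u >> b) & 1) << k; ++b; }
  return s;
}

// ---------------------------------------------------------------------------
// Exact transportation problem (successive shortest augmenting paths).
// Supplies a, demands b (equal totals up to rounding), cost matrix C.
double transport(std::vector<double> a, std::vector<double> b,
                 const std::vector<std::vector<double>>& C) {
  const int na = (int)a.size(), nb = (int)b.size();
  double total = 0.0;
  for (double v : a) total += v;
  if (total <= 1e-15) return 0.0;
  const double tol = 1e-12 * std::max(1.0, total);
  std::vector<std::vector<double>> f(na, std::vector<double>(nb, 0.0));
  const double INF = 1e300;
  int guard = 4 * na * nb + 64;
  while (guard-- > 0) {
    bool any_supply = false;
    for (int i = 0; i < na; ++i) if (a[i] > tol) { any_supply = true; break; }
    if (!any_supply) break;
    // Bellman-Ford over the bipartite residual graph; all residual supplies
    // act as a super-source at distance 0.
    const int V = na + nb;
    std::vector<double> dist(V, INF);
    std::vector<int> parent(V, -1);
    for (int i = 0; i < na; ++i) if (a[i] > tol) dist[i] = 0.0;
    for (int it = 0; it < V; ++it) {
      bool changed = false;
      for (int i = 0; i < na; ++i) {
        for (int j = 0; j < nb; ++j) {
          if (dist[i] < INF && dist[i] + C[i][j] < dist[na + j] - 1e-15) {
            dist[na + j] = dist[i] + C[i][j];
            parent[na + j] = i;
            changed = true;
          }
          if (f[i][j] > tol && dist[na + j] < INF &&
              dist[na + j] - C[i][j] < dist[i] - 1e-15) {
            dist[i] = dist[na + j] - C[i][j];
            parent[i] = na + j;
            changed = true;
          }
        }
      }
      if (!changed) break;
    }
    int jbest = -1;
    for (int j = 0; j < nb; ++j)
      if (b[j] > tol && dist[na + j] < INF &&
          (jbest < 0 || dist[na + j] < dist[na + jbest]))
        jbest = j;
    if (jbest < 0) break;
    // bottleneck along the augmenting path (walk back to the source supply)
    double delta = b[jbest];
    int cur = na + jbest;
    while (parent[cur] != -1) {
      int p = parent[cur];
      if (cur < na)  // reverse edge demand p -> supply cur, capacity f[cur][.]
        delta = std::min(delta, f[cur][p - na]);
      cur = p;
    }
    const int start = cur;  // supply node with dist 0
    delta = std::min(delta, a[start]);
    // augment
    cur = na + jbest;
    while (parent[cur] != -1) {
      int p = parent[cur];
      if (cur >= na) f[p][cur - na] += delta;
      else f[cur][p - na] -= delta;
      cur = p;
    }
    a[start] -= delta;
    b[jbest] -= delta;
  }
  double cost = 0.0;
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) cost += f[i][j] * C[i][j];
  return cost;
}

// EMD between two distributions over bit-states with Hamming ground metric.
// Only net surpluses/deficits need transporting.
double emd_hamming_states(const std::vector<double>& p,
                          const std::vector<double>& q) {
  const int S = (int)p.size();
  std::vector<double> a, b;
  std::vector<int> ia, ib;
  for (int s = 0; s < S; ++s) {
    double d = p[s] - q[s];
    if (d > 1e-14) { a.push_back(d); ia.push_back(s); }
    else if (d < -1e-14) { b.push_back(-d); ib.push_back(s); }
  }
  if (a.empty() || b.empty()) return 0.0;
  std::vector<std::vector<double>> C(a.size(), std::vector<double>(b.size()));
  for (size_t i = 0; i < a.size(); ++i)
    for (size_t j = 0; j < b.size(); ++j)
      C[i][j] = (double)popcnt((unsigned)(ia[i] ^ ib[j]));
  return transport(a, b, C);
}

// Total variation distance: a lower bound on the Hamming EMD (every unit of
// mass that moves travels distance >= 1), used to prune MIP candidates.
inline double total_variation(const std::vector<double>& p,
                              const std::vector<double>& q) {
  double s = 0.0;
  for (size_t k = 0; k < p.size(); ++k) s += std::fabs(p[k] - q[k]);
  return 0.5 * s;
}

// ---------------------------------------------------------------------------

struct Mice {
  int purview = 0;
  double phi = 0.0;
  std::vector<double> rep;   // repertoire over the core purview
  int m1 = 0, p1 = 0, m2 = 0, p2 = 0;  // minimum information partition
};

struct ConceptC {
  int mech = 0;
  double phi = 0.0, phi_cause = 0.0, phi_effect = 0.0;
  Mice cause, effect;
  std::vector<double> cause_full;  // cause repertoire expanded to all nodes
  std::vector<double> eff_marg;    // per-node on-marginals, expanded
};

struct Engine {
  int n = 0, S = 0, full = 0;
  std::vector<std::vector<double>> T;   // S x n state-by-node TPM
  std::vector<double> uq;               // unconstrained effect marginals
  std::vector<int> purview_order;       // non-empty subsets by (size, mask)
  int zero_cond = 0;                    // zero-probability conditioning events
  std::map<std::pair<int, int>, ConceptC> cache;
  std::map<int, std::unique_ptr<Engine>> cut_cache;
  ConceptC null_concept;

  void init(const std::vector<std::vector<double>>& tpm) {
    T = tpm;
    S = (int)T.size();
    n = (int)T[0].size();
    full = S - 1;
    uq.assign(n, 0.0);
    for (int s = 0; s < S; ++s)
      for (int j = 0; j < n; ++j) uq[j] += T[s][j];
    for (int j = 0; j < n; ++j) uq[j] /= S;
    for (int sz = 1; sz <= n; ++sz)
      for (int m = 1; m <= full; ++m)
        if (popcnt(m) == sz) purview_order.push_back(m);
    null_concept.mech = 0;
    null_concept.cause_full.assign(S, 1.0 / S);
    null_concept.eff_marg = uq;
  }

  // Effect marginal of node j given mechanism `mech` clamped to `state`
  // (remaining nodes marginalised uniformly). mech == 0 is unconstrained.
  double effect_marginal(int j, int mech, int state) const {
    if (mech == 0) return uq[j];
    double acc = 0.0;
    int cnt = 0;
    int ms = state & mech;
    for (int s = 0; s < S; ++s)
      if ((s & mech) == ms) { acc += T[s][j]; ++cnt; }
    return acc / cnt;
  }

  // Single mechanism-node cause factor over purview P (Bayesian posterior
  // over past purview states with a uniform prior; non-purview past nodes
  // marginalised uniformly). Normalised; an impossible conditioning event
  // yields a uniform factor and is counted.
  std::vector<double> cause_factor(int i, int on, int P) {
    const int PS = 1 << popcnt(P);
    std::vector<double> f(PS, 0.0);
    for (int s = 0; s < S; ++s) {
      double w = on ? T[s][i] : 1.0 - T[s][i];
      f[compress_state(s, P)] += w;
    }
    double tot = 0.0;
    for (double v : f) tot += v;
    if (tot <= 1e-15) { ++zero_cond; return std::vector<double>(PS, 1.0 / PS); }
    for (double& v : f) v /= tot;
    return f;
  }

  std::vector<double> cause_rep(int mech, int state, int P) {
    const int PS = 1 << popcnt(P);
    std::vector<double> r(PS, 1.0 / PS);
    if (mech == 0 || P == 0) return P == 0 ? std::vector<double>{1.0} : r;
    bool first = true;
    for (int k = 0; k < n; ++k) {
      if (!(mech & (1 << k))) continue;
      std::vector<double> f = cause_factor(k, (state >> k) & 1, P);
      if (first) { r = f; first = false; }
      else for (int u = 0; u < PS; ++u) r[u] *= f[u];
    }
    double tot = 0.0;
    for (double v : r) tot += v;
    if (tot <= 1e-15) { ++zero_cond; return std::vector<double>(PS, 1.0 / PS); }
    for (double& v : r) v /= tot;
    return r;
  }

  std::vector<double> effect_rep(int mech, int state, int P) const {
    if (P == 0) return {1.0};
    const int pc = popcnt(P);
    const int PS = 1 << pc;
    std::vector<double> marg(pc);
    int b = 0;
    for (int k = 0; k < n; ++k)
      if (P & (1 << k)) marg[b++] = effect_marginal(k, mech, state);
    std::vector<double> r(PS, 1.0);
    for (int u = 0; u < PS; ++u)
      for (int c = 0; c < pc; ++c)
        r[u] *= ((u >> c) & 1) ? marg[c] : 1.0 - marg[c];
    return r;
  }

  std::vector<double> repertoire(int dir, int mech, int state, int P) {
    return dir == 0 ? cause_rep(mech, state, P) : effect_rep(mech, state, P);
  }

  // Combine part repertoires r1 (over P1) and r2 (over P2) into a
  // distribution over P = P1 | P2.
  std::vector<double> combine(const std::vector<double>& r1, int P1,
                              const std::vector<double>& r2, int P2,
                              int P) const {
    const int PS = 1 << popcnt(P);
    std::vector<double> out(PS, 1.0);
    for (int u = 0; u < PS; ++u) {
      int fs = expand_state(u, P);
      double v = 1.0;
      if (P1) v *= r1[compress_state(fs, P1)];
      if (P2) v *= r2[compress_state(fs, P2)];
      out[u] = v;
    }
    return out;
  }

  // Small-phi over partitions of (mech, P) for one direction; the whole
  // repertoire is supplied by the caller. Partitions are ordered pairs
  // (M1, P1) with M1 a submask of mech and P1 of P; a part may not be
  // empty on both sides. First minimum wins.
  double phi_mip(int dir, int mech, int state, int P,
                 const std::vector<double>& whole, Mice* out) {
    double best = 1e300;
    int bm1 = -1, bp1 = 0, bm2 = 0, bp2 = 0;
    // effect partitions factorise over nodes: EMD = L1 of node marginals
    std::vector<double> whole_marg;
    if (dir == 1) {
      for (int k = 0; k < n; ++k)
        if (P & (1 << k)) whole_marg.push_back(effect_marginal(k, mech, state));
    }
    for (int m1 = 0; m1 <= mech; ++m1) {
      if ((m1 & mech) != m1) continue;
      const int m2 = mech ^ m1;
      for (int p1 = 0; p1 <= P; ++p1) {
        if ((p1 & P) != p1) continue;
        const int p2 = P ^ p1;
        if ((m1 == 0 && p1 == 0) || (m2 == 0 && p2 == 0)) continue;
        double d;
        if (dir == 1) {
          d = 0.0;
          int b = 0;
          for (int k = 0; k < n; ++k) {
            if (!(P & (1 << k))) continue;
            int mk = (p1 & (1 << k)) ? m1 : m2;
            d += std::fabs(whole_marg[b] - effect_marginal(k, mk, state));
            ++b;
          }
        } else {
          std::vector<double> r1 = cause_rep(m1, state, p1);
          std::vector<double> r2 = cause_rep(m2, state, p2);
          std::vector<double> part = combine(r1, p1, r2, p2, P);
          double lb = total_variation(whole, part);
          if (lb >= best - CMP_EPS && lb > EPS_PHI) continue;  // cannot improve
          d = (lb <= EPS_PHI) ? 0.0 : emd_hamming_states(whole, part);
        }
        if (d < best - CMP_EPS) {
          best = d;
          bm1 = m1; bp1 = p1; bm2 = m2; bp2 = p2;
          if (best <= EPS_PHI) { best = 0.0; goto done; }
        }
      }
    }
  done:
    if (out) { out->m1 = bm1; out->p1 = bp1; out->m2 = bm2; out->p2 = bp2; }
    return best < 1e299 ? best : 0.0;
  }

  // Maximally irreducible cause/effect: maximise small-phi over purviews.
  Mice mice(int dir, int mech, int state) {
    Mice best;
    best.purview = purview_order.front();
    best.phi = -1.0;
    for (int P : purview_order) {
      std::vector<double> whole = repertoire(dir, mech, state, P);
      Mice cand;
      double phi = phi_mip(dir, mech, state, P, whole, &cand);
      if (phi > best.phi + CMP_EPS) {
        best = cand;
        best.purview = P;
        best.phi = phi;
        best.rep = whole;
      }
    }
    if (best.phi < 0) {  // all purviews gave zero
      best.phi = 0.0;
      best.rep = repertoire(dir, mech, state, best.purview);
    }
    return best;
  }

  ConceptC& concept_for(int mech, int state) {
    const std::pair<int, int> key(mech, state & mech);
    auto it = cache.find(key);
    if (it != cache.end()) return it->second;
    ConceptC c;
    c.mech = mech;
    c.cause = mice(0, mech, state);
    c.effect = mice(1, mech, state);
    c.phi_cause = c.cause.phi;
    c.phi_effect = c.effect.phi;
    c.phi = std::min(c.phi_cause, c.phi_effect);
    if (c.phi > EPS_PHI) {
      // expand to the full node set for constellation-space distances
      const int P = c.cause.purview;
      const double fill = 1.0 / (1 << (n - popcnt(P)));
      c.cause_full.assign(S, 0.0);
      for (int s = 0; s < S; ++s)
        c.cause_full[s] = c.cause.rep[compress_state(s, P)] * fill;
      c.eff_marg.assign(n, 0.0);
      for (int k = 0; k < n; ++k)
        c.eff_marg[k] = (c.effect.purview & (1 << k))
                            ? effect_marginal(k, mech, state)
                            : uq[k];
    }
    return cache.emplace(key, std::move(c)).first->second;
  }

  std::vector<const ConceptC*> constellation(int state) {
    std::vector<const ConceptC*> out;
    for (int mech : purview_order) {  // same (size, mask) order over subsets
      const ConceptC& c = concept_for(mech, state);
      if (c.phi > EPS_PHI) out.push_back(&c);
    }
    return out;
  }

  // Engine for the unidirectional cut A -> B (B = complement of A):
  // inputs from A into nodes of B are noised (marginalised uniformly).
  Engine& cut_engine(int A) {
    auto it = cut_cache.find(A);
    if (it != cut_cache.end()) return *it->second;
    auto eng = std::make_unique<Engine>();
    const int B = full & ~A;
    std::vector<std::vector<double>> T2(S, std::vector<double>(n, 0.0));
    for (int j = 0; j < n; ++j) {
      if (!(B & (1 << j))) {
        for (int s = 0; s < S; ++s) T2[s][j] = T[s][j];
        continue;
      }
      for (int s = 0; s < S; ++s) {
        // average over the A-bits of the conditioning state
        double acc = 0.0;
        int cnt = 0;
        for (int a = 0; a <= A; ++a) {
          if ((a & A) != a) continue;
          acc += T[(s & ~A) | a][j];
          ++cnt;
        }
        T2[s][j] = acc / cnt;
      }
    }
    eng->init(T2);
    Engine& ref = *eng;
    cut_cache.emplace(A, std::move(eng));
    return ref;
  }
};

double concept_distance(const ConceptC& c1, const ConceptC& c2) {
  double d = emd_hamming_states(c1.cause_full, c2.cause_full);
  for (size_t k = 0; k < c1.eff_marg.size(); ++k)
    d += std::fabs(c1.eff_marg[k] - c2.eff_marg[k]);
  return d;
}

// Extended EMD between constellations: concept small-phi is transported
// mass; surplus on either side pays its distance to the (uncut) null
// concept, implemented as an extra null node on each side.
double ces_distance(const std::vector<const ConceptC*>& C1,
                    const std::vector<const ConceptC*>& C2,
                    const ConceptC& null_c) {
  const int n1 = (int)C1.size(), n2 = (int)C2.size();
  double sum1 = 0.0, sum2 = 0.0;
  for (auto* c : C1) sum1 += c->phi;
  for (auto* c : C2) sum2 += c->phi;
  if (sum1 + sum2 <= 1e-15) return 0.0;
  std::vector<double> a(n1 + 1), b(n2 + 1);
  for (int i = 0; i < n1; ++i) a[i] = C1[i]->phi;
  a[n1] = sum2;
  for (int j = 0; j < n2; ++j) b[j] = C2[j]->phi;
  b[n2] = sum1;
  std::vector<std::vector<double>> C(n1 + 1, std::vector<double>(n2 + 1, 0.0));
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) C[i][j] = concept_distance(*C1[i], *C2[j]);
    C[i][n2] = concept_distance(*C1[i], null_c);
  }
  for (int j = 0; j < n2; ++j) C[n1][j] = concept_distance(null_c, *C2[j]);
  C[n1][n2] = 0.0;
  return transport(a, b, C);
}

// System-level Phi for one state: minimum over unidirectional cuts of the
// constellation distance between the intact and the cut constellation.
double big_phi(Engine& E, int state, int* best_cut,
               std::vector<const ConceptC*>* ces_out) {
  std::vector<const ConceptC*> C = E.constellation(state);
  if (ces_out) *ces_out = C;
  if (C.empty()) { if (best_cut) *best_cut = 1; return 0.0; }
  double best = 1e300;
  int bcut = 1;
  for (int A = 1; A < E.full; ++A) {
    Engine& cutE = E.cut_engine(A);
    std::vector<const ConceptC*> C2 = cutE.constellation(state);
    double d = ces_distance(C, C2, E.null_concept);
    if (d < best - CMP_EPS) {
      best = d;
      bcut = A;
      if (best <= EPS_PHI) { best = 0.0; break; }
    }
  }
  if (best_cut) *best_cut = bcut;
  return best < 1e299 ? std::max(best, 0.0) : 0.0;
}

// ---- helpers to cross the R boundary ----

std::vector<std::vector<double>> tpm_from_R(const NumericMatrix& tpm) {
  const int S = tpm.nrow(), n = tpm.ncol();
  if (S != (1 << n))
    stop("state-by-node TPM must have 2^n rows for n columns");
  std::vector<std::vector<double>> T(S, std::vector<double>(n));
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < n; ++j) {
      double v = tpm(s, j);
      if (v < -1e-9 || v > 1 + 1e-9 || !R_finite(v))
        stop("TPM probabilities must lie in [0, 1]");
      T[s][j] = std::min(1.0, std::max(0.0, v));
    }
  return T;
}

int mask_from_nodes(const IntegerVector& nodes, int n) {
  int m = 0;
  for (int k : nodes) {
    if (k < 1 || k > n) stop("node index out of range");
    m |= 1 << (k - 1);
  }
  return m;
}

IntegerVector nodes_from_mask(int mask, int n) {
  std::vector<int> out;
  for (int k = 0; k < n; ++k)
    if (mask & (1 << k)) out.push_back(k + 1);
  return wrap(out);
}

int state_from_bits(const IntegerVector& bits) {
  int s = 0;
  for (int k = 0; k < bits.size(); ++k) {
    if (bits[k] != 0 && bits[k] != 1) stop("state must be a 0/1 vector");
    s |= bits[k] << k;
  }
  return s;
}

List concept_to_list(const ConceptC& c, int n) {
  return List::create(
      _["mechanism"] = nodes_from_mask(c.mech, n),
      _["phi"] = c.phi,
      _["phi_cause"] = c.phi_cause,
      _["phi_effect"] = c.phi_effect,
      _["cause_purview"] = nodes_from_mask(c.cause.purview, n),
      _["effect_purview"] = nodes_from_mask(c.effect.purview, n),
      _["cause_repertoire"] = wrap(c.cause.rep),
      _["effect_repertoire"] = wrap(c.effect.rep));
}

}  // namespace

// [[Rcpp::export]]
double cpp_emd_hamming(NumericVector p, NumericVector q) {
  if (p.size() != q.size()) stop("p and q must have equal length");
  int S = p.size();
  if (S < 1 || (S & (S - 1)) != 0)
    stop("length must be a power of two (distribution over bit-states)");
  std::vector<double> pv(p.begin(), p.end()), qv(q.begin(), q.end());
  return emd_hamming_states(pv, qv);
}

// [[Rcpp::export]]
NumericVector cpp_repertoire(NumericMatrix tpm, IntegerVector state_bits,
                             IntegerVector mechanism, IntegerVector purview,
                             std::string direction) {
  Engine E;
  E.init(tpm_from_R(tpm));
  if ((int)state_bits.size() != E.n) stop("state must have one bit per node");
  int dir;
  if (direction == "cause") dir = 0;
  else if (direction == "effect") dir = 1;
  else stop("direction must be 'cause' or 'effect'");
  const int mech = mask_from_nodes(mechanism, E.n);
  const int P = mask_from_nodes(purview, E.n);
  if (P == 0) stop("purview must be non-empty");
  std::vector<double> r = E.repertoire(dir, mech, state_from_bits(state_bits), P);
  NumericVector out = wrap(r);
  out.attr("zero_conditioning") = E.zero_cond;
  return out;
}

// [[Rcpp::export]]
List cpp_mechanism_concept(NumericMatrix tpm, IntegerVector state_bits,
                           IntegerVector mechanism) {
  Engine E;
  E.init(tpm_from_R(tpm));
  if ((int)state_bits.size() != E.n) stop("state must have one bit per node");
  const int mech = mask_from_nodes(mechanism, E.n);
  if (mech == 0) stop("mechanism must be non-empty");
  const ConceptC& c = E.concept_for(mech, state_from_bits(state_bits));
  List out = concept_to_list(c, E.n);
  out["cause_mip"] = List::create(
      _["mechanism_part1"] = nodes_from_mask(c.cause.m1, E.n),
      _["purview_part1"] = nodes_from_mask(c.cause.p1, E.n),
      _["mechanism_part2"] = nodes_from_mask(c.cause.m2, E.n),
      _["purview_part2"] = nodes_from_mask(c.cause.p2, E.n));
  out["effect_mip"] = List::create(
      _["mechanism_part1"] = nodes_from_mask(c.effect.m1, E.n),
      _["purview_part1"] = nodes_from_mask(c.effect.p1, E.n),
      _["mechanism_part2"] = nodes_from_mask(c.effect.m2, E.n),
      _["purview_part2"] = nodes_from_mask(c.effect.p2, E.n));
  out["zero_conditioning"] = E.zero_cond;
  return out;
}

// [[Rcpp::export]]
List cpp_system_phi(NumericMatrix tpm, IntegerVector state_bits) {
  Engine E;
  E.init(tpm_from_R(tpm));
  if ((int)state_bits.size() != E.n) stop("state must have one bit per node");
  const int state = state_from_bits(state_bits);
  int cut = 1;
  std::vector<const ConceptC*> ces;
  double phi = big_phi(E, state, &cut, &ces);
  List concepts(ces.size());
  for (size_t i = 0; i < ces.size(); ++i)
    concepts[i] = concept_to_list(*ces[i], E.n);
  return List::create(
      _["phi"] = phi,
      _["cut_from"] = nodes_from_mask(cut, E.n),
      _["cut_to"] = nodes_from_mask(E.full & ~cut, E.n),
      _["concepts"] = concepts,
      _["zero_conditioning"] = E.zero_cond);
}

// Phi for several states of one TPM, sharing concept and cut caches.
// [[Rcpp::export]]
List cpp_phi_states(NumericMatrix tpm, IntegerVector states0) {
  Engine E;
  E.init(tpm_from_R(tpm));
  const int ns = states0.size();
  NumericVector phi(ns), sum_small_phi(ns);
  IntegerVector n_concepts(ns);
  List cuts(ns);
  for (int i = 0; i < ns; ++i) {
    const int state = states0[i];
    if (state < 0 || state >= E.S) stop("state index out of range");
    int cut = 1;
    std::vector<const ConceptC*> ces;
    phi[i] = big_phi(E, state, &cut, &ces);
    n_concepts[i] = (int)ces.size();
    double sp = 0.0;
    for (auto* c : ces) sp += c->phi;
    sum_small_phi[i] = sp;
    cuts[i] = List::create(_["from"] = nodes_from_mask(cut, E.n),
                           _["to"] = nodes_from_mask(E.full & ~cut, E.n));
  }
  return List::create(
      _["phi"] = phi,
      _["cuts"] = cuts,
      _["n_concepts"] = n_concepts,
      _["sum_small_phi"] = sum_small_phi,
      _["zero_conditioning"] = E.zero_cond);
}
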